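#' Configuration for the planted-network count simulator
#'
#' The generator emulates the situation the benchmark is built for:
#' negative-binomial RNA-seq counts — heteroscedastic, with variance growing
#' with the mean — carrying a planted hub-regulator network, scored against
#' an incomplete "literature" reference derived from the ground truth.
#'
#' @param n_genes,n_samples Matrix dimensions (default 200 x 100).
#' @param n_hubs Number of regulator hubs (default 5).
#' @param targets_per_hub Targets regulated by each hub (default 10); hubs
#'   and their targets are disjoint gene sets.
#' @param signal Latent correlation between a hub and each of its targets,
#'   in (0, 1); default 0.9.
#' @param dispersion NB dispersion: `variance = mu + dispersion * mu^2`;
#'   default 0.1.
#' @param lib_size_range Range of expected per-sample totals; default
#'   2e5-4e5 (about 1000-2000 expected counts per gene at 200 genes, the
#'   per-gene depth a 20-40M-read library gives a 20k-gene transcriptome).
#' @param length_log_mean,length_log_sd Log-normal gene-length parameters
#'   (bases); defaults 7.5 and 0.7 (~1.8 kb median).
#' @param reference_coverage Fraction of true edges kept in the degraded
#'   reference, default 0.6.
#' @param reference_noise_edges Decoy (non-true) reference edges added,
#'   default 50.
#' @param seed Integer seed, default 1.
#' @export
synthetic_config <- function(n_genes = 200L, n_samples = 100L, n_hubs = 5L,
                             targets_per_hub = 10L, signal = 0.9,
                             dispersion = 0.1,
                             lib_size_range = c(2e5, 4e5),
                             length_log_mean = 7.5, length_log_sd = 0.7,
                             reference_coverage = 0.6,
                             reference_noise_edges = 50L, seed = 1L) {
  if (signal <= 0 || signal >= 1) stop("'signal' must be in (0, 1)")
  if (reference_coverage < 0 || reference_coverage > 1)
    stop("'reference_coverage' must be in [0, 1]")
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  if (n_hubs * targets_per_hub >= choose(n_genes, 2))
    stop("planted edges must be fewer than the number of gene pairs")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 n_hubs = as.integer(n_hubs),
                 targets_per_hub = as.integer(targets_per_hub),
                 signal = signal, dispersion = dispersion,
                 lib_size_range = lib_size_range,
                 length_log_mean = length_log_mean,
                 length_log_sd = length_log_sd,
                 reference_coverage = reference_coverage,
                 reference_noise_edges = as.integer(reference_noise_edges),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate counts with a planted hub network
#'
#' Each hub gets a standard-normal latent regulator value per sample; each
#' of its targets' latent values are `signal * hub + sqrt(1 - signal^2) *
#' noise`, and all remaining genes are independent N(0, 1). Latent values
#' pass through an exponential link (per-gene baseline abundances spread
#' log-normally, latent scale 0.7 on the natural-log scale) to per-gene NB
#' means, column-scaled to a library size drawn uniformly from
#' `lib_size_range`; counts are drawn NB with the configured dispersion, so
#' variance grows with the mean as in real RNA-seq. Gene lengths are
#' log-normal. The ground truth is exactly the hub-target edge set.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `counts` (integer matrix, genes x samples), `lengths`
#'   (named vector, bases), `truth` (the planted [gene_network()]) and `cfg`.
#' @export
generate_planted_dataset <- function(cfg = synthetic_config()) {
  g <- cfg$n_genes
  n <- cfg$n_samples
  n_net <- cfg$n_hubs * (1L + cfg$targets_per_hub)
  if (n_net > g)
    stop("infeasible topology: ", cfg$n_hubs, " hubs with ",
         cfg$targets_per_hub, " targets each need ", n_net, " genes, have ",
         g)
  genes <- sprintf("G%04d", seq_len(g))
  hubs <- genes[seq_len(cfg$n_hubs)]
  target_idx <- cfg$n_hubs + seq_len(cfg$n_hubs * cfg$targets_per_hub)
  hub_of <- rep(seq_len(cfg$n_hubs), each = cfg$targets_per_hub)
  with_seed(cfg$seed, {
    z <- matrix(stats::rnorm(g * n), g, n, dimnames = list(genes, NULL))
    z[target_idx, ] <- cfg$signal * z[hub_of, , drop = FALSE] +
      sqrt(1 - cfg$signal^2) * z[target_idx, , drop = FALSE]
    base <- stats::rnorm(g, 0, 1.0)      # per-gene log-abundance spread
    mu <- exp(base + 0.7 * z)            # latent scale 0.7 on the log link
    lib <- stats::runif(n, cfg$lib_size_range[1L], cfg$lib_size_range[2L])
    mu <- sweep(sweep(mu, 2L, colSums(mu), "/"), 2L, lib, "*")
    counts <- matrix(
      if (cfg$dispersion > 0)
        stats::rnbinom(g * n, mu = mu, size = 1 / cfg$dispersion)
      else stats::rpois(g * n, lambda = mu),
      g, n, dimnames = list(genes, sprintf("S%03d", seq_len(n))))
    lengths <- stats::setNames(
      pmax(200, round(stats::rlnorm(g, cfg$length_log_mean,
                                    cfg$length_log_sd))), genes)
    truth <- gene_network(hubs[hub_of], genes[target_idx])
    list(counts = counts, lengths = lengths, truth = truth, cfg = cfg)
  })
}

#' Degrade a ground-truth network into an incomplete reference
#'
#' Models an incomplete literature database: a seeded random
#' `coverage` fraction of the true edges is kept and `noise_edges` decoy
#' pairs (absent from the truth) are added. Against such a reference a
#' perfect predictor scores precision close to `coverage`.
#'
#' @param truth Ground-truth [gene_network()].
#' @param genes Gene universe the decoys are drawn from.
#' @param coverage Fraction of true edges kept, default 0.6.
#' @param noise_edges Number of decoy edges, default 50.
#' @param seed Integer seed.
#' @return The degraded reference [gene_network()].
#' @export
degrade_reference <- function(truth, genes, coverage = 0.6,
                              noise_edges = 50L, seed = NULL) {
  n_true <- n_edges(truth)
  avail <- choose(length(unique(genes)), 2) - n_true
  if (noise_edges > avail)
    stop("'noise_edges' (", noise_edges, ") exceeds the ", avail,
         " non-true pairs available")
  with_seed(seed, {
    n_keep <- round(coverage * n_true)
    keep <- sort(sample.int(n_true, n_keep))
    kept <- truth$edges[keep, , drop = FALSE]
    truth_keys <- paste(truth$edges$from, truth$edges$to, sep = "\t")
    decoy_from <- character(0)
    decoy_to <- character(0)
    while (length(decoy_from) < noise_edges) {
      cand <- random_network(genes, noise_edges - length(decoy_from))$edges
      ck <- paste(cand$from, cand$to, sep = "\t")
      new <- !(ck %in% truth_keys) &
        !(ck %in% paste(decoy_from, decoy_to, sep = "\t"))
      decoy_from <- c(decoy_from, cand$from[new])
      decoy_to <- c(decoy_to, cand$to[new])
    }
    gene_network(c(kept$from, decoy_from), c(kept$to, decoy_to))
  })
}
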