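#' Evaluation universe
#'
#' The universe is the set of genes eligible for pairing — by default the
#' genes of the post-filtering expression matrix, since only those can be
#' predicted. It fixes the total number of candidate pairs `C(n, 2)` and the
#' reference edges with both endpoints inside the gene set, the two
#' quantities the overlap tests condition on.
#'
#' @param genes Character vector of gene symbols.
#' @param ref A reference [gene_network()].
#' @return A `universe` list with `genes`, `n_pairs` and `reference`
#'   (the reference restricted to the universe).
#' @export
make_universe <- function(genes, ref) {
  genes <- unique(genes)
  inside <- ref$edges$from %in% genes & ref$edges$to %in% genes
  structure(list(genes = genes,
                 n_pairs = choose(length(genes), 2),
                 reference = gene_network(ref$edges$from[inside],
                                          ref$edges$to[inside])),
            class = "universe")
}

#' Overlap and precision against a reference network
#'
#' A predicted edge counts as a true positive when the same unordered pair
#' appears in the reference; everything else predicted is a false positive.
#' `network_precision()` is TP / (TP + FP). Recall-type metrics are
#' deliberately not part of the default report: with an incomplete reference
#' an absent edge is not evidence of a true negative, so only the predicted
#' set is scored. (For synthetic data with a complete ground truth,
#' [network_recall()] is available.)
#'
#' @param pred,ref [gene_network()] objects (predicted and reference).
#' @return `network_overlap()`: the TP count. `network_precision()`: TP over
#'   predicted edges; an empty prediction is an error since the ratio is
#'   undefined.
#' @export
network_overlap <- function(pred, ref) {
  length(intersect(edge_keys(pred), edge_keys(ref)))
}

#' @rdname network_overlap
#' @export
network_precision <- function(pred, ref) {
  if (n_edges(pred) == 0L)
    stop("precision is undefined for an empty predicted network")
  network_overlap(pred, ref) / n_edges(pred)
}

#' @rdname network_overlap
#' @export
network_recall <- function(pred, ref) {
  if (n_edges(ref) == 0L)
    stop("recall is undefined for an empty reference network")
  network_overlap(pred, ref) / n_edges(ref)
}

check_in_universe <- function(pred, universe) {
  out <- !(pred$edges$from %in% universe$genes &
             pred$edges$to %in% universe$genes)
  if (any(out))
    stop(sum(out), " predicted edge(s) fall outside the universe gene set")
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability of drawing at least the observed number of
#' reference pairs when `|pred|` pairs are sampled without replacement from
#' the `C(n, 2)` universe pairs of which `|ref in universe|` are reference.
#' Smaller values mean the predicted network overlaps the reference more than
#' chance would allow.
#'
#' @param pred Predicted [gene_network()]; its edges must lie inside the
#'   universe.
#' @param universe A [make_universe()] object (carries the reference).
#' @return The p-value.
#' @export
hypergeom_overlap_test <- function(pred, universe) {
  check_in_universe(pred, universe)
  tp <- network_overlap(pred, universe$reference)
  m <- n_edges(universe$reference)
  k <- n_edges(pred)
  if (tp > min(k, m))
    stop("internal inconsistency: TP exceeds min(|pred|, |ref|)")
  stats::phyper(tp - 1, m, universe$n_pairs - m, k, lower.tail = FALSE)
}

#' One-sided Fisher overlap test
#'
#' Exact test on the 2x2 table (predicted x reference over universe pairs),
#' alternative "greater". Degenerate tables (e.g. the reference covering all
#' pairs) give p = 1.
#'
#' @inheritParams hypergeom_overlap_test
#' @export
fisher_overlap_test <- function(pred, universe) {
  check_in_universe(pred, universe)
  tp <- network_overlap(pred, universe$reference)
  k <- n_edges(pred)
  m <- n_edges(universe$reference)
  N <- universe$n_pairs
  tab <- matrix(c(tp, k - tp, m - tp, N - k - m + tp), nrow = 2)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

# Decode linear indices over the upper triangle enumerated row-major:
# (1,2),(1,3),...,(1,g),(2,3),... into (i, j) pairs.
decode_pair <- function(idx, g) {
  i <- ceiling(g - 0.5 - sqrt((g - 0.5)^2 - 2 * idx))
  j <- idx - (i - 1) * g + i * (i - 1) / 2 + i
  cbind(i, j)
}

#' Seeded uniform random network
#'
#' Samples `n_edges` distinct unordered gene pairs uniformly without
#' replacement; no self-loops or duplicates, reproducible for a fixed seed.
#'
#' @param genes Character vector of gene symbols.
#' @param n_edges Number of edges, at most `C(length(genes), 2)`.
#' @param seed Integer seed.
#' @export
random_network <- function(genes, n_edges, seed = NULL) {
  genes <- unique(genes)
  g <- length(genes)
  total <- choose(g, 2)
  if (n_edges > total)
    stop("'n_edges' (", n_edges, ") exceeds the number of gene pairs (",
         total, ")")
  idx <- with_seed(seed, sample(total, n_edges))
  ij <- decode_pair(idx, g)
  gene_network(genes[ij[, 1L]], genes[ij[, 2L]])
}

#' Random-network performance baseline
#'
#' Generates `n_networks` seeded random networks with `n_edges` edges over
#' the universe genes and reports each one's precision and hypergeometric
#' overlap p-value against the reference. The mean precision estimates the
#' chance level `|ref in universe| / n_pairs` and anchors the interpretation
#' of every other performance score: a combination near this level predicts
#' no better than random pairing.
#'
#' @param genes Universe gene symbols.
#' @param n_edges Edges per random network.
#' @param n_networks Number of networks, default 10.
#' @param ref Reference [gene_network()].
#' @param seed Integer seed; network b uses `seed + b`.
#' @return List with `mean_precision`, per-network `precisions` and
#'   `p_values`, and the analytic `expected_precision`.
#' @export
random_baseline <- function(genes, n_edges, n_networks = 10L, ref,
                            seed = NULL) {
  universe <- make_universe(genes, ref)
  precisions <- numeric(n_networks)
  p_values <- numeric(n_networks)
  for (b in seq_len(n_networks)) {
    net <- random_network(universe$genes, n_edges,
                          seed = if (is.null(seed)) NULL else seed + b)
    precisions[b] <- network_overlap(net, universe$reference) / n_edges
    p_values[b] <- hypergeom_overlap_test(net, universe)
  }
  list(mean_precision = mean(precisions), precisions = precisions,
       p_values = p_values,
       expected_precision = n_edges(universe$reference) / universe$n_pairs)
}

#' Score a predicted network against a reference
#'
#' Bundles overlap, precision and the chosen overlap test into the fields of
#' a performance record.
#'
#' @param pred Predicted [gene_network()].
#' @param universe A [make_universe()] object.
#' @param test `"hypergeometric"` (default) or `"fisher"`.
#' @return List with `tp`, `predicted`, `precision`, `p_value`.
#' @export
evaluate_network <- function(pred, universe,
                             test = c("hypergeometric", "fisher")) {
  test <- match.arg(test)
  tp <- network_overlap(pred, universe$reference)
  k <- n_edges(pred)
  p <- if (k == 0L) NA_real_
       else if (test == "hypergeometric") hypergeom_overlap_test(pred, universe)
       else fisher_overlap_test(pred, universe)
  list(tp = tp, predicted = k,
       precision = if (k == 0L) NA_real_ else tp / k,
       p_value = p)
}
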