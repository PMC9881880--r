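#' Inference algorithm names and configuration
#'
#' @return `gni_algorithms()` returns `c("relnet", "c3net", "aracne")`.
#' @export
gni_algorithms <- function() c("relnet", "c3net", "aracne")

# Short record prefixes used in combination labels.
gni_prefix <- c(relnet = "rn", c3net = "c3", aracne = "ar")

#' @rdname gni_algorithms
#' @param algorithm One of [gni_algorithms()].
#' @param threshold_mode How the significance threshold is chosen:
#'   `"permutation"` (default; seeded row-shuffle null), `"top_k"` (keep the
#'   k strongest pairs) or `"absolute"` (user-supplied value).
#' @param alpha Significance level for the permutation null, default 0.01.
#' @param n_permutations Number of row-shuffle permutations, default 1000.
#' @param k Target pair count for `top_k` mode.
#' @param value Threshold for `absolute` mode.
#' @param dpi_eps Additive DPI tolerance for ARACNE, default 0: an edge is
#'   removed when some triangle partner pair both exceed it by more than
#'   `dpi_eps`. At 0 every triangle loses its strictly weakest edge, which
#'   shrinks ARACNE's output to near C3NET size.
#' @param seed Integer seed for the permutation null.
#' @export
gni_config <- function(algorithm = "c3net",
                       threshold_mode = c("permutation", "top_k", "absolute"),
                       alpha = 0.01, n_permutations = 1000L, k = NULL,
                       value = NULL, dpi_eps = 0, seed = NULL) {
  algorithm <- match.arg(algorithm, gni_algorithms())
  threshold_mode <- match.arg(threshold_mode)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (dpi_eps < 0) stop("'dpi_eps' must be >= 0")
  structure(list(algorithm = algorithm, threshold_mode = threshold_mode,
                 alpha = alpha, n_permutations = as.integer(n_permutations),
                 k = k, value = value, dpi_eps = dpi_eps, seed = seed),
            class = "gni_config")
}

offdiag_scores <- function(A) A[upper.tri(A)]

#' Significance threshold for an association matrix
#'
#' Permutation mode shuffles each row of the expression matrix independently
#' (seeded), recomputes the association matrix per permutation, pools the
#' off-diagonal null scores and takes their `1 - alpha` quantile. `top_k`
#' mode returns the k-th largest off-diagonal score; `absolute` mode returns
#' the user value.
#'
#' @param A Association matrix.
#' @param m Expression matrix the permutation null is built from (with the
#'   same estimator `config`); required in permutation mode.
#' @param cfg A [gni_config()].
#' @param config The [estimator_config()] used for `A`.
#' @export
significance_threshold <- function(A, m = NULL, cfg = gni_config(),
                                   config = estimator_config("PCC")) {
  switch(cfg$threshold_mode,
    absolute = {
      if (is.null(cfg$value)) stop("absolute mode needs 'value'")
      cfg$value
    },
    top_k = {
      s <- sort(offdiag_scores(A), decreasing = TRUE)
      if (is.null(cfg$k) || cfg$k < 1L || cfg$k > length(s))
        stop("'k' must be between 1 and the number of gene pairs (",
             length(s), ")")
      s[cfg$k]
    },
    permutation = {
      if (is.null(m)) stop("permutation mode needs the expression matrix 'm'")
      null_scores <- with_seed(cfg$seed, {
        unlist(lapply(seq_len(cfg$n_permutations), function(p) {
          perm <- m
          for (i in seq_len(nrow(m)))
            perm[i, ] <- m[i, sample.int(ncol(m))]
          offdiag_scores(association_matrix(perm, config))
        }))
      })
      stats::quantile(null_scores, 1 - cfg$alpha, names = FALSE)
    })
}

net_from_pairs <- function(A, idx) {
  sym <- rownames(A)
  gene_network(sym[idx[, 1L]], sym[idx[, 2L]], weight = A[idx])
}

#' RELNET: relevance network
#'
#' Keeps every pair whose (positive) score reaches the threshold; all other
#' algorithms here prune this network further, so at equal threshold
#' `c3net <= aracne(eps = 0) <= relnet` as edge sets.
#'
#' @param A Symmetric association matrix with gene rownames.
#' @param threshold Non-negative score threshold.
#' @export
relnet <- function(A, threshold) {
  if (threshold < 0) stop("'threshold' must be >= 0")
  sel <- which(upper.tri(A) & A >= threshold & A > 0, arr.ind = TRUE)
  net_from_pairs(A, sel)
}

#' C3NET: one maximal edge per gene
#'
#' Sub-threshold scores are zeroed; each gene with any surviving score
#' contributes the edge to its highest-scoring partner (ties go to the
#' lexicographically smallest partner symbol); the network is the union over
#' genes, so it has at most one edge per gene.
#'
#' @inheritParams relnet
#' @export
c3net <- function(A, threshold) {
  if (threshold < 0) stop("'threshold' must be >= 0")
  S <- A
  S[S < threshold] <- 0
  diag(S) <- 0
  sym <- rownames(A)
  from <- character(0)
  to <- character(0)
  wt <- numeric(0)
  for (i in seq_len(nrow(S))) {
    mx <- max(S[i, ])
    if (mx > 0) {
      cand <- which(S[i, ] == mx)
      j <- cand[order(sym[cand])][1L]
      from <- c(from, sym[i])
      to <- c(to, sym[j])
      wt <- c(wt, mx)
    }
  }
  gene_network(from, to, weight = wt)
}

#' ARACNE: relevance network pruned by the data processing inequality
#'
#' Starts from [relnet()] and removes edge (i, j) when some gene k closes a
#' triangle with both (i, k) and (j, k) present and
#' `score_ij < min(score_ik, score_jk) - dpi_eps`. Removal decisions are
#' evaluated simultaneously against the pre-pruning edge set, making the
#' result independent of edge order.
#'
#' @inheritParams relnet
#' @param dpi_eps Additive DPI tolerance, default 0.
#' @export
aracne <- function(A, threshold, dpi_eps = 0) {
  if (dpi_eps < 0) stop("'dpi_eps' must be >= 0")
  adj <- A >= threshold & A > 0
  diag(adj) <- FALSE
  sel <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(net_from_pairs(A, sel))
  keep <- vapply(seq_len(nrow(sel)), function(e) {
    i <- sel[e, 1L]
    j <- sel[e, 2L]
    k <- which(adj[i, ] & adj[j, ])
    !any(A[i, j] < pmin(A[i, k], A[j, k]) - dpi_eps)
  }, logical(1))
  net_from_pairs(A, sel[keep, , drop = FALSE])
}

#' Infer a network with one of the three algorithms
#'
#' @inheritParams relnet
#' @param algorithm One of [gni_algorithms()].
#' @param dpi_eps ARACNE's DPI tolerance.
#' @export
infer_network <- function(A, algorithm, threshold, dpi_eps = 0) {
  algorithm <- match.arg(algorithm, gni_algorithms())
  switch(algorithm,
    relnet = relnet(A, threshold),
    c3net = c3net(A, threshold),
    aracne = aracne(A, threshold, dpi_eps))
}
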