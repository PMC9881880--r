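#' Association estimator names
#'
#' @return `c("PCC", "SCC", "PBG", "bspline", "CS")` — Pearson, Spearman,
#'   Pearson-based Gaussian MI, B-spline MI and Chao-Shen MI.
#' @export
estimators <- function() c("PCC", "SCC", "PBG", "bspline", "CS")

#' Estimator configuration
#'
#' @param estimator One of [estimators()] (case-insensitive; "BS" is accepted
#'   for the B-spline estimator).
#' @param bins Discretization cardinality B for the MI estimators, default 10.
#' @param spline_order B-spline order k (1 = hard binning, 2 = linear),
#'   default 2; must satisfy `bins >= spline_order`.
#' @param clamp_negative Clamp negative MI estimates to zero, default TRUE.
#' @export
estimator_config <- function(estimator, bins = 10L, spline_order = 2L,
                             clamp_negative = TRUE) {
  est <- estimators()[match(toupper(ifelse(toupper(estimator) == "BS",
                                           "bspline", estimator)),
                            toupper(estimators()))]
  if (is.na(est))
    stop("unknown estimator '", estimator, "'; use one of ",
         paste(estimators(), collapse = ", "))
  bins <- as.integer(bins)
  spline_order <- as.integer(spline_order)
  if (spline_order < 1L) stop("'spline_order' must be >= 1")
  if (bins < spline_order) stop("'bins' must be >= 'spline_order'")
  structure(list(estimator = est, bins = bins, spline_order = spline_order,
                 clamp_negative = isTRUE(clamp_negative)),
            class = "estimator_config")
}

#' Copula transform
#'
#' Per gene (row), values are replaced by their average ranks divided by
#' (n_samples + 1), so the output lies strictly inside (0, 1) and ties share
#' the mean rank. Rank-based downstream statistics (Spearman) are invariant
#' to this map; for tie-free rows it is idempotent.
#'
#' @param m Expression matrix with at least 2 samples.
#' @export
copula_transform <- function(m) {
  if (ncol(m) < 2L) stop("copula transform needs at least 2 samples")
  out <- t(apply(m, 1L, rank, ties.method = "average")) / (ncol(m) + 1)
  dimnames(out) <- dimnames(m)
  out
}

# Shared correlation backbone; constant rows yield r = 0 with one warning.
cor_pairs <- function(m, method) {
  const <- row_vars(m) == 0
  r <- suppressWarnings(stats::cor(t(m), method = method))
  if (any(const)) {
    warning(sum(const), " constant gene(s); their correlations set to 0")
    r[const, ] <- 0
    r[, const] <- 0
  }
  r[!is.finite(r)] <- 0
  dimnames(r) <- list(rownames(m), rownames(m))
  r
}

as_assoc <- function(scores, estimator, signs = NULL) {
  diag(scores) <- 0
  scores <- (scores + t(scores)) / 2  # enforce exact symmetry
  attr(scores, "estimator") <- estimator
  if (!is.null(signs)) attr(scores, "signs") <- signs
  scores
}

#' Pearson and Spearman association matrices
#'
#' Pairwise correlation of gene expression profiles. The stored score is the
#' absolute correlation (edge strength); the sign is retained in the `signs`
#' attribute so positive and negative associations stay distinguishable.
#' Constant rows get score 0 (with a warning). The diagonal is set to 0.
#'
#' @param m Expression matrix (genes x samples).
#' @return Symmetric numeric matrix with attributes `estimator` and `signs`.
#' @export
pcc_matrix <- function(m) {
  r <- cor_pairs(m, "pearson")
  as_assoc(abs(r), "PCC", signs = sign(r))
}

#' @rdname pcc_matrix
#' @export
scc_matrix <- function(m) {
  r <- cor_pairs(m, "spearman")
  as_assoc(abs(r), "SCC", signs = sign(r))
}

#' Pearson-based Gaussian mutual information
#'
#' For bivariate Gaussian data the mutual information is
#' `-0.5 * log(1 - r^2)` nats, with `|r|` clamped to `1 - 1e-12` before the
#' log. Monotone in `|r|`, zero at independence.
#'
#' @param m Expression matrix.
#' @export
pbg_matrix <- function(m) {
  r <- cor_pairs(m, "pearson")
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  as_assoc(-0.5 * log(1 - r^2), "PBG", signs = sign(r))
}

# Fractional bin memberships from B-spline basis functions of order k over
# B bins: values are affinely mapped to [0, B - k + 1] and each observation's
# memberships sum to 1. Returns NULL for constant vectors.
bspline_memberships <- function(x, bins, order) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(NULL)
  top <- bins - order + 1
  z <- (x - rng[1L]) / (rng[2L] - rng[1L]) * top
  z <- pmin(z, top * (1 - 1e-12))  # right edge belongs to the last bin
  knots <- c(rep(0, order), seq_len(bins - order), rep(top, order))
  splines::splineDesign(knots, z, ord = order)
}

#' B-spline mutual information
#'
#' The generalized-histogram MI estimator: each observation is spread over
#' adjacent bins with weights given by B-spline basis functions of order
#' `spline_order` (order 1 reduces to hard equal-width binning); weighted
#' marginal and joint histograms feed the plug-in MI, in nats. Constant
#' vectors score 0; negative estimates are clamped to 0 when
#' `clamp_negative`.
#'
#' @param x,y Numeric vectors of equal length (>= `bins` observations
#'   recommended).
#' @param bins,spline_order,clamp_negative See [estimator_config()].
#' @export
bspline_mi <- function(x, y, bins = 10L, spline_order = 2L,
                       clamp_negative = TRUE) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  wx <- bspline_memberships(x, bins, spline_order)
  wy <- bspline_memberships(y, bins, spline_order)
  if (is.null(wx) || is.null(wy)) return(0)
  mi_from_memberships(wx, wy, clamp_negative)
}

mi_from_memberships <- function(wx, wy, clamp_negative = TRUE) {
  n <- nrow(wx)
  pxy <- crossprod(wx, wy) / n
  px <- colMeans(wx)
  py <- colMeans(wy)
  pos <- pxy > 0
  mi <- sum(pxy[pos] * log(pxy[pos] / outer(px, py)[pos]))
  if (clamp_negative) mi <- max(mi, 0)
  mi
}

# Hard equal-width bin index in 1..bins; NULL for constant vectors.
hard_bins <- function(x, bins) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(NULL)
  idx <- floor((x - rng[1L]) / (rng[2L] - rng[1L]) * bins) + 1L
  pmin(idx, bins)
}

# Chao-Shen coverage-adjusted entropy (nats) from a vector of cell counts.
# Sample coverage C = 1 - f1/n (f1 = singleton cells; f1 = n is backed off to
# n - 1 so C stays positive); each observed cell contributes the
# Horvitz-Thompson term -C*p * log(C*p) / (1 - (1 - C*p)^n).
chao_shen_entropy <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0L || length(counts) == 1L) return(0)
  f1 <- sum(counts == 1L)
  if (f1 == n) f1 <- n - 1L
  cc <- 1 - f1 / n
  p <- cc * counts / n
  sum(-p * log(p) / (1 - (1 - p)^n))
}

#' Chao-Shen mutual information
#'
#' Hard equal-width discretization into `bins` bins per variable, then
#' coverage-adjusted (Horvitz-Thompson) entropies for X, Y and the joint:
#' `MI = H(X) + H(Y) - H(X,Y)`, in nats, clamped at 0. Constant vectors
#' score 0.
#'
#' @inheritParams bspline_mi
#' @export
chao_shen_mi <- function(x, y, bins = 10L, clamp_negative = TRUE) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  bx <- hard_bins(x, bins)
  by <- hard_bins(y, bins)
  if (is.null(bx) || is.null(by)) return(0)
  hx <- chao_shen_entropy(tabulate(bx, bins))
  hy <- chao_shen_entropy(tabulate(by, bins))
  hxy <- chao_shen_entropy(tabulate((bx - 1L) * bins + by, bins * bins))
  mi <- hx + hy - hxy
  if (clamp_negative) mi <- max(mi, 0)
  mi
}

#' Full association matrix for one estimator
#'
#' Computes the symmetric gene-by-gene score matrix for the configured
#' estimator; the diagonal is 0 and the result is deterministic for a fixed
#' input. For the MI estimators the per-gene discretizations are computed
#' once and reused across pairs.
#'
#' @param m Expression matrix with at least 3 genes.
#' @param config An [estimator_config()], or an estimator name.
#' @export
association_matrix <- function(m, config = estimator_config("PCC")) {
  if (is.character(config)) config <- estimator_config(config)
  if (nrow(m) < 3L) stop("need at least 3 genes")
  switch(config$estimator,
    PCC = pcc_matrix(m),
    SCC = scc_matrix(m),
    PBG = pbg_matrix(m),
    bspline = {
      w <- lapply(seq_len(nrow(m)), function(i)
        bspline_memberships(m[i, ], config$bins, config$spline_order))
      pairwise_assoc(m, "bspline", function(i, j) {
        if (is.null(w[[i]]) || is.null(w[[j]])) 0
        else mi_from_memberships(w[[i]], w[[j]], config$clamp_negative)
      })
    },
    CS = {
      b <- lapply(seq_len(nrow(m)), function(i) hard_bins(m[i, ], config$bins))
      h <- vapply(b, function(bi)
        if (is.null(bi)) 0 else chao_shen_entropy(tabulate(bi, config$bins)),
        numeric(1))
      B <- config$bins
      pairwise_assoc(m, "CS", function(i, j) {
        if (is.null(b[[i]]) || is.null(b[[j]])) return(0)
        hxy <- chao_shen_entropy(tabulate((b[[i]] - 1L) * B + b[[j]], B * B))
        mi <- h[i] + h[j] - hxy
        if (config$clamp_negative) max(mi, 0) else mi
      })
    })
}

pairwise_assoc <- function(m, estimator, f) {
  g <- nrow(m)
  scores <- matrix(0, g, g, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(g - 1L)) {
    for (j in seq.int(i + 1L, g)) {
      scores[i, j] <- scores[j, i] <- f(i, j)
    }
  }
  as_assoc(scores, estimator)
}
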