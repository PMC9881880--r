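#' The five normalization options
#'
#' @return `c("TMM", "RLE", "VST", "QN", "NoNorm")`.
#' @export
norm_methods <- function() c("TMM", "RLE", "VST", "QN", "NoNorm")

new_norm_factors <- function(factors, lib_size) {
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("normalization factors must be positive and finite; a sample may ",
         "share no expressed genes with the reference")
  structure(list(factors = factors,
                 effective_lib_size = lib_size * factors),
            class = "norm_factors")
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values: the reference sample is the one whose
#' 75th-percentile count fraction is closest to the mean of those; per
#' sample, library-size-adjusted log2 ratios (M) against the reference are
#' doubly trimmed (30\% on M, 5\% on the average log abundance A) and
#' combined by an inverse-asymptotic-variance weighted mean; factors are
#' standardized so their product is one. Computed through edgeR's
#' `calcNormFactors`.
#'
#' @param m Count matrix with at least 2 samples.
#' @return A `norm_factors` list with per-sample `factors` (product 1) and
#'   `effective_lib_size` (library size times factor).
#' @export
tmm_factors <- function(m) {
  check_counts(m)
  if (ncol(m) < 2L) stop("TMM needs at least 2 samples")
  f <- edgeR::calcNormFactors(m, method = "TMM")
  new_norm_factors(stats::setNames(f, colnames(m)), colSums(m))
}

#' RLE (median-of-ratios) scaling factors
#'
#' The pseudo-reference is the per-gene geometric mean over samples
#' (genes with any zero count are excluded); each sample's factor is the
#' median over genes of count / pseudo-reference, standardized so the
#' factors multiply to one.
#'
#' @param m Count matrix with at least one gene expressed in every sample.
#' @return A `norm_factors` list, as for [tmm_factors()].
#' @export
rle_factors <- function(m) {
  check_counts(m)
  pos <- rowSums(m == 0) == 0L
  if (!any(pos))
    stop("RLE: no gene has nonzero counts in all samples")
  sub <- m[pos, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  f <- apply(sub / ref, 2L, stats::median)
  f <- f / exp(mean(log(f)))
  new_norm_factors(stats::setNames(f, colnames(m)), colSums(m))
}

#' Apply scaling factors to an expression matrix
#'
#' Divides each column by its factor, i.e. rescales the values as if the
#' library sizes had been the effective library sizes. All-one factors leave
#' the matrix unchanged.
#'
#' @param m Expression matrix.
#' @param nf A `norm_factors` object from [tmm_factors()] or [rle_factors()].
#' @export
apply_factors <- function(m, nf) {
  if (length(nf$factors) != ncol(m))
    stop("factor length does not match the number of samples")
  sweep(m, 2L, nf$factors, "/")
}

#' Fit the parametric dispersion trend for the VST
#'
#' On size-factor-normalized counts (RLE factors; library-size factors when
#' RLE is undefined) each gene's method-of-moments dispersion is
#' `max(0, (var - mu) / mu^2)`. The trend `alpha(mu) = a0 + a1 / mu`
#' (asymptotic dispersion plus an extra-Poisson term) is fitted over genes
#' with positive dispersion by least squares with two rounds of outlier
#' down-weighting (residuals beyond 3 robust SD get weight 0); the fit is
#' seedless and deterministic. With fewer than 10 positive-dispersion genes
#' the fit falls back to a plain `log2(x + 1)` transform, with a warning.
#'
#' @param m Count matrix (>= 10 genes, >= 3 samples recommended).
#' @return A `vst_fit` list with `a0`, `a1`, `size_factors` and `fallback`.
#' @export
vst_fit <- function(m) {
  check_counts(m)
  sf <- tryCatch(rle_factors(m)$factors, error = function(e) {
    lib <- colSums(m)
    lib / exp(mean(log(lib)))
  })
  norm <- sweep(m, 2L, sf, "/")
  mu <- rowMeans(norm)
  v <- row_vars(norm)
  disp <- pmax(0, (v - mu) / mu^2)
  use <- disp > 0 & mu > 0 & is.finite(disp)
  if (sum(use) < 10L) {
    warning("fewer than 10 positive-dispersion genes; ",
            "falling back to log2(x + 1)")
    return(structure(list(a0 = NA_real_, a1 = NA_real_, size_factors = sf,
                          fallback = TRUE), class = "vst_fit"))
  }
  x <- 1 / mu[use]
  y <- disp[use]
  w <- rep(1, length(y))
  co <- c(mean(y), 0)
  for (round in 1:3) {
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    co <- fit$coefficients
    r <- y - (co[1L] + co[2L] * x)
    s <- stats::mad(r)
    if (s <= 0) break
    w <- as.numeric(abs(r) <= 3 * s)
    if (all(w == 0)) break
  }
  structure(list(a0 = max(co[1L], 1e-8), a1 = max(co[2L], 0),
                 size_factors = sf, fallback = FALSE), class = "vst_fit")
}

#' Closed-form variance-stabilizing transform
#'
#' For the fitted negative-binomial dispersion trend the transform
#' `log2((1 + a1 + 2*a0*x + 2*sqrt(a0*x*(1 + a1 + a0*x))) / (4*a0))`
#' is strictly monotone in `x` and approaches `log2(x)` for large `x`
#' (slope 1 on the log2 scale). A fallback fit applies `log2(x + 1)`.
#'
#' @param m Matrix of (normalized) non-negative values.
#' @param fit A `vst_fit`.
#' @export
vst_apply <- function(m, fit) {
  if (isTRUE(fit$fallback)) return(log2(m + 1))
  a0 <- fit$a0
  a1 <- fit$a1
  log2((1 + a1 + 2 * a0 * m + 2 * sqrt(a0 * m * (1 + a1 + a0 * m))) /
         (4 * a0))
}

#' Fit and apply the VST to a count matrix
#'
#' Convenience wrapper: fits the dispersion trend on `m`, divides by the same
#' size factors, and applies the closed-form transform.
#'
#' @param m Count matrix.
#' @export
vst_transform <- function(m) {
  fit <- vst_fit(m)
  vst_apply(sweep(m, 2L, fit$size_factors, "/"), fit)
}

#' Quantile normalization
#'
#' Replaces each column's values by the across-column mean of order
#' statistics at each rank; ties within a column receive the mean of their
#' implied values. Afterwards every column carries the same multiset of
#' values; the map is idempotent. Computed through limma's
#' `normalizeQuantiles(ties = TRUE)`.
#'
#' @param m Expression matrix with at least 2 samples.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2L) stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(as.matrix(m), ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Apply a normalization method within the pipeline
#'
#' Factors and dispersions are always estimated on the count matrix; how the
#' result reaches the expression matrix depends on the method: `NoNorm`
#' returns `m` unchanged; `TMM`/`RLE` rescale the columns of `m` by factors
#' estimated on `counts`; `QN` quantile-normalizes `m`; `VST` is fitted on
#' `counts`, applied to the size-factor-normalized counts, and its output
#' replaces `m` (the data-type tag is bookkeeping only), which keeps the
#' count-based variance model valid regardless of the upstream data type.
#'
#' @param m Expression matrix at the current pipeline stage.
#' @param counts The (pseudocounted) count matrix the factors are estimated
#'   from.
#' @param method One of [norm_methods()].
#' @export
apply_normalization <- function(m, counts, method) {
  method <- match.arg(method, norm_methods())
  switch(method,
    NoNorm = m,
    TMM = apply_factors(m, tmm_factors(counts)),
    RLE = apply_factors(m, rle_factors(counts)),
    QN = quantile_normalize(m),
    VST = vst_transform(counts))
}
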