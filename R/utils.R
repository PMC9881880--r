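# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` runs `code` as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Unbiased per-row sample variance of a numeric matrix.
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(0, nrow(m)))
  rowSums((m - rowMeans(m))^2) / (n - 1L)
}

# Validate a genes-by-samples numeric matrix of non-negative values.
check_counts <- function(m, what = "count matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(m)))
    stop(what, " must have gene symbols as rownames", call. = FALSE)
  if (anyNA(m))
    stop(what, " contains missing values", call. = FALSE)
  if (any(m < 0))
    stop(what, " contains negative values", call. = FALSE)
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
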