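#' The six basic data types
#'
#' Raw counts, CPM and TPM, each with and without a subsequent log2:
#' `raw`, `l2`, `cpm`, `l2cpm`, `tpm`, `l2tpm`.
#'
#' @return Character vector of the six data-type names.
#' @export
data_types <- function() c("raw", "l2", "cpm", "l2cpm", "tpm", "l2tpm")

#' Add the global pseudocount
#'
#' Adds `offset` to every cell, once per pipeline run, before any other
#' transformation; the returned matrix carries the attribute
#' `pseudocount_added` so downstream code will not add it again. The offset
#' guards the log2 (and the geometric means inside RLE/VST) against zeros
#' and, together with the default filtering, damps the very-high-variance
#' genes that can otherwise dominate an inferred network as spurious hubs.
#'
#' @param m Count matrix.
#' @param offset Non-negative pseudocount, default 1.
#' @export
add_pseudocount <- function(m, offset = 1) {
  if (offset < 0) stop("'offset' must be non-negative")
  if (isTRUE(attr(m, "pseudocount_added"))) return(m)
  out <- m + offset
  if (offset > 0) attr(out, "pseudocount_added") <- TRUE
  out
}

#' Counts per million
#'
#' Each column is scaled to sum to one million: `x * 1e6 / colSum`.
#'
#' @param m Matrix with strictly positive column sums.
#' @export
cpm_transform <- function(m) {
  lib <- colSums(m)
  if (any(lib == 0))
    stop("zero column sum in sample(s): ",
         paste(colnames(m)[lib == 0], collapse = ", "))
  sweep(m, 2L, lib, "/") * 1e6
}

#' Transcripts per million
#'
#' Counts are first divided by gene length in kilobases, then each column of
#' rates is scaled to sum to one million. With equal lengths for all genes
#' TPM coincides with CPM.
#'
#' @param m Count matrix with gene rownames.
#' @param lengths Named numeric vector of gene lengths in bases.
#' @export
tpm_transform <- function(m, lengths) {
  if (is.null(lengths)) stop("TPM requires gene lengths")
  missing <- setdiff(rownames(m), names(lengths))
  if (length(missing))
    stop("missing gene length for: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ...")
  len <- lengths[rownames(m)]
  if (any(len <= 0)) stop("gene lengths must be positive")
  rate <- m / (len / 1000)
  sweep(rate, 2L, colSums(rate), "/") * 1e6
}

#' Elementwise log2
#'
#' Errors on non-positive values, which signal that the pseudocount was
#' skipped upstream.
#'
#' @param m Matrix of strictly positive values.
#' @export
log2_transform <- function(m) {
  if (any(m <= 0))
    stop("log2 on non-positive values; was the pseudocount skipped?")
  log2(m)
}

#' Apply a basic data-type transformation
#'
#' Adds the pseudocount (once; a matrix already carrying the
#' `pseudocount_added` attribute is left as-is) and dispatches on the data
#' type: `raw` is the pseudocounted matrix itself, `l2` its log2, `cpm`/`tpm`
#' the per-million scalings of it, `l2cpm`/`l2tpm` their log2.
#'
#' @param m Count matrix.
#' @param datatype One of [data_types()].
#' @param lengths Gene lengths in bases, required for `tpm`/`l2tpm`.
#' @param pseudocount Offset added before transforming, default 1.
#' @export
apply_datatype <- function(m, datatype, lengths = NULL, pseudocount = 1) {
  datatype <- match.arg(datatype, data_types())
  pm <- add_pseudocount(m, pseudocount)
  switch(datatype,
    raw = pm,
    l2 = log2_transform(pm),
    cpm = cpm_transform(pm),
    l2cpm = log2_transform(cpm_transform(pm)),
    tpm = tpm_transform(pm, lengths),
    l2tpm = log2_transform(tpm_transform(pm, lengths)))
}
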