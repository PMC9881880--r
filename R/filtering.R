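#' Drop unannotated genes
#'
#' Removes rows whose symbol is missing: `NA`, the literal string "NA", or
#' empty after whitespace trimming. Row order is preserved.
#'
#' @param m Count matrix with gene rownames.
#' @return The matrix without unannotated rows; attribute `n_removed` holds
#'   the number of dropped rows.
#' @export
drop_unannotated <- function(m) {
  check_counts(m)
  sym <- trimws(rownames(m))
  bad <- is.na(sym) | sym == "NA" | sym == ""
  if (all(bad))
    stop("all genes are unannotated; nothing left after cleaning")
  out <- m[!bad, , drop = FALSE]
  attr(out, "n_removed") <- sum(bad)
  out
}

#' Collapse duplicated gene symbols
#'
#' For each symbol occurring more than once, only the row with the highest
#' sample variance (computed on the values as given, i.e. raw counts) is
#' kept; ties are broken in favour of the first occurrence. Surviving rows
#' keep their original relative order.
#'
#' @param m Count matrix with gene rownames.
#' @return Matrix with unique rownames; attribute `n_removed` counts the
#'   dropped duplicate rows.
#' @export
collapse_duplicates <- function(m) {
  check_counts(m)
  sym <- rownames(m)
  if (!anyDuplicated(sym)) {
    attr(m, "n_removed") <- 0L
    return(m)
  }
  v <- row_vars(m)
  keep <- logical(nrow(m))
  for (s in unique(sym)) {
    idx <- which(sym == s)
    keep[idx[which.max(v[idx])]] <- TRUE
  }
  out <- m[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Low-expression filter on the CPM scale
#'
#' Removes a gene when any of three rules, evaluated on CPM computed from the
#' raw column sums of `m` (no pseudocount), fires:
#' \enumerate{
#'   \item the share of samples with CPM at or below `low_cpm` is at least
#'     `low_frac` (default: CPM <= 0.1 in >= 20\% of samples);
#'   \item the maximum CPM over samples is at or below `max_cpm` (default 0.7);
#'   \item the mean CPM over samples is below `mean_cpm` (default 0.35).
#' }
#' Removals are attributed to the first matching rule. At a library size of
#' 20 million reads the 0.1-CPM cut corresponds to 2 raw counts (7.5 counts
#' at 75 million), so the thresholds are meaningful only on raw counts.
#'
#' @param m Raw count matrix.
#' @param low_cpm,low_frac,max_cpm,mean_cpm Rule thresholds as above.
#' @return List with `counts` (the filtered matrix) and `report`, a
#'   `filter_report` list itemizing removals per rule.
#' @export
expression_filter <- function(m, low_cpm = 0.1, low_frac = 0.20,
                              max_cpm = 0.7, mean_cpm = 0.35) {
  check_counts(m)
  if (ncol(m) < 1L) stop("need at least one sample")
  lib <- colSums(m)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(m)[lib == 0], collapse = ", "))
  cpmv <- sweep(m, 2L, lib, "/") * 1e6
  r1 <- rowMeans(cpmv <= low_cpm) >= low_frac
  r2 <- apply(cpmv, 1L, max) <= max_cpm
  r3 <- rowMeans(cpmv) < mean_cpm
  rule <- ifelse(r1, 1L, ifelse(r2, 2L, ifelse(r3, 3L, 0L)))
  out <- m[rule == 0L, , drop = FALSE]
  report <- filter_report(
    n_input = nrow(m),
    n_removed_low_frac = sum(rule == 1L),
    n_removed_low_max = sum(rule == 2L),
    n_removed_low_mean = sum(rule == 3L),
    n_output = nrow(out))
  list(counts = out, report = report)
}

filter_report <- function(n_input = 0L, n_removed_unannotated = 0L,
                          n_removed_duplicates = 0L, n_removed_low_frac = 0L,
                          n_removed_low_max = 0L, n_removed_low_mean = 0L,
                          n_output = 0L) {
  rep <- list(n_input = n_input,
              n_removed_unannotated = n_removed_unannotated,
              n_removed_duplicates = n_removed_duplicates,
              n_removed_low_frac = n_removed_low_frac,
              n_removed_low_max = n_removed_low_max,
              n_removed_low_mean = n_removed_low_mean,
              n_output = n_output)
  removed <- sum(unlist(rep[grep("^n_removed", names(rep))]))
  if (rep$n_input - removed != rep$n_output)
    stop("filter report does not reconcile: ", rep$n_input, " - ", removed,
         " != ", rep$n_output)
  structure(rep, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter report:", x$n_input, "genes in,", x$n_output, "out\n")
  cat("  unannotated:", x$n_removed_unannotated,
      " duplicates:", x$n_removed_duplicates, "\n")
  cat("  low-expression (frac/max/mean):", x$n_removed_low_frac, "/",
      x$n_removed_low_max, "/", x$n_removed_low_mean, "\n")
  invisible(x)
}

#' Full gene-cleaning pipeline
#'
#' Runs [drop_unannotated()], [collapse_duplicates()] and
#' [expression_filter()] in that order and combines their tallies into one
#' reconciled [filter_report].
#'
#' @inheritParams expression_filter
#' @return List with `counts` and `report`.
#' @export
filter_counts <- function(m, low_cpm = 0.1, low_frac = 0.20,
                          max_cpm = 0.7, mean_cpm = 0.35) {
  n_in <- nrow(m)
  m1 <- drop_unannotated(m)
  n_na <- attr(m1, "n_removed")
  m2 <- collapse_duplicates(m1)
  n_dup <- attr(m2, "n_removed")
  ex <- expression_filter(m2, low_cpm = low_cpm, low_frac = low_frac,
                          max_cpm = max_cpm, mean_cpm = mean_cpm)
  report <- filter_report(
    n_input = n_in,
    n_removed_unannotated = n_na,
    n_removed_duplicates = n_dup,
    n_removed_low_frac = ex$report$n_removed_low_frac,
    n_removed_low_max = ex$report$n_removed_low_max,
    n_removed_low_mean = ex$report$n_removed_low_mean,
    n_output = nrow(ex$counts))
  list(counts = ex$counts, report = report)
}

#' Variance filter
#'
#' Removes the `floor(drop_fraction * n_genes)` genes with the lowest
#' variance; variance is computed on the CPM scale of the input so that
#' sequencing depth does not confound the cross-gene comparison. Ties at the
#' removal boundary keep the earlier row. Used to compare default filtering
#' against an additional "high variance" (HV) gene set.
#'
#' @param m Count matrix (at least 5 genes).
#' @param drop_fraction Fraction of genes to drop, in `[0, 1)`; default 0.2
#'   (the bottom fifth).
#' @return The filtered matrix, original row order preserved.
#' @export
variance_filter <- function(m, drop_fraction = 0.20) {
  check_counts(m)
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("'drop_fraction' must be in [0, 1)")
  if (nrow(m) < 5L) stop("need at least 5 genes")
  n_drop <- floor(drop_fraction * nrow(m))
  if (n_drop == 0L) return(m)
  lib <- colSums(m)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(m)[lib == 0], collapse = ", "))
  v <- row_vars(sweep(m, 2L, lib, "/") * 1e6)
  # ascending variance; among ties the later row sorts first, so it is dropped
  drop <- order(v, -seq_along(v))[seq_len(n_drop)]
  m[-drop, , drop = FALSE]
}
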