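#' Enumerate the preprocessing grid
#'
#' Full cross-product of data type (6) x normalization (5) x copula
#' transform on/off (2) x estimator (5) = 300 combinations, in a stable
#' deterministic order, minus any exclusions. Excluding the Chao-Shen
#' estimator and quantile normalization — the consistently poor performers —
#' leaves the 192-combination grid used for rank aggregation.
#'
#' @param exclude_estimators,exclude_normalizations,exclude_datatypes
#'   Character vectors of options to drop (must name known options).
#' @return Data.frame with columns `estimator`, `ct` (logical),
#'   `normalization`, `datatype` and the combination `label`
#'   (`{estimator}_{CT|noCT}_{norm}_{datatype}`).
#' @export
enumerate_grid <- function(exclude_estimators = NULL,
                           exclude_normalizations = NULL,
                           exclude_datatypes = NULL) {
  check_known <- function(x, known, what) {
    bad <- setdiff(x, known)
    if (length(bad))
      stop("unknown ", what, ": ", paste(bad, collapse = ", "))
    setdiff(known, x)
  }
  est <- check_known(exclude_estimators, estimators(), "estimator")
  nrm <- check_known(exclude_normalizations, norm_methods(), "normalization")
  dtt <- check_known(exclude_datatypes, data_types(), "datatype")
  grid <- expand.grid(datatype = dtt, normalization = nrm,
                      ct = c(TRUE, FALSE), estimator = est,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("estimator", "ct", "normalization", "datatype")]
  grid$label <- combo_label(grid$estimator, grid$ct, grid$normalization,
                            grid$datatype)
  rownames(grid) <- NULL
  grid
}

#' @rdname enumerate_grid
#' @param estimator,ct,normalization,datatype Combination components.
#' @export
combo_label <- function(estimator, ct, normalization, datatype) {
  paste(estimator, ifelse(ct, "CT", "noCT"), normalization, datatype,
        sep = "_")
}

#' Run one preprocessing combination end to end
#'
#' Executes the whole pipeline on an already-filtered count matrix:
#' pseudocount, data-type transform, normalization (factors estimated on the
#' pseudocounted counts), optional copula transform, association estimation,
#' thresholding, network inference, and evaluation against the reference
#' over the universe of the input genes. Errors are re-raised with the
#' failing stage named.
#'
#' @param counts Filtered count matrix.
#' @param combo One row of [enumerate_grid()] (or a list with the same
#'   fields).
#' @param gni_cfg A [gni_config()] naming the inference algorithm and
#'   thresholding.
#' @param ref Reference [gene_network()].
#' @param lengths Gene lengths in bases (needed for TPM data types).
#' @param dataset Dataset label recorded in the output.
#' @param bins,spline_order Estimator settings for the MI estimators.
#' @param universe Optional precomputed [make_universe()]; defaults to the
#'   genes of `counts`.
#' @return One-row data.frame performance record with columns `combination`
#'   (`{gni}.{label}`), `gni`, `dataset`, `precision`, `tp`, `predicted`,
#'   `p_value`.
#' @export
run_combo <- function(counts, combo, gni_cfg, ref, lengths = NULL,
                      dataset = "D1", bins = 10L, spline_order = 2L,
                      universe = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  pm <- stage("pseudocount", add_pseudocount(counts))
  em <- stage("datatype", apply_datatype(pm, combo$datatype, lengths))
  em <- stage("normalization",
              apply_normalization(em, pm, combo$normalization))
  if (isTRUE(combo$ct)) em <- stage("copula", copula_transform(em))
  ecfg <- estimator_config(combo$estimator, bins = bins,
                           spline_order = spline_order)
  A <- stage("association", association_matrix(em, ecfg))
  thr <- stage("threshold",
               significance_threshold(A, em, gni_cfg, config = ecfg))
  net <- stage("inference",
               infer_network(A, gni_cfg$algorithm, thr, gni_cfg$dpi_eps))
  if (is.null(universe)) universe <- make_universe(rownames(counts), ref)
  ev <- stage("evaluation", evaluate_network(net, universe))
  data.frame(
    combination = paste0(gni_prefix[[gni_cfg$algorithm]], ".", combo$label),
    gni = gni_cfg$algorithm, dataset = dataset,
    precision = ev$precision, tp = ev$tp, predicted = ev$predicted,
    p_value = ev$p_value, stringsAsFactors = FALSE)
}

#' Run the full benchmark grid
#'
#' One record per (dataset x combination x algorithm). Individual failures
#' (e.g. an undefined precision for an empty prediction) are recorded as NA
#' rows with a warning and the run continues. Records whose key appears in
#' `done` are skipped, which makes interrupted runs resumable.
#'
#' @param counts_list Named list of filtered count matrices, one per dataset.
#' @param combos Data.frame from [enumerate_grid()].
#' @param gni Character vector of algorithms to run.
#' @param ref Reference [gene_network()].
#' @param lengths Gene lengths in bases.
#' @param gni_cfg Template [gni_config()]; its algorithm field is overridden
#'   per run.
#' @param done Optional previous records data.frame; completed
#'   (combination, dataset) cells are not recomputed.
#' @inheritParams run_combo
#' @return Records data.frame (one row per run).
#' @export
run_grid <- function(counts_list, combos, gni = gni_algorithms(), ref,
                     lengths = NULL, gni_cfg = gni_config(),
                     bins = 10L, spline_order = 2L, done = NULL) {
  if (length(counts_list) < 1L) stop("need at least one dataset")
  if (is.null(names(counts_list)))
    names(counts_list) <- paste0("D", seq_along(counts_list))
  done_keys <- if (is.null(done)) character(0)
               else paste(done$combination, done$dataset)
  out <- vector("list", 0L)
  for (ds in names(counts_list)) {
    universe <- make_universe(rownames(counts_list[[ds]]), ref)
    for (ci in seq_len(nrow(combos))) {
      combo <- combos[ci, ]
      for (alg in gni) {
        cfg <- gni_cfg
        cfg$algorithm <- match.arg(alg, gni_algorithms())
        key <- paste0(gni_prefix[[cfg$algorithm]], ".", combo$label, " ", ds)
        if (key %in% done_keys) next
        rec <- tryCatch(
          run_combo(counts_list[[ds]], combo, cfg, ref, lengths,
                    dataset = ds, bins = bins, spline_order = spline_order,
                    universe = universe),
          error = function(e) {
            warning("record ", key, " failed: ", conditionMessage(e),
                    call. = FALSE)
            data.frame(
              combination = paste0(gni_prefix[[cfg$algorithm]], ".",
                                   combo$label),
              gni = cfg$algorithm, dataset = ds, precision = NA_real_,
              tp = NA_integer_, predicted = NA_integer_,
              p_value = NA_real_, stringsAsFactors = FALSE)
          })
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  res <- do.call(rbind, out)
  if (!is.null(done)) res <- rbind(done[, record_columns], res)
  rownames(res) <- NULL
  res
}

#' Rank combinations across datasets
#'
#' Within each dataset (and, by default, within each inference algorithm so
#' the algorithm's own effect drops out) combinations are ranked by
#' descending precision with ties sharing the minimum rank (best rank 1).
#' Ranks are then aggregated per combination across datasets into median,
#' mean, best and worst rank; the output is sorted ascending by median rank,
#' ties broken by mean rank then label. Every combination must be present in
#' every dataset; holes are an error.
#'
#' @param records Records data.frame from [run_grid()].
#' @param per_gni Rank within each algorithm separately (default TRUE).
#' @return Data.frame with `combination`, `median_rank`, `mean_rank`,
#'   `best_rank`, `worst_rank`, plus one `rank_<dataset>` column per dataset.
#' @export
rank_combos <- function(records, per_gni = TRUE) {
  if (anyNA(records$precision)) {
    bad <- records[is.na(records$precision), ]
    stop("records with missing precision: ",
         paste(utils::head(paste(bad$combination, bad$dataset), 5L),
               collapse = "; "))
  }
  datasets <- unique(records$dataset)
  group <- if (per_gni) paste(records$dataset, records$gni)
           else records$dataset
  records$rank <- stats::ave(-records$precision, group,
                             FUN = function(x) rank(x, ties.method = "min"))
  wide <- stats::reshape(
    records[, c("combination", "dataset", "rank")],
    idvar = "combination", timevar = "dataset", direction = "wide")
  rank_cols <- paste0("rank.", datasets)
  holes <- which(is.na(as.matrix(wide[, rank_cols, drop = FALSE])),
                 arr.ind = TRUE)
  if (nrow(holes))
    stop("missing combination-dataset cells: ",
         paste(utils::head(paste(wide$combination[holes[, 1L]],
                                 datasets[holes[, 2L]]), 5L),
               collapse = "; "))
  rk <- as.matrix(wide[, rank_cols, drop = FALSE])
  out <- data.frame(
    combination = wide$combination,
    median_rank = apply(rk, 1L, stats::median),
    mean_rank = rowMeans(rk),
    best_rank = apply(rk, 1L, min),
    worst_rank = apply(rk, 1L, max),
    stringsAsFactors = FALSE)
  colnames(wide)[match(rank_cols, colnames(wide))] <-
    paste0("rank_", datasets)
  out <- cbind(out, wide[, paste0("rank_", datasets), drop = FALSE])
  out <- out[order(out$median_rank, out$mean_rank, out$combination), ]
  rownames(out) <- NULL
  out
}

#' Precision as a function of sample size
#'
#' Subsamples columns without replacement (seeded) and reruns one
#' preprocessing combination per size and algorithm. Replicates use nested
#' subsamples — each smaller sample set is a subset of the larger one within
#' a replicate — which reduces variance between adjacent sizes.
#'
#' @param counts Filtered count matrix.
#' @param combo One grid row.
#' @param gni Character vector of algorithms.
#' @param sizes Strictly increasing sample counts, each at most
#'   `ncol(counts)`; sizes below 8 trigger a warning.
#' @param reps Independent subsample replicates per size, default 3.
#' @param seed Integer seed; replicate r draws with `seed + r`.
#' @inheritParams run_combo
#' @return Long data.frame with columns `size`, `gni`, `rep`, `precision`.
#' @export
sample_size_curve <- function(counts, combo, gni = "c3net", sizes,
                              reps = 3L, seed = 1L, ref, lengths = NULL,
                              gni_cfg = gni_config(), bins = 10L,
                              spline_order = 2L) {
  sizes <- as.integer(sizes)
  if (is.unsorted(sizes, strictly = TRUE))
    stop("'sizes' must be strictly increasing")
  if (max(sizes) > ncol(counts))
    stop("largest size exceeds the available ", ncol(counts), " samples")
  if (any(sizes < 8L))
    warning("sizes below 8 samples give very unstable associations")
  universe <- make_universe(rownames(counts), ref)
  out <- vector("list", 0L)
  for (r in seq_len(reps)) {
    perm <- with_seed(seed + r, sample.int(ncol(counts)))
    for (s in sizes) {
      sub <- counts[, perm[seq_len(s)], drop = FALSE]
      for (alg in gni) {
        cfg <- gni_cfg
        cfg$algorithm <- match.arg(alg, gni_algorithms())
        prec <- tryCatch(
          run_combo(sub, combo, cfg, ref, lengths, bins = bins,
                    spline_order = spline_order,
                    universe = universe)$precision,
          error = function(e) NA_real_)
        out[[length(out) + 1L]] <- data.frame(
          size = s, gni = cfg$algorithm, rep = r, precision = prec,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default-versus-variance-filtered comparison
#'
#' Runs the grid twice per dataset: on the input as given and on its
#' variance-filtered version (bottom fifth of genes by CPM-scale variance
#' removed), the latter labeled `<dataset>HV` ("high variance"). The paired
#' records allow a direct comparison of the two filtering policies.
#'
#' @inheritParams run_grid
#' @param drop_fraction Fraction of lowest-variance genes removed for the HV
#'   arm, default 0.2.
#' @return Records data.frame with `2 x combinations x algorithms` rows per
#'   dataset.
#' @export
variance_filter_comparison <- function(counts_list, combos,
                                       gni = gni_algorithms(), ref,
                                       lengths = NULL,
                                       gni_cfg = gni_config(),
                                       drop_fraction = 0.20, bins = 10L,
                                       spline_order = 2L) {
  if (is.null(names(counts_list)))
    names(counts_list) <- paste0("D", seq_along(counts_list))
  both <- list()
  for (ds in names(counts_list)) {
    both[[ds]] <- counts_list[[ds]]
    both[[paste0(ds, "HV")]] <- variance_filter(counts_list[[ds]],
                                                drop_fraction)
  }
  run_grid(both, combos, gni, ref, lengths, gni_cfg,
           bins = bins, spline_order = spline_order)
}
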