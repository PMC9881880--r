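#' Read a gene-by-sample count matrix
#'
#' Expects a delimited text file with gene symbols in the first column and one
#' column per sample with a header row of sample IDs. The delimiter is sniffed
#' from the header (tab preferred over comma) unless given explicitly.
#' Duplicate gene symbols are retained (collapse them with
#' [collapse_duplicates()]); negative, missing or non-numeric cells are
#' rejected with the offending location named.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter; `NULL` (default) sniffs tab vs comma.
#' @return A numeric matrix with gene symbols as rownames and sample IDs as
#'   colnames. The logical attribute `duplicated_symbols` flags rows whose
#'   symbol occurs more than once.
#' @export
read_counts <- function(path, delimiter = NULL) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L)
    stop("'", path, "' is empty")
  if (is.null(delimiter))
    delimiter <- if (grepl("\t", header)) "\t" else ","
  dt <- data.table::fread(path, sep = delimiter, header = TRUE,
                          data.table = FALSE, colClasses = list(character = 1))
  if (ncol(dt) < 2L)
    stop("malformed header in '", path,
         "': need a gene-symbol column plus at least one sample column")
  samples <- colnames(dt)[-1L]
  if (anyDuplicated(samples))
    stop("malformed header in '", path, "': duplicated sample IDs: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (nrow(dt) == 0L)
    stop("'", path, "' contains no gene rows")
  symbols <- trimws(as.character(dt[[1L]]))
  body <- dt[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop("non-numeric cell in '", path, "' at row ", bad,
           " (gene '", symbols[bad], "'), column '", samples[j], "'")
    }
  }
  m <- as.matrix(body)
  rownames(m) <- symbols
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing value in '", path, "' at gene '", symbols[idx[1L]],
         "', sample '", samples[idx[2L]], "'")
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative value in '", path, "' at gene '", symbols[idx[1L]],
         "', sample '", samples[idx[2L]], "'")
  }
  attr(m, "duplicated_symbols") <- symbols %in% symbols[duplicated(symbols)]
  m
}

#' Write a count or expression matrix as TSV
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param symbol_col Name for the gene-symbol column.
#' @export
write_counts <- function(m, path, symbol_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- symbol_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an undirected edge list
#'
#' Accepts two-column TSV/CSV edge lists (optional third numeric column taken
#' as weight) and SIF (`node relation node`, detected when the file has three
#' columns whose third is non-numeric). An optional header row whose first two
#' fields are `from`/`to` (any case) is skipped. Self-loops and duplicate
#' pairs in either orientation are dropped; the counts of dropped rows are
#' available on the returned network as attributes `n_self_dropped` and
#' `n_dup_dropped`.
#'
#' @param path Path to the edge-list file.
#' @return A [gene_network()].
#' @export
read_edge_list <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(trimws(first)))
    stop("edge list '", path, "' is empty")
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else " "
  dt <- data.table::fread(path, sep = sep, header = FALSE, fill = TRUE,
                          data.table = FALSE, colClasses = "character")
  f2 <- trimws(tolower(strsplit(first, sep, fixed = TRUE)[[1L]]))
  if (length(f2) >= 2L && identical(f2[1:2], c("from", "to")))
    dt <- dt[-1L, , drop = FALSE]
  if (nrow(dt) == 0L)
    stop("edge list '", path, "' has no edges")
  if (ncol(dt) < 2L)
    stop("edge list '", path, "': line 1 has fewer than 2 fields")
  bad <- which(!nzchar(trimws(dt[[2L]])) | is.na(dt[[2L]]))
  if (length(bad))
    stop("edge list '", path, "': line ", bad[1L], " has fewer than 2 fields")
  from <- dt[[1L]]
  to <- dt[[2L]]
  weight <- NULL
  if (ncol(dt) >= 3L) {
    third <- suppressWarnings(as.numeric(dt[[3L]]))
    if (ncol(dt) == 3L && anyNA(third) && all(nzchar(trimws(dt[[3L]])))) {
      # SIF: the middle column is the relation type, the third the target node
      to <- dt[[3L]]
    } else if (!anyNA(third)) {
      weight <- third
    }
  }
  gene_network(from, to, weight = weight)
}

#' Write a network as a two/three-column TSV
#'
#' Round-trips losslessly through [read_edge_list()]; an empty network yields
#' a header-only file.
#'
#' @param net A [gene_network()].
#' @param path Output path.
#' @export
write_network <- function(net, path) {
  cols <- intersect(c("from", "to", "weight"), colnames(net$edges))
  utils::write.table(net$edges[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

record_columns <- c("combination", "gni", "dataset",
                    "precision", "tp", "predicted", "p_value")

#' Read and write performance-record tables
#'
#' Records are one row per (dataset, preprocessing combination, inference
#' algorithm) with columns `combination`, `gni`, `dataset`, `precision`,
#' `tp`, `predicted`, `p_value` — the same quantities as the headline
#' performance tables (precision TP/(TP+FP), overlap TP, predicted TP+FP,
#' overlap-test p-value).
#'
#' @param records A data.frame of performance records.
#' @param path File path.
#' @return `read_records()` returns the records data.frame.
#' @export
write_records <- function(records, path) {
  missing <- setdiff(record_columns, colnames(records))
  if (length(missing))
    stop("records table lacks columns: ", paste(missing, collapse = ", "))
  utils::write.table(records[, record_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  missing <- setdiff(record_columns, colnames(df))
  if (length(missing))
    stop("records file '", path, "' lacks columns: ",
         paste(missing, collapse = ", "))
  df
}

#' Read a gene-length annotation table
#'
#' Two-column TSV (symbol, length in bases), with or without a header.
#'
#' @param path Path to the annotation file.
#' @return Named numeric vector of lengths in bases.
#' @export
read_gene_lengths <- function(path) {
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(dt) < 2L)
    stop("gene-length table '", path, "' needs two columns (symbol, length)")
  len <- suppressWarnings(as.numeric(dt[[2L]]))
  if (anyNA(len))
    stop("gene-length table '", path, "' has non-numeric lengths at line ",
         which(is.na(len))[1L])
  if (any(len <= 0))
    stop("gene-length table '", path, "' has non-positive lengths")
  stats::setNames(len, trimws(as.character(dt[[1L]])))
}
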