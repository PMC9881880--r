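#' Undirected gene network
#'
#' A `gene_network` is a self-loop-free set of unordered gene-symbol pairs,
#' stored canonically: within each edge the two symbols are sorted
#' lexicographically, edges are deduplicated regardless of orientation, and
#' rows are ordered by (from, to). Optional per-edge weights (association
#' scores) and signs (+1/-1, for correlation-based estimators) are carried
#' along; when duplicates are dropped the first occurrence wins.
#'
#' @param from,to Character vectors of gene symbols, one edge per element.
#' @param weight Optional numeric vector of edge weights.
#' @param sign Optional integer vector of edge signs (+1 or -1).
#' @return An object of class `gene_network`: a list with an `edges`
#'   data.frame (`from`, `to`, and optionally `weight`, `sign`) plus
#'   attributes `n_self_dropped` and `n_dup_dropped` recording what
#'   canonicalization removed.
#' @examples
#' net <- gene_network(c("B", "A", "C"), c("A", "B", "C"))
#' n_edges(net)  # (B,A) and (A,B) collapse; (C,C) is dropped
#' @export
gene_network <- function(from = character(), to = character(),
                         weight = NULL, sign = NULL) {
  from <- trimws(as.character(from))
  to <- trimws(as.character(to))
  if (length(from) != length(to))
    stop("'from' and 'to' must have the same length")
  a <- pmin(from, to)
  b <- pmax(from, to)
  self <- a == b
  key <- paste(a, b, sep = "\t")
  dup <- duplicated(key) & !self
  keep <- !self & !dup
  edges <- data.frame(from = a[keep], to = b[keep],
                      stringsAsFactors = FALSE)
  if (!is.null(weight)) edges$weight <- as.numeric(weight)[keep]
  if (!is.null(sign)) edges$sign <- as.integer(sign)[keep]
  o <- order(edges$from, edges$to)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges),
            n_self_dropped = sum(self),
            n_dup_dropped = sum(dup),
            class = "gene_network")
}

#' @rdname gene_network
#' @param net A `gene_network`.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname gene_network
#' @export
network_genes <- function(net) sort(unique(c(net$edges$from, net$edges$to)))

# Canonical "from\tto" key per edge, the unit of undirected comparison.
edge_keys <- function(net) paste(net$edges$from, net$edges$to, sep = "\t")

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", n_edges(x), "edges over",
      length(network_genes(x)), "genes\n")
  invisible(x)
}
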