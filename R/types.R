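#' Construct an expression matrix
#'
#' An expression matrix is a base numeric matrix with genes in rows and
#' samples in columns, carrying unique row (gene) and column (sample) names
#' and only finite values. All reconstructors take this shape.
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids,sample_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @return a validated numeric matrix of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop_netaggr("expression matrix needs gene and sample ids")
  }
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop_netaggr("id lengths do not match matrix dimensions")
  }
  check_unique_ids(gene_ids, "gene ids")
  check_unique_ids(sample_ids, "sample ids")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop_netaggr("non-finite expression value at gene '", gene_ids[bad[1]],
                 "', sample '", sample_ids[bad[2]], "'")
  }
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Construct a weighted undirected network
#'
#' A weighted network over genes `V` is a symmetric numeric matrix of edge
#' confidence scores with zero diagonal; a larger absolute score means a
#' stronger interaction and 0 means no interaction.
#'
#' @param scores square numeric matrix of edge scores.
#' @param gene_ids optional character vector of vertex names (defaults to
#'   the dimnames of `scores`).
#' @param symmetrize_tol asymmetries up to this absolute tolerance are
#'   averaged away; larger asymmetry is an error.
#' @return a symmetric matrix of class `weighted_network`.
#' @export
weighted_network <- function(scores, gene_ids = rownames(scores),
                             symmetrize_tol = 1e-8) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (nrow(scores) != ncol(scores)) {
    stop_netaggr("network score matrix must be square")
  }
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(scores)))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(scores)) {
    stop_netaggr("gene_ids length does not match matrix dimension")
  }
  check_unique_ids(gene_ids, "gene ids")
  if (!all(is.finite(scores))) stop_netaggr("network scores must be finite")
  asym <- max(abs(scores - t(scores)))
  if (asym > symmetrize_tol) {
    stop_netaggr("network matrix is asymmetric (max |w_ij - w_ji| = ",
                 format(asym), ")")
  }
  scores <- (scores + t(scores)) / 2
  diag(scores) <- 0
  dimnames(scores) <- list(gene_ids, gene_ids)
  class(scores) <- c("weighted_network", class(scores))
  scores
}

#' Construct a gold-standard network topology
#'
#' @param gene_ids character vector of vertex names.
#' @param edges two-column matrix or data.frame of gene-id pairs (undirected,
#'   no self-loops, no duplicates).
#' @return an object of class `true_network`: a list with `gene_ids` and a
#'   data.frame `edges` with columns `from`/`to` (from < to in gene order).
#' @export
true_network <- function(gene_ids, edges) {
  gene_ids <- as.character(gene_ids)
  check_unique_ids(gene_ids, "gene ids")
  edges <- as.data.frame(edges)[, 1:2]
  names(edges) <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  unknown <- setdiff(c(edges$from, edges$to), gene_ids)
  if (length(unknown)) {
    stop_netaggr("edge endpoints not in gene set: ",
                 paste(unknown, collapse = ", "))
  }
  if (any(edges$from == edges$to)) stop_netaggr("self-loops are not allowed")
  # canonical orientation: from precedes to in gene_ids order
  ord <- match(edges$from, gene_ids) > match(edges$to, gene_ids)
  tmp <- edges$from[ord]
  edges$from[ord] <- edges$to[ord]
  edges$to[ord] <- tmp
  if (anyDuplicated(paste(edges$from, edges$to))) {
    stop_netaggr("duplicate edges are not allowed")
  }
  rownames(edges) <- NULL
  structure(list(gene_ids = gene_ids, edges = edges), class = "true_network")
}

#' @export
as.matrix.weighted_network <- function(x, ...) as_plain_matrix(x)

#' @export
as.matrix.expression_matrix <- function(x, ...) as_plain_matrix(x)

#' @export
print.weighted_network <- function(x, ...) {
  k <- sum(abs(x[lower.tri(x)]) > 0)
  cat("<weighted_network> ", nrow(x), " genes, ", k,
      " nonzero of ", nrow(x) * (nrow(x) - 1) / 2, " pairs\n", sep = "")
  invisible(x)
}

#' @export
print.true_network <- function(x, ...) {
  cat("<true_network> ", length(x$gene_ids), " genes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x), " genes x ", ncol(x), " samples\n",
      sep = "")
  invisible(x)
}

# logical adjacency matrix of a true_network, in its gene order
truth_adjacency <- function(truth) {
  p <- length(truth$gene_ids)
  adj <- matrix(FALSE, p, p, dimnames = list(truth$gene_ids, truth$gene_ids))
  i <- match(truth$edges$from, truth$gene_ids)
  j <- match(truth$edges$to, truth$gene_ids)
  adj[cbind(i, j)] <- TRUE
  adj[cbind(j, i)] <- TRUE
  adj
}

# strip S3 class down to a plain matrix (internal convenience)
as_plain_matrix <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}
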