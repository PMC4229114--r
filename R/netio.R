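#' Read an expression matrix from a delimited text file
#'
#' Expects genes in rows and samples in columns: the first row holds sample
#' ids, the first column gene ids, and the body is strictly numeric (no
#' missing values). File order of genes and samples is preserved.
#'
#' @param path path to the file.
#' @param delimiter field delimiter (tab by default).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop_netaggr("file not found: ", path)
  df <- read.table(path, sep = delimiter, header = TRUE, row.names = NULL,
                   check.names = FALSE, colClasses = "character",
                   comment.char = "", quote = "")
  gene_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  body <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop_netaggr("cannot parse expression value '", body[bad[1], bad[2]],
                 "' at gene '", gene_ids[bad[1]], "', sample '",
                 sample_ids[bad[2]], "'")
  }
  expression_matrix(vals, gene_ids = gene_ids, sample_ids = sample_ids)
}

#' Write an expression matrix to a delimited text file
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @param delimiter field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, delimiter = "\t") {
  expr <- expression_matrix(as_plain_matrix(as.matrix(expr)))
  df <- data.frame(gene = rownames(expr), as_plain_matrix(expr),
                   check.names = FALSE)
  write_table_checked(df, path, delimiter)
  invisible(path)
}

#' Read a weighted network from an edge list or labeled square matrix
#'
#' The format is auto-detected: a file whose header row and first column
#' carry the same id set (and whose body is square) is read as a labeled
#' score matrix; otherwise the file must be a 3-column edge list
#' `gene_a, gene_b, score`. Edge-list rows set both `w[i,j]` and `w[j,i]`;
#' pairs not listed score 0. Conflicting duplicate pairs (same pair,
#' different score) and self-loops are errors. Square input asymmetric
#' beyond `1e-8` is an error; smaller asymmetry is symmetrized by averaging.
#'
#' @param path path to the file.
#' @param gene_ids optional ordered vertex set: the returned network is over
#'   exactly these genes, and ids in the file outside this set are an error.
#' @param delimiter field delimiter.
#' @return a [weighted_network()].
#' @export
read_network <- function(path, gene_ids = NULL, delimiter = "\t") {
  if (!file.exists(path)) stop_netaggr("file not found: ", path)
  df <- read.table(path, sep = delimiter, header = TRUE, row.names = NULL,
                   check.names = FALSE, colClasses = "character",
                   comment.char = "", quote = "")
  header_ids <- colnames(df)[-1]
  is_square <- ncol(df) == nrow(df) + 1 && nrow(df) > 0 &&
    setequal(df[[1]], header_ids)
  if (is_square) {
    return(read_network_matrix(df, gene_ids))
  }
  if (ncol(df) != 3) {
    stop_netaggr("expected a 3-column edge list or a labeled square matrix")
  }
  from <- df[[1]]
  to <- df[[2]]
  w <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(w)) stop_netaggr("cannot parse edge score '", df[[3]][which(is.na(w))[1]], "'")
  if (any(from == to)) {
    stop_netaggr("self-loop in edge list: ", from[which(from == to)[1]])
  }
  if (is.null(gene_ids)) gene_ids <- sort(unique(c(from, to)))
  unknown <- setdiff(c(from, to), gene_ids)
  if (length(unknown)) {
    stop_netaggr("edge genes not in gene set: ", paste(unknown, collapse = ", "))
  }
  key <- paste(pmin(from, to), pmax(from, to))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflicting <- vapply(unique(dup), function(k) {
      length(unique(w[key == k])) > 1
    }, logical(1))
    if (any(conflicting)) {
      stop_netaggr("conflicting duplicate pairs in edge list: ",
                   paste(unique(dup)[conflicting], collapse = "; "))
    }
    keep <- !duplicated(key)
    from <- from[keep]; to <- to[keep]; w <- w[keep]
  }
  p <- length(gene_ids)
  scores <- matrix(0, p, p, dimnames = list(gene_ids, gene_ids))
  i <- match(from, gene_ids)
  j <- match(to, gene_ids)
  scores[cbind(i, j)] <- w
  scores[cbind(j, i)] <- w
  weighted_network(scores)
}

read_network_matrix <- function(df, gene_ids) {
  file_ids <- df[[1]]
  header_ids <- colnames(df)[-1]
  if (!setequal(file_ids, header_ids)) {
    stop_netaggr("square matrix row and column labels differ")
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(vals)) stop_netaggr("cannot parse score matrix value")
  dimnames(vals) <- list(file_ids, header_ids)
  vals <- vals[, file_ids, drop = FALSE] # align columns to row order
  net <- weighted_network(vals, gene_ids = file_ids)
  if (!is.null(gene_ids)) {
    unknown <- setdiff(file_ids, gene_ids)
    if (length(unknown)) {
      stop_netaggr("network genes not in gene set: ",
                   paste(unknown, collapse = ", "))
    }
    p <- length(gene_ids)
    full <- matrix(0, p, p, dimnames = list(gene_ids, gene_ids))
    full[file_ids, file_ids] <- as_plain_matrix(net)
    net <- weighted_network(full)
  }
  net
}

#' Write a weighted network to a text file
#'
#' @param net a [weighted_network()].
#' @param path output path.
#' @param format `"edgelist"` writes one row per unordered pair with
#'   `|w| > threshold`, pairs lexicographically sorted; `"matrix"` writes
#'   the full labeled square matrix.
#' @param threshold minimum absolute score for edge-list rows.
#' @param delimiter field delimiter.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edgelist", "matrix"),
                          threshold = 0, delimiter = "\t") {
  format <- match.arg(format)
  net <- weighted_network(as_plain_matrix(as.matrix(net)))
  if (threshold < 0) stop_netaggr("threshold must be >= 0")
  if (format == "matrix") {
    df <- data.frame(gene = rownames(net), as_plain_matrix(net),
                     check.names = FALSE)
  } else {
    ids <- rownames(net)
    lt <- which(lower.tri(net), arr.ind = TRUE)
    keep <- abs(net[lt]) > threshold
    lt <- lt[keep, , drop = FALSE]
    a <- pmin(ids[lt[, 1]], ids[lt[, 2]])
    b <- pmax(ids[lt[, 1]], ids[lt[, 2]])
    ord <- order(a, b)
    df <- data.frame(gene_a = a[ord], gene_b = b[ord],
                     score = net[lt][keep][ord])
  }
  write_table_checked(df, path, delimiter)
  invisible(path)
}

#' Read a gold-standard topology from an edge list
#'
#' Accepts 2- or 3-column edge lists (a third score column is ignored).
#'
#' @param path path to the file.
#' @param gene_ids optional full vertex set including unconnected genes;
#'   defaults to the genes appearing in edges.
#' @param delimiter field delimiter.
#' @return a [true_network()].
#' @export
read_truth <- function(path, gene_ids = NULL, delimiter = "\t") {
  if (!file.exists(path)) stop_netaggr("file not found: ", path)
  df <- read.table(path, sep = delimiter, header = TRUE, row.names = NULL,
                   check.names = FALSE, colClasses = "character",
                   comment.char = "", quote = "")
  if (ncol(df) < 2) stop_netaggr("expected a 2- or 3-column edge list")
  if (is.null(gene_ids)) gene_ids <- sort(unique(c(df[[1]], df[[2]])))
  true_network(gene_ids, df[, 1:2])
}

#' Write a gold-standard topology as an edge list
#'
#' @param truth a [true_network()].
#' @param path output path.
#' @param delimiter field delimiter.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, delimiter = "\t") {
  write_table_checked(truth$edges, path, delimiter)
  invisible(path)
}

write_table_checked <- function(df, path, delimiter) {
  ok <- tryCatch({
    write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop_netaggr("cannot write '", path, "': ", conditionMessage(ok))
  }
}
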