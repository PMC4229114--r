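# Fixtures and independent brute-force oracles used across test files.

# small weighted network from an explicit lower-triangle score vector
net_from_scores <- function(scores, ids = NULL) {
  k <- length(scores)
  p <- (1 + sqrt(1 + 8 * k)) / 2
  stopifnot(p == round(p))
  if (is.null(ids)) ids <- LETTERS[seq_len(p)]
  m <- matrix(0, p, p, dimnames = list(ids, ids))
  m[lower.tri(m)] <- scores
  weighted_network(m + t(m))
}

lower_tri_vec <- function(net) {
  m <- as.matrix(net)
  m[lower.tri(m)]
}

# brute-force midranks by explicit sort: position averaging per tied value
oracle_ranks <- function(scores) {
  a <- abs(scores)
  ord <- order(a, decreasing = TRUE)
  pos <- seq_along(a)
  r <- numeric(length(a))
  i <- 1
  while (i <= length(a)) {
    j <- i
    while (j < length(a) && a[ord[j + 1]] == a[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(pos[i:j])
    i <- j + 1
  }
  r
}

# brute-force inverse rank product over a list of lower-triangle score vectors
oracle_rank_product_scores <- function(score_vectors) {
  ranks <- lapply(score_vectors, oracle_ranks)
  rp <- Reduce(`*`, ranks)
  rp^(-1 / length(score_vectors))
}

# brute-force Mann-Whitney AUC with midrank tie handling
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (s in pos) {
    total <- total + sum(s > neg) + 0.5 * sum(s == neg)
  }
  total / (length(pos) * length(neg))
}

# random symmetric zero-diagonal score matrix
random_network <- function(p, seed, sparse = 0) {
  set.seed(seed)
  k <- p * (p - 1) / 2
  s <- rnorm(k)
  if (sparse > 0) s[sample.int(k, floor(sparse * k))] <- 0
  net_from_scores(s, ids = sprintf("g%02d", seq_len(p)))
}

# tiny expression fixture with named genes
tiny_expr <- function(p = 3, n = 10, seed = 1) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(p * n), p, n),
                    gene_ids = paste0("g", seq_len(p)),
                    sample_ids = paste0("s", seq_len(n)))
}

# temp file cleaned up when the calling test finishes
withr_local_file <- function(name, envir = parent.frame()) {
  file.path(withr::local_tempdir(.local_envir = envir), name)
}
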