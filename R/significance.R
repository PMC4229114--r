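#' Permutation significance of aggregated edges
#'
#' Builds a null distribution for the rank product by independently
#' permuting each network's lower-triangle rank assignment `n_perm` times
#' and recomputing all pair rank products. Because every pair has the same
#' null by exchangeability, the null values are pooled across pairs and
#' permutations, and each observed rank product gets
#' `p = (1 + #\{null RP <= observed RP\}) / (1 + n_perm * K)` with `K` the
#' number of pairs. P-values are Benjamini-Hochberg adjusted; edges with
#' adjusted p <= `alpha` are flagged significant. This reduces a complete
#' weighted aggregate to the edge set that ranks consistently better than
#' chance.
#'
#' @param nets list of >= 2 [weighted_network()] objects on one gene set.
#' @param n_perm number of permutations (>= 100).
#' @param alpha significance level for the adjusted p-values.
#' @param seed integer seed.
#' @return an object of class `edge_significance`: a data.frame with one
#'   row per unordered pair (`gene_a`, `gene_b`, `rank_product`,
#'   `p_value`, `p_adjusted`, `significant`), sorted by rank product.
#' @export
permutation_significance <- function(nets, n_perm = 1000, alpha = 0.05,
                                     seed = 1) {
  if (!is.list(nets) || length(nets) < 2) {
    stop_netaggr("need at least 2 networks")
  }
  if (n_perm < 100) {
    stop_netaggr("n_perm must be >= 100 for usable p-value resolution")
  }
  ids <- rownames(nets[[1]])
  p <- length(ids)
  lt <- which(lower.tri(matrix(0, p, p)))
  rank_cols <- vapply(nets, function(net) {
    if (!identical(rownames(net), ids)) {
      stop_netaggr("networks disagree on the gene set")
    }
    edge_ranks(net)[lt]
  }, numeric(length(lt)))
  k <- length(lt)
  g <- ncol(rank_cols)
  log_ranks <- log(rank_cols)
  obs <- rowSums(log_ranks)

  null_pool <- with_seed(seed, {
    pool <- numeric(k * n_perm)
    for (b in seq_len(n_perm)) {
      perm <- rowSums(vapply(seq_len(g), function(col) {
        log_ranks[sample.int(k), col]
      }, numeric(k)))
      pool[((b - 1) * k + 1):(b * k)] <- perm
    }
    pool
  })
  null_sorted <- sort(null_pool)
  # tolerance absorbs exp/log round-off so equal rank products count as ties
  count_le <- findInterval(obs + 1e-9, null_sorted)
  p_value <- (1 + count_le) / (1 + length(null_pool))
  p_adjusted <- p.adjust(p_value, method = "BH")

  pair_idx <- which(lower.tri(matrix(0, p, p)), arr.ind = TRUE)
  out <- data.frame(gene_a = ids[pair_idx[, 2]], gene_b = ids[pair_idx[, 1]],
                    rank_product = exp(obs), p_value = p_value,
                    p_adjusted = p_adjusted,
                    significant = p_adjusted <= alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank_product), ]
  rownames(out) <- NULL
  structure(out, class = c("edge_significance", "data.frame"),
            n_perm = n_perm, alpha = alpha, n_networks = g)
}
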