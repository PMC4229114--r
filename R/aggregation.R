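#' Rank the edges of a weighted network
#'
#' Every unordered gene pair `(i, j)`, `i < j`, is ranked by descending
#' absolute score: the most confident interaction gets rank 1. Tied scores
#' (including the block of exact zeros produced by sparse reconstructors)
#' share the midrank, so the lower-triangle ranks always sum to
#' `K (K + 1) / 2` with `K = N (N - 1) / 2` pairs.
#'
#' @param net a [weighted_network()].
#' @return a symmetric rank matrix of class `rank_matrix` (diagonal `NA`).
#' @export
edge_ranks <- function(net) {
  net <- as.matrix(net)
  p <- nrow(net)
  if (p < 2) stop_netaggr("need at least 2 genes to rank edges")
  lt <- lower.tri(net)
  r <- rank(-abs(net[lt]), ties.method = "average")
  ranks <- matrix(NA_real_, p, p, dimnames = dimnames(net))
  ranks[lt] <- r
  ranks <- pmin(ranks, t(ranks), na.rm = TRUE)
  class(ranks) <- c("rank_matrix", class(ranks))
  ranks
}

#' Aggregate networks by the inverse rank product
#'
#' The consensus score of pair `(i, j)` across `G` networks is
#' `s_ij = (prod_g r_g(i, j))^(-1/G)`, the inverse geometric mean of the
#' pair's per-network ranks. Scores lie in `(0, 1]`; `s_ij = 1` only for a
#' pair ranked first in every network, and ordering by `s` descending is
#' ordering by rank product ascending. Being rank-based, the aggregate is
#' invariant to any strictly increasing transform of any one input
#' network's absolute scores.
#'
#' @param nets list of [weighted_network()] objects over an identical
#'   ordered gene set.
#' @return a [weighted_network()] of inverse-rank-product scores, with a
#'   `provenance` attribute listing the input names.
#' @export
rank_product_aggregate <- function(nets) {
  if (!is.list(nets) || length(nets) == 0) {
    stop_netaggr("need a non-empty list of networks")
  }
  ids <- rownames(nets[[1]])
  for (k in seq_along(nets)) {
    other <- rownames(nets[[k]])
    if (!identical(other, ids)) {
      diff <- union(setdiff(ids, other), setdiff(other, ids))
      stop_netaggr("networks disagree on the gene set",
                   if (length(diff)) paste0(" (symmetric difference: ",
                                            paste(diff, collapse = ", "), ")")
                   else " (same genes, different order)")
    }
  }
  g <- length(nets)
  p <- length(ids)
  lt <- lower.tri(matrix(0, p, p))
  # sum of log ranks == log rank product; numerically safe for any G, K
  log_rp <- 0
  for (net in nets) {
    log_rp <- log_rp + log(edge_ranks(net)[lt])
  }
  scores <- matrix(0, p, p, dimnames = list(ids, ids))
  scores[lt] <- exp(-log_rp / g)
  scores <- scores + t(scores)
  out <- weighted_network(scores)
  attr(out, "provenance") <- list(
    inputs = if (!is.null(names(nets))) names(nets) else
      paste0("network_", seq_len(g)),
    n_networks = g,
    ties = "midrank"
  )
  out
}
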