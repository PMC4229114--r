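#' Generate an approximately scale-free gold-standard network
#'
#' Grows a preferential-attachment tree (each new node attaches to an
#' existing node with probability proportional to degree + 1), then adds
#' the remaining `n_edges - (n_genes - 1)` edges between non-adjacent pairs
#' sampled with probability proportional to the product of endpoint
#' degrees. The result is connected, has exactly `n_edges` edges, and has
#' the heavy-tailed degree distribution characteristic of biological
#' interaction networks (a few hub genes of high degree).
#'
#' @param n_genes number of genes (nodes).
#' @param n_edges number of edges; must lie in
#'   `[n_genes - 1, n_genes (n_genes - 1) / 2]`.
#' @param seed integer seed; the same seed always yields the same edge set.
#' @return a [true_network()] with gene ids `g001, g002, ...`.
#' @export
generate_scale_free <- function(n_genes, n_edges, seed = 1) {
  if (n_genes < 2) stop_netaggr("need at least 2 genes")
  max_edges <- n_genes * (n_genes - 1) / 2
  if (n_edges < n_genes - 1 || n_edges > max_edges) {
    stop_netaggr("n_edges must be in [", n_genes - 1, ", ", max_edges,
                 "] for a connected ", n_genes, "-gene network")
  }
  width <- max(3, nchar(n_genes))
  ids <- sprintf(paste0("g%0", width, "d"), seq_len(n_genes))
  with_seed(seed, {
    deg <- integer(n_genes)
    from <- integer(n_edges)
    to <- integer(n_edges)
    for (i in 2:n_genes) {
      j <- sample.int(i - 1, 1, prob = deg[seq_len(i - 1)] + 1)
      from[i - 1] <- j
      to[i - 1] <- i
      deg[i] <- deg[i] + 1
      deg[j] <- deg[j] + 1
    }
    n_extra <- n_edges - (n_genes - 1)
    if (n_extra > 0) {
      have <- new.env(hash = TRUE)
      for (e in seq_len(n_genes - 1)) {
        assign(paste(from[e], to[e]), TRUE, envir = have)
      }
      added <- 0
      while (added < n_extra) {
        pair <- sample.int(n_genes, 2, prob = deg + 1)
        a <- min(pair); b <- max(pair)
        key <- paste(a, b)
        if (exists(key, envir = have, inherits = FALSE)) next
        assign(key, TRUE, envir = have)
        added <- added + 1
        from[n_genes - 1 + added] <- a
        to[n_genes - 1 + added] <- b
        deg[a] <- deg[a] + 1
        deg[b] <- deg[b] + 1
      }
    }
    true_network(ids, data.frame(from = ids[from], to = ids[to]))
  })
}

#' Simulate expression data from a gold-standard topology
#'
#' Realizes the conditional-normal scheme as a sequential linear-Gaussian
#' model: edges are oriented from the earlier-generated gene to the later
#' one (so the orientation is acyclic by construction), each edge gets a
#' weight drawn uniformly from `edge_weight_range` with a random sign, and
#' genes are visited in generation order with
#' `x_i = sum_parents w_ij x_j + N(0, 1)`. Root genes are pure `N(0, 1)`
#' innovations, so marginal signal variance grows with connectivity. The
#' observed expression adds measurement noise: `y = x + N(0, noise_sd^2)`.
#' (Scaling the innovations themselves would cancel out of every
#' correlation and leave the noise level without any effect on
#' reconstruction; additive expression noise is the interpretation under
#' which the noise level matters.) For a single edge of weight `w` the
#' population correlation of the observed pair is
#' `w / sqrt((1 + noise_sd^2) (w^2 + 1 + noise_sd^2))`.
#'
#' @param truth a [true_network()].
#' @param n_samples number of samples (columns) to draw.
#' @param noise_sd standard deviation of the additive expression noise (> 0).
#' @param edge_weight_range length-2 numeric `(low, high)`, `0 < low <= high`.
#' @param seed integer seed.
#' @return an [expression_matrix()] (genes x samples), genes in truth order.
#' @export
simulate_expression <- function(truth, n_samples, noise_sd = 0.25,
                                edge_weight_range = c(0.5, 1), seed = 1) {
  if (n_samples < 2) stop_netaggr("need at least 2 samples")
  if (noise_sd <= 0) stop_netaggr("noise_sd must be > 0")
  if (length(edge_weight_range) != 2 || edge_weight_range[1] <= 0 ||
      edge_weight_range[1] > edge_weight_range[2]) {
    stop_netaggr("edge_weight_range must be (low, high) with 0 < low <= high")
  }
  ids <- truth$gene_ids
  p <- length(ids)
  ei <- match(truth$edges$from, ids)
  ej <- match(truth$edges$to, ids)
  parent <- pmin(ei, ej) # generation order == gene order
  child <- pmax(ei, ej)
  with_seed(seed, {
    n_e <- length(parent)
    w <- if (n_e > 0) {
      runif(n_e, edge_weight_range[1], edge_weight_range[2]) *
        sample(c(-1, 1), n_e, replace = TRUE)
    } else numeric(0)
    x <- matrix(rnorm(p * n_samples), nrow = p)
    for (i in seq_len(p)) {
      es <- which(child == i)
      for (e in es) {
        x[i, ] <- x[i, ] + w[e] * x[parent[e], ]
      }
    }
    x <- x + matrix(rnorm(p * n_samples, sd = noise_sd), nrow = p)
    width <- max(3, nchar(n_samples))
    expression_matrix(x, gene_ids = ids,
                      sample_ids = sprintf(paste0("s%0", width, "d"),
                                           seq_len(n_samples)))
  })
}

#' Generate the full simulation grid
#'
#' One `(truth, expression)` dataset per combination of network size,
#' sample size and noise level, each with a seed derived from the master
#' seed. The defaults reproduce the standard benchmark grid of
#' 5 network sizes x 6 sample sizes x 4 noise levels = 120 datasets.
#'
#' @param sizes list of `c(n_genes, n_edges)` pairs.
#' @param sample_sizes integer vector of sample counts.
#' @param noise_levels numeric vector of expression-noise standard deviations.
#' @param seed master seed.
#' @param edge_weight_range passed to [simulate_expression()].
#' @return a list of cells, each a list with `truth`, `expr`, `n_genes`,
#'   `n_edges`, `n_samples`, `noise_sd`, `seed`.
#' @export
generate_grid <- function(sizes = list(c(17, 20), c(44, 57), c(83, 114),
                                       c(231, 311), c(612, 911)),
                          sample_sizes = c(20, 50, 100, 200, 500, 1000),
                          noise_levels = c(0.25, 0.5, 1.0, 1.5),
                          seed = 1,
                          edge_weight_range = c(0.5, 1)) {
  if (!length(sizes) || !length(sample_sizes) || !length(noise_levels)) {
    stop_netaggr("all factor lists must be non-empty")
  }
  cells <- list()
  idx <- 0
  for (si in seq_along(sizes)) {
    size <- sizes[[si]]
    truth <- generate_scale_free(size[1], size[2],
                                 seed = derive_seed(seed, si))
    for (ni in seq_along(sample_sizes)) {
      for (vi in seq_along(noise_levels)) {
        idx <- idx + 1
        cell_seed <- derive_seed(seed, si, ni, vi)
        expr <- simulate_expression(truth, sample_sizes[ni],
                                    noise_sd = noise_levels[vi],
                                    edge_weight_range = edge_weight_range,
                                    seed = cell_seed)
        cells[[idx]] <- list(truth = truth, expr = expr,
                             n_genes = size[1], n_edges = size[2],
                             n_samples = sample_sizes[ni],
                             noise_sd = noise_levels[vi], seed = cell_seed)
      }
    }
  }
  cells
}
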