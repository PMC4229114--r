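test_that("a degenerate bootstrap reduces to the plain reconstruction", {
  expr <- tiny_expr(p = 8, n = 30, seed = 1)
  config <- ensemble_config(B = 1, sample_fraction = 1, methods = "softcor",
                            seed = 4)
  boot <- bootstrap_ena(expr, "softcor", config)
  plain <- reconstruct_softcor(expr)
  expect_equal(edge_ranks(boot), edge_ranks(plain))
})

test_that("bootstrap output is bit-identical across worker counts and seeds reproduce", {
  expr <- tiny_expr(p = 10, n = 40, seed = 2)
  config1 <- ensemble_config(B = 8, methods = "softcor", seed = 7, workers = 1)
  config8 <- ensemble_config(B = 8, methods = "softcor", seed = 7, workers = 4)
  n1 <- bootstrap_ena(expr, "softcor", config1)
  n8 <- bootstrap_ena(expr, "softcor", config8)
  expect_identical(as.matrix(n1), as.matrix(n8))
  n1b <- bootstrap_ena(expr, "softcor", config1)
  expect_identical(as.matrix(n1), as.matrix(n1b))
  other <- bootstrap_ena(expr, "softcor",
                         ensemble_config(B = 8, methods = "softcor", seed = 8))
  expect_false(identical(as.matrix(n1), as.matrix(other)))
})

test_that("replicate failures are capped at 20%", {
  expr <- tiny_expr(p = 5, n = 20, seed = 3)
  config <- ensemble_config(B = 5, methods = "space", seed = 1,
                            reconstruction_args = list(space = list(lambda = -1)))
  expect_error(suppressWarnings(bootstrap_ena(expr, "space", config)),
               "20%")
})

test_that("an ensemble of identical members preserves the member ranking", {
  expr <- tiny_expr(p = 7, n = 50, seed = 4)
  config <- ensemble_config(B = 1, sample_fraction = 1,
                            methods = c("softcor", "softcor", "softcor"),
                            seed = 2)
  agg <- multimethod_ena(expr, config)
  expect_equal(edge_ranks(agg), edge_ranks(reconstruct_softcor(expr)))
})

test_that("a failing method aborts the cross-method ensemble", {
  expr <- tiny_expr(p = 5, n = 20, seed = 5)
  config <- ensemble_config(B = 1, sample_fraction = 1,
                            methods = c("softcor", "space"), seed = 2,
                            reconstruction_args = list(space = list(lambda = -1)))
  expect_error(multimethod_ena(expr, config), "lambda")
})

test_that("exactly reversed rankings aggregate to mirror-symmetric rank products", {
  # brute force on 4 genes: rank products r (K + 1 - r) pair up symmetrically
  k <- 6
  n1 <- net_from_scores(seq(k, 1) / k, ids = c("A", "B", "C", "D"))
  n2 <- net_from_scores(seq(1, k) / k, ids = c("A", "B", "C", "D"))
  agg <- rank_product_aggregate(list(n1, n2))
  rp <- sort(lower_tri_vec(agg)^(-2)) # recover the rank products
  expect_equal(rp, sort((1:k) * (k + 1 - (1:k))))
  expect_equal(rp[1], rp[2]) # extremes tie with their mirrors
})

test_that("cross-dataset ensembles restrict to the shared genes with a warning", {
  set.seed(9)
  make <- function(ids) {
    expression_matrix(matrix(rnorm(length(ids) * 30), length(ids), 30),
                      gene_ids = ids, sample_ids = paste0("s", 1:30))
  }
  e1 <- make(c("A", "B", "C"))
  e2 <- make(c("B", "C", "D"))
  config <- ensemble_config(B = 1, sample_fraction = 1, methods = "softcor",
                            seed = 3)
  expect_warning(net <- multidataset_ena(list(e1, e2), config), "shared genes")
  expect_identical(rownames(net), c("B", "C"))
  expect_error(multidataset_ena(list(make(c("A", "B")), make(c("C", "D"))),
                                config),
               "fewer than 2")
})

test_that("two identical datasets reproduce the single-dataset ensemble ranking", {
  expr <- tiny_expr(p = 6, n = 40, seed = 11)
  config <- ensemble_config(B = 1, sample_fraction = 1,
                            methods = c("softcor", "shrinkage_pcor"), seed = 5)
  single <- multimethod_ena(expr, config)
  double <- suppressWarnings(multidataset_ena(list(expr, expr), config))
  expect_equal(edge_ranks(double), edge_ranks(single))
})

test_that("bootstrapping improves the sparse fit in most replications", {
  # scaled-down directional check: 44-gene network, few samples, modest B
  wins <- 0
  n_rep <- 7
  for (seed in seq_len(n_rep)) {
    truth <- generate_scale_free(44, 57, seed = derive_seed(seed, 1))
    expr <- simulate_expression(truth, 20, noise_sd = 0.25,
                                seed = derive_seed(seed, 2))
    single_auc <- evaluate_network(reconstruct_space(expr), truth)$auc
    config <- ensemble_config(B = 30, methods = "space",
                              seed = derive_seed(seed, 3))
    boot_auc <- evaluate_network(bootstrap_ena(expr, "space", config),
                                 truth)$auc
    wins <- wins + (boot_auc > single_auc)
  }
  expect_gt(wins, n_rep / 2)
})
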