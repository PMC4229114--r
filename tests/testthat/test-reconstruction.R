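chain_expr <- function(n = 1000, seed = 8, noise_sd = 0.05) {
  truth <- true_network(c("A", "B", "C"),
                        data.frame(from = c("A", "B"), to = c("B", "C")))
  simulate_expression(truth, n, noise_sd = noise_sd,
                      edge_weight_range = c(0.8, 0.8), seed = seed)
}

test_that("all reconstructors return symmetric zero-diagonal networks in gene order", {
  expr <- tiny_expr(p = 6, n = 40, seed = 2)
  for (method in c("space", "shrinkage_pcor", "softcor")) {
    net <- reconstruct_network(expr, method)
    expect_identical(rownames(net), rownames(expr))
    expect_identical(as.matrix(net), t(as.matrix(net)))
    expect_equal(unname(diag(net)), rep(0, 6))
  }
})

test_that("input validation names the offending gene", {
  expr <- tiny_expr(p = 4, n = 10, seed = 3)
  bad <- as.matrix(expr)
  bad[2, ] <- 7 # constant gene g2
  bad <- expression_matrix(bad)
  for (method in c("space", "shrinkage_pcor", "softcor")) {
    expect_error(reconstruct_network(bad, method), "g2")
  }
  expect_error(reconstruct_space(tiny_expr(p = 4, n = 2)), "samples")
})

test_that("sparse partial correlation recovers a strong two-gene dependence", {
  truth <- true_network(c("A", "B"), data.frame(from = "A", to = "B"))
  expr <- simulate_expression(truth, 200, noise_sd = 0.25,
                              edge_weight_range = c(0.8, 0.8), seed = 21)
  sign_w <- sign(cor(expr["A", ], expr["B", ]))
  net <- reconstruct_space(expr)
  expect_gt(net["A", "B"] * sign_w, 0.3)
})

test_that("independent genes yield an (almost) empty sparse fit", {
  set.seed(77)
  expr <- expression_matrix(matrix(rnorm(10 * 500), 10, 500),
                            gene_ids = paste0("g", 1:10),
                            sample_ids = paste0("s", 1:500))
  # family-wise calibrated penalty: no edges survive under independence
  strict <- default_space_lambda(500, 10, alpha = 1e-4)
  net <- reconstruct_space(expr, lambda = strict)
  expect_equal(sum(abs(lower_tri_vec(net)) > 0), 0)
  # the default penalty sits at ~z/2 standard errors per pair, so a few
  # stray edges are expected -- but the fit must stay very sparse
  net_default <- reconstruct_space(expr)
  expect_lt(mean(abs(lower_tri_vec(net_default)) > 0), 0.15)
})

test_that("a three-gene chain is resolved into its two direct edges", {
  expr <- chain_expr()
  # population partial correlation of the non-adjacent pair is 0
  space <- reconstruct_space(expr)
  expect_gt(abs(space["A", "B"]), abs(space["A", "C"]))
  expect_gt(abs(space["B", "C"]), abs(space["A", "C"]))
  # the default penalty thresholds near 1.5 sampling sds, so the indirect
  # pair is only guaranteed to vanish at a family-wise calibrated penalty
  strict <- reconstruct_space(expr,
                              lambda = default_space_lambda(1000, 3,
                                                            alpha = 1e-4))
  expect_equal(strict["A", "C"], 0)
  expect_gt(abs(strict["A", "B"]), 0.3)
  expect_gt(abs(strict["B", "C"]), 0.3)
  shrink <- reconstruct_shrinkage_pcor(expr)
  expect_gt(shrink["A", "B"], shrink["A", "C"])
  expect_gt(shrink["B", "C"], shrink["A", "C"])
})

test_that("shrinkage partial correlations vanish for orthogonal data", {
  set.seed(5)
  q <- qr.Q(qr(matrix(rnorm(50 * 4), 50, 4))) # exactly orthogonal columns
  expr <- expression_matrix(t(q), gene_ids = paste0("g", 1:4),
                            sample_ids = paste0("s", 1:50))
  net <- reconstruct_shrinkage_pcor(expr)
  expect_lt(max(abs(lower_tri_vec(net))), 1e-10)
  intensity <- attr(net, "run_log")$shrinkage_intensity
  expect_gte(intensity, 0)
  expect_lte(intensity, 1)
})

test_that("shrinkage intensity is clipped to [0, 1] on arbitrary inputs", {
  for (seed in 1:4) {
    expr <- tiny_expr(p = 5, n = 4 + seed, seed = seed)
    intensity <- attr(reconstruct_shrinkage_pcor(expr),
                      "run_log")$shrinkage_intensity
    expect_gte(intensity, 0)
    expect_lte(intensity, 1)
  }
})

test_that("soft-thresholded correlation behaves as |cor|^beta", {
  expr <- tiny_expr(p = 5, n = 30, seed = 6)
  x <- as.matrix(expr)
  x2 <- rbind(x, 2 * x[1, ] + 3)
  rownames(x2) <- c(rownames(x), "dup")
  dup <- expression_matrix(x2)
  net <- reconstruct_softcor(dup)
  expect_equal(net["g1", "dup"], 1) # perfectly correlated duplicate
  net1 <- reconstruct_softcor(expr, beta = 1)
  expect_equal(as.matrix(net1), abs(cor(t(x))) - diag(5),
               tolerance = 1e-12, ignore_attr = TRUE)
  # beta only sharpens: rankings at beta = 1 and beta = 6 coincide
  net6 <- reconstruct_softcor(expr, beta = 6)
  expect_equal(edge_ranks(net6), edge_ranks(net1))
  expect_true(all(lower_tri_vec(net6) >= 0 & lower_tri_vec(net6) <= 1))
})

test_that("correlation-based fits are invariant to per-gene affine rescaling", {
  expr <- tiny_expr(p = 5, n = 25, seed = 10)
  scaled <- expression_matrix(diag(c(2, 0.5, 10, 1, 3)) %*% as.matrix(expr) +
                                c(1, -2, 0, 5, 100),
                              gene_ids = rownames(expr),
                              sample_ids = colnames(expr))
  expect_equal(as.matrix(reconstruct_softcor(scaled)),
               as.matrix(reconstruct_softcor(expr)), tolerance = 1e-8)
  expect_equal(as.matrix(reconstruct_shrinkage_pcor(scaled)),
               as.matrix(reconstruct_shrinkage_pcor(expr)), tolerance = 1e-8)
  expect_equal(as.matrix(reconstruct_space(scaled)),
               as.matrix(reconstruct_space(expr)), tolerance = 1e-8)
})

test_that("sparse fit ranks true edges on top when n >> p", {
  truth <- generate_scale_free(20, 25, seed = 14)
  expr <- simulate_expression(truth, 1000, noise_sd = 0.25, seed = 15)
  net <- reconstruct_space(expr)
  expect_gt(evaluate_network(net, truth)$auc, 0.9)
})
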