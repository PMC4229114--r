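#' Reconstruct a network from expression data
#'
#' Dispatches to one of the three baseline reconstructors by name.
#'
#' @param expr an [expression_matrix()] (genes x samples).
#' @param method `"space"` (sparse symmetric partial correlation),
#'   `"shrinkage_pcor"` (shrinkage partial correlation) or `"softcor"`
#'   (soft-thresholded correlation).
#' @param ... passed to the method-specific reconstructor.
#' @return a [weighted_network()].
#' @export
reconstruct_network <- function(expr, method = c("space", "shrinkage_pcor",
                                                 "softcor"), ...) {
  method <- match.arg(method)
  switch(method,
         space = reconstruct_space(expr, ...),
         shrinkage_pcor = reconstruct_shrinkage_pcor(expr, ...),
         softcor = reconstruct_softcor(expr, ...))
}

#' Default L1 penalty for the sparse partial-correlation fit
#'
#' `sqrt(n) * qnorm(1 - alpha / (2 p^2))`: the penalty level that targets
#' family-wise control of false edge selection over the roughly `p^2`
#' implicit tests at level `alpha`.
#'
#' @param n number of samples.
#' @param p number of genes.
#' @param alpha nominal selection level.
#' @return a positive scalar penalty.
#' @export
default_space_lambda <- function(n, p, alpha = 0.05) {
  sqrt(n) * qnorm(1 - alpha / (2 * p^2))
}

#' Sparse symmetric partial-correlation reconstruction
#'
#' Estimates the partial-correlation matrix by a joint penalized
#' regression: every standardized gene is regressed on all the others with
#' the regression coefficients tied through the symmetric
#' partial-correlation parameterization, and the summed squared residuals
#' plus an L1 penalty `lambda * sum_{i<j} |rho_ij|` are minimized by cyclic
#' coordinate descent (each pair update is an exact soft-threshold step).
#' The diagonal concentrations are refit from residual variances between
#' outer iterations. Output scores are the estimated partial correlations;
#' most are exactly zero (sparse network).
#'
#' @param expr an [expression_matrix()]; needs >= 3 samples, >= 2 genes,
#'   positive variance for every gene.
#' @param lambda L1 penalty, or `"auto"` for [default_space_lambda()].
#' @param max_iter maximum coordinate-descent sweeps per outer iteration.
#' @param tol convergence tolerance on the maximum absolute change of any
#'   partial correlation within a sweep.
#' @param outer_iter number of outer iterations (diagonal refits).
#' @return a [weighted_network()] of signed partial correlations, with a
#'   `run_log` attribute recording `lambda`, sweeps and convergence. A
#'   warning is raised (and the partial result returned) if the sweep
#'   budget is exhausted.
#' @export
reconstruct_space <- function(expr, lambda = "auto", max_iter = 500,
                              tol = 1e-6, outer_iter = 3) {
  x <- check_expr_for_fit(expr)
  n <- ncol(x)
  p <- nrow(x)
  if (identical(lambda, "auto")) {
    lambda <- default_space_lambda(n, p)
  }
  if (!is.numeric(lambda) || lambda <= 0) {
    stop_netaggr("lambda must be positive or \"auto\"")
  }
  if (tol <= 0) stop_netaggr("tol must be > 0")
  # standardize genes to mean 0, ||x||^2 = n (population sd)
  xs <- x - rowMeans(x)
  xs <- xs / sqrt(rowMeans(xs^2))
  fit <- .space_cd(t(xs), lambda, as.integer(max_iter), tol,
                   as.integer(outer_iter))
  if (!fit$converged) {
    warning("sparse partial-correlation fit did not converge within ",
            max_iter, " sweeps; returning partial result", call. = FALSE)
  }
  net <- weighted_network(fit$rho, gene_ids = rownames(x))
  attr(net, "run_log") <- list(method = "space", lambda = lambda,
                               sweeps = fit$sweeps,
                               converged = fit$converged)
  net
}

#' Shrinkage partial-correlation reconstruction
#'
#' Computes the sample correlation matrix, shrinks it toward the identity
#' with the analytic data-driven intensity
#' `lambda* = sum var(r_ij) / sum r_ij^2` (clipped to `[0, 1]`), inverts the
#' shrunk correlation matrix (Moore-Penrose pseudoinverse if singular), and
#' standardizes the negated inverse to partial correlations. Scores are
#' absolute partial correlations; the output is dense.
#'
#' @param expr an [expression_matrix()]; needs >= 3 samples.
#' @return a [weighted_network()] with a `run_log` attribute recording the
#'   shrinkage intensity.
#' @export
reconstruct_shrinkage_pcor <- function(expr) {
  x <- check_expr_for_fit(expr)
  n <- ncol(x)
  p <- nrow(x)
  zs <- t(scale(t(x))) # gene-standardized, sd with denominator n - 1
  r <- tcrossprod(zs) / (n - 1)
  diag(r) <- 1
  # empirical variance of each correlation coefficient from the products
  # w_kij = z_ki z_kj: var(r_ij) = n/(n-1)^3 sum_k (w_kij - mean_k w_kij)^2
  wk2 <- tcrossprod(zs^2) # sum_k w_kij^2
  var_r <- n / (n - 1)^3 * (wk2 - (n - 1)^2 / n * r^2)
  off <- upper.tri(r)
  intensity <- sum(var_r[off]) / sum(r[off]^2)
  intensity <- min(1, max(0, intensity))
  r_shrunk <- (1 - intensity) * r
  diag(r_shrunk) <- 1
  omega <- pseudo_solve(r_shrunk)
  dd <- sqrt(diag(omega))
  pcor <- -omega / tcrossprod(dd)
  diag(pcor) <- 0
  net <- weighted_network(abs(pcor), gene_ids = rownames(x),
                          symmetrize_tol = 1e-6)
  attr(net, "run_log") <- list(method = "shrinkage_pcor",
                               shrinkage_intensity = intensity)
  net
}

#' Soft-thresholded correlation reconstruction
#'
#' Weighted-coexpression-style adjacency: `w_ij = |cor(x_i, x_j)|^beta`.
#' With the default `beta = 6` strong correlations are emphasized; since
#' the power is strictly monotone, any `beta >= 1` yields the same edge
#' ranking on distinct absolute correlations.
#'
#' @param expr an [expression_matrix()]; needs >= 3 samples.
#' @param beta soft-thresholding power (>= 1).
#' @return a dense [weighted_network()] with scores in `[0, 1]`.
#' @export
reconstruct_softcor <- function(expr, beta = 6) {
  x <- check_expr_for_fit(expr)
  if (beta < 1) stop_netaggr("beta must be >= 1")
  a <- abs(cor(t(x)))^beta
  diag(a) <- 0
  net <- weighted_network(a, gene_ids = rownames(x), symmetrize_tol = 1e-6)
  attr(net, "run_log") <- list(method = "softcor", beta = beta)
  net
}

check_expr_for_fit <- function(expr) {
  x <- as.matrix(expr)
  if (is.null(rownames(x))) stop_netaggr("expression matrix needs gene ids")
  if (nrow(x) < 2) stop_netaggr("need at least 2 genes")
  if (ncol(x) < 3) stop_netaggr("need at least 3 samples")
  v <- apply(x, 1, sd)
  if (any(v == 0)) {
    stop_netaggr("zero-variance gene(s): ",
                 paste(rownames(x)[v == 0], collapse = ", "))
  }
  x
}

# Moore-Penrose pseudoinverse via SVD; exact inverse when well-conditioned.
pseudo_solve <- function(m, rtol = 1e-10) {
  s <- svd(m)
  keep <- s$d > rtol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
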