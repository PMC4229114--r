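#' Run a canned simulation experiment
#'
#' Three templates mirror the package's three ensemble workflows on
#' simulated data:
#'
#' * `"bootstrap"`: one scale-free truth (default 231 genes / 311 edges),
#'   one small dataset (default 20 samples, noise sd 0.25); compares a
#'   single sparse partial-correlation fit against its bootstrap ensemble.
#' * `"methods"`: one dataset (default 83 genes / 114 edges, 200 samples);
#'   compares each single-method network against the cross-method ensemble.
#' * `"datasets"`: three datasets from one truth (default 231 genes,
#'   200 samples each, noise sd 0.25 / 1 / 2); compares per-dataset
#'   ensembles, the naive pooled-samples ensemble, and the cross-dataset
#'   ensemble.
#'
#' @param template one of `"bootstrap"`, `"methods"`, `"datasets"`.
#' @param seed master seed.
#' @param n_genes,n_edges truth topology size.
#' @param n_samples samples per dataset.
#' @param noise_sd innovation noise sd (scalar; `"datasets"` takes a
#'   vector, one per dataset).
#' @param B bootstrap replicates.
#' @param sample_fraction bootstrap subsample fraction.
#' @param methods reconstruction methods for the ensemble templates.
#' @param workers parallelism degree.
#' @return a list with the simulated `truth`, the fitted networks, and an
#'   `evaluations` data.frame of AUC/AUPR per approach.
#' @export
run_experiment <- function(template = c("bootstrap", "methods", "datasets"),
                           seed = 1, n_genes = NULL, n_edges = NULL,
                           n_samples = NULL, noise_sd = NULL, B = NULL,
                           sample_fraction = 0.70,
                           methods = c("space", "shrinkage_pcor", "softcor"),
                           workers = 1) {
  template <- match.arg(template)
  switch(template,
    bootstrap = experiment_bootstrap(
      seed = seed,
      n_genes = n_genes %||% 231, n_edges = n_edges %||% 311,
      n_samples = n_samples %||% 20, noise_sd = noise_sd %||% 0.25,
      B = B %||% 100, sample_fraction = sample_fraction, workers = workers),
    methods = experiment_methods(
      seed = seed,
      n_genes = n_genes %||% 83, n_edges = n_edges %||% 114,
      n_samples = n_samples %||% 200, noise_sd = noise_sd %||% 0.25,
      B = B %||% 1, methods = methods, sample_fraction = sample_fraction,
      workers = workers),
    datasets = experiment_datasets(
      seed = seed,
      n_genes = n_genes %||% 231, n_edges = n_edges %||% 311,
      n_samples = n_samples %||% 200,
      noise_sd = noise_sd %||% c(0.25, 1, 2),
      B = B %||% 20, methods = methods, sample_fraction = sample_fraction,
      workers = workers))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

eval_row <- function(approach, net, truth) {
  ev <- evaluate_network(net, truth)
  data.frame(approach = approach, auc = ev$auc, aupr = ev$aupr)
}

experiment_bootstrap <- function(seed, n_genes, n_edges, n_samples, noise_sd,
                                 B, sample_fraction, workers) {
  truth <- generate_scale_free(n_genes, n_edges, seed = derive_seed(seed, 1))
  expr <- simulate_expression(truth, n_samples, noise_sd = noise_sd,
                              seed = derive_seed(seed, 2))
  single <- reconstruct_space(expr)
  config <- ensemble_config(B = B, sample_fraction = sample_fraction,
                            methods = "space", seed = derive_seed(seed, 3),
                            workers = workers)
  boot <- bootstrap_ena(expr, "space", config)
  evaluations <- rbind(eval_row("single_space", single, truth),
                       eval_row("bootstrap_space", boot, truth))
  list(template = "bootstrap", truth = truth, expr = expr,
       networks = list(single_space = single, bootstrap_space = boot),
       evaluations = evaluations, seed = seed)
}

experiment_methods <- function(seed, n_genes, n_edges, n_samples, noise_sd,
                               B, methods, sample_fraction, workers) {
  truth <- generate_scale_free(n_genes, n_edges, seed = derive_seed(seed, 1))
  expr <- simulate_expression(truth, n_samples, noise_sd = noise_sd,
                              seed = derive_seed(seed, 2))
  config <- ensemble_config(B = B, sample_fraction = sample_fraction,
                            methods = methods, seed = derive_seed(seed, 3),
                            workers = workers)
  singles <- lapply(methods, function(m) reconstruct_network(expr, m))
  names(singles) <- methods
  ensemble <- multimethod_ena(expr, config)
  evaluations <- do.call(rbind, c(
    lapply(methods, function(m) eval_row(m, singles[[m]], truth)),
    list(eval_row("multimethod_ena", ensemble, truth))))
  list(template = "methods", truth = truth, expr = expr,
       networks = c(singles, list(multimethod_ena = ensemble)),
       evaluations = evaluations, seed = seed)
}

experiment_datasets <- function(seed, n_genes, n_edges, n_samples, noise_sd,
                                B, methods, sample_fraction, workers) {
  truth <- generate_scale_free(n_genes, n_edges, seed = derive_seed(seed, 1))
  exprs <- lapply(seq_along(noise_sd), function(d) {
    simulate_expression(truth, n_samples, noise_sd = noise_sd[d],
                        seed = derive_seed(seed, 10 + d))
  })
  config <- ensemble_config(B = B, sample_fraction = sample_fraction,
                            methods = methods, seed = derive_seed(seed, 3),
                            workers = workers)
  per_dataset <- lapply(seq_along(exprs), function(d) {
    dconfig <- config
    dconfig$seed <- derive_seed(config$seed, 2000 + d)
    multimethod_ena(exprs[[d]], dconfig)
  })
  names(per_dataset) <- paste0("dataset_noise_", noise_sd)
  cross <- rank_product_aggregate(per_dataset)
  pooled_expr <- expression_matrix(
    do.call(cbind, lapply(seq_along(exprs), function(d) {
      m <- as_plain_matrix(as.matrix(exprs[[d]]))
      colnames(m) <- paste0("d", d, "_", colnames(m))
      m
    })))
  pconfig <- config
  pconfig$seed <- derive_seed(config$seed, 999)
  pooled <- multimethod_ena(pooled_expr, pconfig)
  evaluations <- do.call(rbind, c(
    lapply(seq_along(per_dataset), function(d) {
      eval_row(names(per_dataset)[d], per_dataset[[d]], truth)
    }),
    list(eval_row("pooled_samples", pooled, truth),
         eval_row("multidataset_ena", cross, truth))))
  list(template = "datasets", truth = truth, exprs = exprs,
       networks = c(per_dataset,
                    list(pooled_samples = pooled, multidataset_ena = cross)),
       evaluations = evaluations, seed = seed)
}
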