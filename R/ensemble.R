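#' Ensemble configuration
#'
#' @param B bootstrap replicates per method (>= 1). `B = 1` with
#'   `sample_fraction = 1` means a single plain reconstruction.
#' @param sample_fraction fraction of samples drawn per replicate, in
#'   `(0, 1]`. Replicates draw `ceiling(sample_fraction * n)` samples
#'   without replacement by default (the 70% subsampling scheme); set
#'   `replace = TRUE` for classical with-replacement resampling.
#' @param methods character subset of
#'   `c("space", "shrinkage_pcor", "softcor")`.
#' @param seed master seed; every replicate/method/dataset derives its own
#'   stream from it, so results do not depend on `workers`.
#' @param workers parallelism degree for bootstrap replicates
#'   (`parallel::mclapply`; forks, so > 1 has no effect on Windows).
#' @param replace draw bootstrap samples with replacement.
#' @param reconstruction_args named list of extra arguments per method,
#'   e.g. `list(space = list(lambda = 10))`.
#' @return a list of class `ensemble_config`.
#' @export
ensemble_config <- function(B = 100, sample_fraction = 0.70,
                            methods = c("space", "shrinkage_pcor", "softcor"),
                            seed = 1, workers = 1, replace = FALSE,
                            reconstruction_args = list()) {
  if (B < 1) stop_netaggr("B must be >= 1")
  if (sample_fraction <= 0 || sample_fraction > 1) {
    stop_netaggr("sample_fraction must be in (0, 1]")
  }
  methods <- match.arg(methods, c("space", "shrinkage_pcor", "softcor"),
                       several.ok = TRUE)
  if (!length(methods)) stop_netaggr("methods must be non-empty")
  structure(list(B = as.integer(B), sample_fraction = sample_fraction,
                 methods = methods, seed = as.integer(seed),
                 workers = as.integer(workers), replace = replace,
                 reconstruction_args = reconstruction_args),
            class = "ensemble_config")
}

method_args <- function(config, method) {
  args <- config$reconstruction_args[[method]]
  if (is.null(args)) list() else args
}

#' Bootstrap ensemble of one reconstruction method
#'
#' Rebuilds the network `B` times on random subsamples of the dataset
#' (by default 70% of samples, drawn without replacement) and merges the
#' `B` networks by the inverse rank product. Replicates use seeds derived
#' from `(config$seed, replicate index)`, so the result is bit-identical
#' for any `workers` value. Replicates whose reconstruction fails are
#' skipped with a warning; more than 20% failures is an error.
#'
#' @param expr an [expression_matrix()].
#' @param method reconstruction method name.
#' @param config an [ensemble_config()].
#' @return a [weighted_network()] of inverse-rank-product scores with
#'   provenance (replicate count, failures).
#' @export
bootstrap_ena <- function(expr, method = "space", config = ensemble_config()) {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  n_sub <- ceiling(config$sample_fraction * n)
  if (n_sub < 3) {
    stop_netaggr("sample_fraction * n gives ", n_sub,
                 " samples per replicate; need >= 3")
  }
  args <- method_args(config, method)
  one_replicate <- function(b) {
    idx <- with_seed(derive_seed(config$seed, b), {
      sample.int(n, n_sub, replace = config$replace)
    })
    tryCatch(
      do.call(reconstruct_network,
              c(list(expr = expression_matrix(expr[, idx, drop = FALSE],
                                              sample_ids = paste0("r", seq_len(n_sub))),
                     method = method), args)),
      error = function(e) structure(conditionMessage(e), class = "replicate_failure")
    )
  }
  nets <- if (config$workers > 1) {
    parallel::mclapply(seq_len(config$B), one_replicate,
                       mc.cores = config$workers)
  } else {
    lapply(seq_len(config$B), one_replicate)
  }
  failed <- vapply(nets, inherits, logical(1), "replicate_failure")
  if (any(failed)) {
    warning(sum(failed), " of ", config$B,
            " bootstrap replicates failed and were skipped (first: ",
            nets[[which(failed)[1]]], ")", call. = FALSE)
  }
  if (sum(failed) > 0.2 * config$B) {
    stop_netaggr("more than 20% of bootstrap replicates failed (",
                 sum(failed), "/", config$B, ")")
  }
  nets <- nets[!failed]
  out <- rank_product_aggregate(nets)
  prov <- attr(out, "provenance")
  prov$kind <- "bootstrap"
  prov$method <- method
  prov$B <- config$B
  prov$failures <- sum(failed)
  prov$sample_fraction <- config$sample_fraction
  attr(out, "provenance") <- prov
  out
}

#' Cross-method ensemble on one dataset
#'
#' Builds one network per reconstruction method (a bootstrap ensemble per
#' method when `config$B > 1`, a single full-data fit when `B == 1`) and
#' merges them by the inverse rank product, placing confidence on edges
#' that rank highly across all methods. A failing method is an error: a
#' cross-method ensemble with a missing member is not silently reduced.
#'
#' @param expr an [expression_matrix()].
#' @param config an [ensemble_config()] with >= 1 methods.
#' @return a [weighted_network()] of inverse-rank-product scores.
#' @export
multimethod_ena <- function(expr, config = ensemble_config()) {
  nets <- lapply(seq_along(config$methods), function(m) {
    method <- config$methods[m]
    mconfig <- config
    mconfig$seed <- derive_seed(config$seed, 1000 + m)
    if (config$B > 1) {
      bootstrap_ena(expr, method, mconfig)
    } else {
      do.call(reconstruct_network,
              c(list(expr = expr, method = method),
                method_args(config, method)))
    }
  })
  names(nets) <- config$methods
  out <- rank_product_aggregate(nets)
  prov <- attr(out, "provenance")
  prov$kind <- "multimethod"
  prov$B <- config$B
  attr(out, "provenance") <- prov
  out
}

#' Cross-dataset ensemble
#'
#' Restricts all datasets to the ordered intersection of their gene sets,
#' builds a cross-method ensemble per dataset, and merges the per-dataset
#' networks by the inverse rank product. With `flat = TRUE` the
#' per-dataset/per-method networks are instead pooled into one flat
#' aggregation.
#'
#' @param exprs list of >= 2 [expression_matrix()] objects.
#' @param config an [ensemble_config()].
#' @param flat aggregate all dataset-method networks in a single step
#'   instead of per-dataset ensembles first.
#' @return a [weighted_network()] over the common gene set.
#' @export
multidataset_ena <- function(exprs, config = ensemble_config(), flat = FALSE) {
  if (!is.list(exprs) || length(exprs) < 2) {
    stop_netaggr("need at least 2 datasets")
  }
  common <- Reduce(intersect, lapply(exprs, rownames))
  if (length(common) < 2) {
    stop_netaggr("gene sets share fewer than 2 genes")
  }
  dropped <- unique(unlist(lapply(exprs, function(e) {
    setdiff(rownames(e), common)
  })))
  if (length(dropped)) {
    warning("restricting to ", length(common),
            " shared genes; dropping: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ...", call. = FALSE)
  }
  exprs <- lapply(exprs, function(e) {
    expression_matrix(as.matrix(e)[common, , drop = FALSE])
  })
  per_dataset <- lapply(seq_along(exprs), function(d) {
    dconfig <- config
    dconfig$seed <- derive_seed(config$seed, 2000 + d)
    if (flat) {
      lapply(seq_along(config$methods), function(m) {
        method <- config$methods[m]
        mconfig <- dconfig
        mconfig$seed <- derive_seed(dconfig$seed, 1000 + m)
        if (config$B > 1) bootstrap_ena(exprs[[d]], method, mconfig)
        else do.call(reconstruct_network,
                     c(list(expr = exprs[[d]], method = method),
                       method_args(config, method)))
      })
    } else {
      multimethod_ena(exprs[[d]], dconfig)
    }
  })
  nets <- if (flat) unlist(per_dataset, recursive = FALSE) else per_dataset
  names(nets) <- NULL
  out <- rank_product_aggregate(nets)
  prov <- attr(out, "provenance")
  prov$kind <- if (flat) "multidataset_flat" else "multidataset"
  prov$n_datasets <- length(exprs)
  attr(out, "provenance") <- prov
  out
}
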