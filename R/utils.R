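#' Derive a reproducible child seed
#'
#' Deterministically maps a master seed plus one or more stream indices to a
#' new seed in `[1, 2^31 - 2]`. Used so that bootstrap replicates, methods
#' and datasets each consume an independent, worker-count-invariant random
#' stream.
#'
#' @param seed integer master seed.
#' @param ... integer stream indices (e.g. replicate number).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, Lehmer modulus
  x <- as.double(seed %% m)
  for (idx in c(...)) {
    x <- (x * 48271 + as.double(idx) * 16807 + 1) %% m
  }
  as.integer(x %% (m - 1) + 1)
}

# Run `expr` under a given seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# shared validation helpers ---------------------------------------------

stop_netaggr <- function(...) stop(..., call. = FALSE)

check_unique_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_netaggr("duplicate ", what, ": ", paste(dup, collapse = ", "))
  }
  invisible(ids)
}
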