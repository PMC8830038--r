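# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. Seeds must stay below 2^31 - 1.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Derive a reproducible child seed from a parent seed and an index, used so
# that parallel workers get independent but deterministic streams.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ls <- function(msg, ...) abort(sprintf(msg, ...), class = "lipidsite_error")

# lapply that honours a worker count while guaranteeing results independent
# of it: forked workers are only used for side-effect-free computations.
ls_lapply <- function(x, fun, n_workers = 1L) {
  n_workers <- max(1L, as.integer(n_workers))
  if (n_workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(x, fun, mc.cores = n_workers, mc.preschedule = TRUE)
  } else {
    lapply(x, fun)
  }
}
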