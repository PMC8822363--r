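# Internal helpers: seeded evaluation and seed fan-out.

check_seed <- function(seed) {
  if (length(seed) != 1 || !is.finite(seed) || seed != round(seed))
    stop("seed must be a single integer")
  as.integer(seed %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  seed <- check_seed(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic fan-out of one global seed into per-stage seeds. Documented
# counter scheme: stage k gets (seed + 104729 * k) mod (2^31 - 1).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(check_seed(seed)) + 104729 * as.numeric(k)) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
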