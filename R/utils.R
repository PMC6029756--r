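# Internal helpers: seeded RNG scopes and label-derived sub-seeds, so each
# generator consumes an independent, reproducible stream and never disturbs
# the caller's RNG state.

with_seed_local <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# deterministic 31-bit sub-seed from a base seed and a string label
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
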