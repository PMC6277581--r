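# run code with a temporary RNG state, restoring the caller's stream
with_seed_ <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single finite integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive independent sub-seeds from a master seed (kept within 32-bit range)
derive_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(.Machine$integer.max - 1L, n))
}
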