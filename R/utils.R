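# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive `n` stream seeds (< 2^31) from one base seed, reproducibly.
derive_seeds <- function(base_seed, n) {
  with_seed(base_seed, sample.int(.Machine$integer.max - 1L, n))
}

# dB reference: auditory-threshold convention, full scale = 1 pressure unit.
DB_REF <- 2e-5

db_from_power <- function(p) 10 * log10(p / DB_REF^2)
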