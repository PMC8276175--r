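# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.  All stochastic entry points funnel through this, so a run is
# fully reproducible from its seed.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: one global seed per run, sub-module
# seeds split off by fixed offsets so that independent stages draw from
# independent streams.  Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# Gauss error function (base R exposes only pnorm).
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || x > max || (!allow_zero && x == 0)) {
    abort(sprintf("`%s` = %g is outside the allowed range [%g, %g].",
                  name, x, min, max))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

# Energy deposited per unit volume per unit dose at unit density:
# 1 Gy = 1 J/kg and 1 keV = 1.602177e-16 J, so a cubic micrometre of
# water (1e-15 kg) receives 6.2415 keV per Gy.
KEV_PER_UM3_PER_GY <- 1e-15 / 1.602176634e-16
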