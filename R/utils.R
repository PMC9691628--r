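# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic generators in the package funnel through this
# so that a seed fixes every output byte.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a distinct child seed per generation stage so stages are
# independently reproducible. Kept below 2^31 - 1.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 7919L) %% 2147483587)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(min), format(max)))
  }
  invisible(x)
}

# Stable mean of a 0/1-ish percentage with NA for empty denominators.
percent_of <- function(n, total) {
  if (total == 0) return(NA_real_)
  100 * n / total
}
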