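# Internal helpers: seeding, validation, small numerics.

# Run `expr` under a temporary RNG state seeded from `seed`; restores the
# caller's .Random.seed afterwards so generators never perturb user RNG flow.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministic named substream: one user-level seed fans out to independent
# module streams. Kept below 2^31 - 1 (R integer range).
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 97)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper),
          class = "hushift_error_spec")
  }
  invisible(x)
}

check_values <- function(values, what = "sample") {
  if (!is.numeric(values) || length(values) == 0L) {
    abort(sprintf("%s must be a non-empty numeric vector", what),
          class = "hushift_error_input")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort(sprintf("%s contains non-finite values", what),
          class = "hushift_error_input")
  }
  invisible(values)
}

# Central moments m2..m4 -> skewness / non-excess kurtosis.
shape_from_central <- function(m2, m3, m4) {
  c(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}
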