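#' Wrap an angle into (-180, 180]
#'
#' @param x Angle(s) in degrees.
#' @return Numeric vector of the same length with values in `(-180, 180]`.
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.  All stochastic steps in the package go through
# this so that a single integer seed makes every pipeline stage reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive `n` independent 31-bit sub-seeds from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Parabolic (three-point quadratic) interpolation of an extremum.  Given
# scores at positions x-h, x, x+h with the middle one largest, returns the
# sub-grid offset in the same units as h, clamped to [-h, h].
parabolic_peak <- function(y_m, y_0, y_p, h) {
  denom <- y_m - 2 * y_0 + y_p
  if (!is.finite(denom) || abs(denom) < 1e-15) return(0)
  d <- 0.5 * (y_m - y_p) / denom * h
  max(min(d, h), -h)
}
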