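#' Centered running median
#'
#' Running median with an arbitrary (odd or even) window, used for trace
#' smoothing, movement-profile smoothing and spot-mobility smoothing. For an
#' odd window the half-width shrinks symmetrically near the series ends
#' (down to the raw value at the first and last sample), which keeps the
#' filter exact on linear series everywhere — a property the bleaching
#' normalization relies on. For an even window the window for index `i` is
#' `[i - k/2, i + k/2 - 1]`, clipped at the ends.
#'
#' @param x numeric vector.
#' @param k window width in samples (`k >= 1`).
#' @return numeric vector of the same length as `x`.
#' @export
run_median <- function(x, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  k <- as.integer(k)
  n <- length(x)
  if (n == 0L || k == 1L) return(x)
  if (k %% 2L == 1L) {
    hw <- k %/% 2L
    vapply(seq_len(n), function(i) {
      h <- min(hw, i - 1L, n - i)
      stats::median(x[(i - h):(i + h)])
    }, numeric(1))
  } else {
    lo <- k %/% 2L
    hi <- k %/% 2L - 1L
    vapply(seq_len(n), function(i) {
      stats::median(x[max(1L, i - lo):min(n, i + hi)])
    }, numeric(1))
  }
}

# Evaluate an expression with the RNG seeded locally, restoring the caller's
# RNG state afterwards so simulations are reproducible without clobbering the
# session seed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Ordinary least-squares straight line y ~ t; returns c(intercept, slope).
# Degenerate inputs (single time point or zero time variance) give a flat
# line at the mean.
fit_line <- function(t, y) {
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 2L || stats::var(t) == 0) {
    return(c(intercept = mean(y), slope = 0))
  }
  b <- stats::cov(t, y) / stats::var(t)
  a <- mean(y) - b * mean(t)
  c(intercept = a, slope = b)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# half-cosine ramp from 0 at u=0 to 1 at u=1, C1 at both ends; clamped outside
cos_ramp <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  0.5 * (1 - cos(pi * u))
}
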