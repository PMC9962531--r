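# Independent oracles used across the suite.

# Hand-coded Fritsch-Carlson monotone cubic Hermite interpolant, written
# directly from the classic algorithm: secant slopes, three-point tangent
# initialisation, and the circle-of-radius-3 tangent limiter. Serves as the
# independent route against the package's interpolant.
fc_interpolate <- function(x, y, xout) {
  n <- length(x)
  delta <- diff(y) / diff(x)
  m <- numeric(n)
  m[1] <- delta[1]
  m[n] <- delta[n - 1]
  if (n > 2) m[2:(n - 1)] <- (delta[-(n - 1)] + delta[-1]) / 2
  for (k in seq_len(n - 1)) {
    if (delta[k] == 0) {
      m[k] <- 0
      m[k + 1] <- 0
    } else {
      a <- m[k] / delta[k]
      b <- m[k + 1] / delta[k]
      s <- a^2 + b^2
      if (s > 9) {
        tau <- 3 / sqrt(s)
        m[k] <- tau * a * delta[k]
        m[k + 1] <- tau * b * delta[k]
      }
    }
  }
  vapply(xout, function(q) {
    k <- findInterval(q, x, all.inside = TRUE)
    h <- x[k + 1] - x[k]
    u <- (q - x[k]) / h
    h00 <- 2 * u^3 - 3 * u^2 + 1
    h10 <- u^3 - 2 * u^2 + u
    h01 <- -2 * u^3 + 3 * u^2
    h11 <- u^3 - u^2
    h00 * y[k] + h10 * h * m[k] + h01 * y[k + 1] + h11 * h * m[k + 1]
  }, numeric(1))
}

# Build a uniform-grid strain trace directly (bypassing the generators) for
# detector- and sensor-level tests.
make_strain <- function(elongation_mm, dt = 0.05) {
  t <- seq(0, by = dt, length.out = length(elongation_mm))
  out <- tibble::tibble(t_s = t, elongation_mm = elongation_mm)
  class(out) <- c("strain_trace", class(out))
  out
}

make_resistance <- function(resistance_kohm, dt = 0.05) {
  t <- seq(0, by = dt, length.out = length(resistance_kohm))
  out <- tibble::tibble(t_s = t, resistance_kohm = resistance_kohm)
  class(out) <- c("resistance_trace", class(out))
  out
}

default_gauge <- function(...) {
  fit_gauge_response(gauge_calibration_points(), ...)
}

# Replay the breathing generator's artifact draw (same RNG sequence) to get
# the artifact bump times independently of the waveform itself.
replay_artifact_times <- function(profile, duration_s) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(profile$seed)
  n <- stats::rpois(1, profile$artifact_rate_per_min * duration_s / 60)
  if (n == 0) numeric(0) else sort(stats::runif(n, 0, duration_s))
}

# Count complete triangular cycles by counting falling-to-rising turnarounds
# in the derivative sign — an independent route for the cycle-count identity.
count_triangle_cycles <- function(trace) {
  d <- sign(round(diff(trace$elongation_mm), 12))
  d <- d[d != 0]
  sum(d[-1] == 1 & d[-length(d)] == -1) + as.integer(d[length(d)] == -1)
}
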