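#' Calibration points of the printed textile gauge
#'
#' The printed sensor's calibration is expressed as the sensory coefficient —
#' the percent rise in resistance relative to the unstretched baseline,
#' `(R - R0)/R0 * 100` — measured at a set of tension distances. This helper
#' returns the packaged calibration table for the cotton + MWCNT + PPy print
#' (mean coefficients with standard deviation and coefficient of variation at
#' 5/10/15/20 mm).
#'
#' @return A tibble with columns `stretch_mm`, `coefficient_pct`, `sd_pct`,
#'   `cv`.
#' @examples
#' gauge_calibration_points()
#' @export
gauge_calibration_points <- function() {
  tibble::tibble(
    stretch_mm      = c(5, 10, 15, 20),
    coefficient_pct = c(27.49, 61.93, 89.89, 136.91),
    sd_pct          = c(3.13, 10.91, 12.04, 5.72),
    cv              = c(0.11, 0.18, 0.13, 0.04)
  )
}

#' Fit a gauge-response curve to calibration points
#'
#' Builds a monotone mapping from absolute elongation (mm) to relative
#' resistance rise (percent) through the origin and every calibration point.
#' The default interpolant is the Fritsch--Carlson monotone shape-preserving
#' cubic (`stats::splinefun(method = "monoH.FC")`), which reproduces each
#' calibration point exactly; beyond the last point the curve continues as a
#' power law fitted to the last two points. A pure least-squares linear mode
#' (`mode = "linear"`, through the origin) is available but does not
#' interpolate the points exactly.
#'
#' @param points Data frame with columns `stretch_mm` (> 0, distinct) and
#'   `coefficient_pct` (>= 0, non-decreasing in stretch). At least two points.
#' @param R0_kohm Baseline (unstretched) sensor resistance, kOhm. The default
#'   150 kOhm gives breath-scale resistance swings large enough to clear the
#'   detector's 80 kOhm susceptibility at a 10 mm stretch.
#' @param hysteresis_ratio Unloading gain divided by loading gain, in (0, 1];
#'   1 disables hysteresis.
#' @param relaxation_tau_s Time constant of the exponential relaxation of the
#'   unloading branch toward the loading branch, s.
#' @param mode `"monotone_cubic"` (default) or `"linear"`.
#' @return An object of class `gauge_response`.
#' @examples
#' gr <- fit_gauge_response(gauge_calibration_points())
#' gauge_coefficient(gr, c(0, 5, 10))
#' @export
fit_gauge_response <- function(points,
                               R0_kohm = 150,
                               hysteresis_ratio = 1,
                               relaxation_tau_s = 1,
                               mode = c("monotone_cubic", "linear")) {
  mode <- match.arg(mode)
  points <- tibble::as_tibble(points)
  if (!all(c("stretch_mm", "coefficient_pct") %in% names(points))) {
    rlang::abort("`points` needs columns `stretch_mm` and `coefficient_pct`.")
  }
  points <- dplyr::arrange(points, .data$stretch_mm)
  s <- points$stretch_mm
  cc <- points$coefficient_pct
  if (length(s) < 2L) rlang::abort("Need at least 2 calibration points.")
  if (any(s <= 0)) rlang::abort("Calibration stretches must be > 0.")
  if (anyDuplicated(s)) rlang::abort("Calibration stretches must be distinct.")
  if (any(cc < 0)) rlang::abort("Sensory coefficients must be >= 0.")
  dec <- which(diff(cc) < 0)
  if (length(dec) > 0) {
    i <- dec[1]
    rlang::abort(sprintf(
      "Calibration set is not monotone: coefficient drops from %.4g%% at %g mm to %.4g%% at %g mm.",
      cc[i], s[i], cc[i + 1], s[i + 1]))
  }
  check_number(R0_kohm, "R0_kohm", 0, strict_lower = TRUE)
  check_number(hysteresis_ratio, "hysteresis_ratio", 0, 1, strict_lower = TRUE)
  check_number(relaxation_tau_s, "relaxation_tau_s", 0, strict_lower = TRUE)

  s_knots <- c(0, s)
  c_knots <- c(0, cc)
  s_max <- s[length(s)]
  c_max <- cc[length(cc)]

  if (mode == "monotone_cubic") {
    interp <- stats::splinefun(s_knots, c_knots, method = "monoH.FC")
    # power-law continuation beyond the last knot, matched at the knot
    p <- if (length(s) >= 2 && cc[length(cc) - 1] > 0) {
      log(c_max / cc[length(cc) - 1]) / log(s_max / s[length(s) - 1])
    } else 1
    curve <- function(x) {
      x <- pmax(x, 0)
      out <- numeric(length(x))
      inside <- x <= s_max
      out[inside] <- interp(x[inside])
      out[!inside] <- c_max * (x[!inside] / s_max)^p
      out
    }
  } else {
    slope <- sum(s * cc) / sum(s * s)  # least squares through the origin
    p <- 1
    curve <- function(x) pmax(x, 0) * slope
  }

  structure(
    list(points = points, R0_kohm = R0_kohm, curve = curve,
         hysteresis_ratio = hysteresis_ratio,
         relaxation_tau_s = relaxation_tau_s,
         mode = mode, extrapolation_exponent = p),
    class = "gauge_response"
  )
}

#' Query a fitted gauge-response curve
#'
#' @param response A [fit_gauge_response()] object.
#' @param stretch_mm Elongations to evaluate at, mm (>= 0).
#' @return Sensory coefficients, percent.
#' @export
gauge_coefficient <- function(response, stretch_mm) {
  stopifnot(inherits(response, "gauge_response"))
  if (any(stretch_mm < 0)) rlang::abort("`stretch_mm` must be >= 0.")
  response$curve(stretch_mm)
}

#' @export
print.gauge_response <- function(x, ...) {
  cat(sprintf(
    "<gauge_response> R0 = %g kOhm, %d calibration points (%s), hysteresis ratio %g\n",
    x$R0_kohm, nrow(x$points), x$mode, x$hysteresis_ratio))
  invisible(x)
}

#' @export
tidy.gauge_response <- function(x, ...) {
  dplyr::mutate(x$points,
                fitted_pct = gauge_coefficient(x, .data$stretch_mm),
                residual_pct = .data$coefficient_pct - .data$fitted_pct)
}

#' @export
glance.gauge_response <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    R0_kohm = x$R0_kohm,
    n_points = nrow(x$points),
    mode = x$mode,
    hysteresis_ratio = x$hysteresis_ratio,
    max_abs_residual_pct = max(abs(td$residual_pct)),
    extrapolation_exponent = x$extrapolation_exponent
  )
}

#' Plot a fitted gauge-response curve with its calibration points
#'
#' @param object A `gauge_response`.
#' @param max_stretch_mm Right edge of the plotted stretch range, mm.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gauge_response <- function(object, max_stretch_mm = NULL, ...) {
  if (is.null(max_stretch_mm)) {
    max_stretch_mm <- 1.1 * max(object$points$stretch_mm)
  }
  grid <- tibble::tibble(stretch_mm = seq(0, max_stretch_mm, length.out = 200))
  grid$coefficient_pct <- gauge_coefficient(object, grid$stretch_mm)
  ggplot2::ggplot(grid, ggplot2::aes(.data$stretch_mm,
                                     .data$coefficient_pct)) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::geom_point(data = object$points, size = 2) +
    ggplot2::labs(x = "Stretch (mm)", y = "Sensory coefficient (%)") +
    ggplot2::theme_minimal()
}

#' Measurement-noise specification for the simulated sensor
#'
#' @param resistance_sd_kohm Standard deviation of additive Gaussian
#'   resistance noise, kOhm (>= 0; 0 disables noise).
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(resistance_sd_kohm = 0, seed = 1L) {
  check_number(resistance_sd_kohm, "resistance_sd_kohm", 0)
  structure(list(resistance_sd_kohm = resistance_sd_kohm,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

new_resistance_trace <- function(t, resistance, dt) {
  out <- tibble::tibble(t_s = t, resistance_kohm = resistance)
  attr(out, "dt") <- dt
  class(out) <- c("resistance_trace", class(out))
  out
}

#' Sensor resistance along a strain trace
#'
#' Maps elongation to resistance through the calibrated gauge response:
#' `R(t) = R0 * (1 + curve(elongation(t)) / 100)` on the loading branch. With
#' `hysteresis_ratio < 1` the unloading branch moves with a reduced gain, and
#' the resulting excess resistance relaxes exponentially toward the loading
#' branch with time constant `relaxation_tau_s`, so a full load--unload cycle
#' returns to `R0` after a few time constants. Optional Gaussian measurement
#' noise is seeded and clipped so resistance stays positive.
#'
#' @param strain A `strain_trace` tibble (`t_s`, `elongation_mm`).
#' @param response A [fit_gauge_response()] object.
#' @param noise A [noise_spec()]; default noise-free.
#' @return A `resistance_trace` tibble (`t_s`, `resistance_kohm`).
#' @examples
#' gr <- fit_gauge_response(gauge_calibration_points())
#' st <- instron_waveform(instron_protocol(beam_speed_mm_min = 240))
#' rt <- resistance_at(st, gr)
#' range(rt$resistance_kohm)
#' @export
resistance_at <- function(strain, response, noise = noise_spec()) {
  stopifnot(inherits(response, "gauge_response"),
            inherits(noise, "noise_spec"))
  if (!all(c("t_s", "elongation_mm") %in% names(strain))) {
    rlang::abort("`strain` needs columns `t_s` and `elongation_mm`.")
  }
  if (any(!is.finite(strain$elongation_mm)) ||
      any(strain$elongation_mm < 0)) {
    rlang::abort("`strain` elongation must be finite and >= 0.")
  }
  dt <- check_uniform_grid(strain$t_s, "strain")

  r_load <- response$R0_kohm *
    (1 + response$curve(strain$elongation_mm) / 100)

  h <- response$hysteresis_ratio
  if (h < 1) {
    # Two-branch hysteresis: unloading changes resistance with gain h; the
    # retained excess decays toward the loading branch with time constant tau.
    decay <- exp(-dt / response$relaxation_tau_s)
    n <- length(r_load)
    excess <- numeric(n)
    for (i in 2:n) {
      d <- r_load[i] - r_load[i - 1]
      e <- excess[i - 1] * decay
      if (d < 0) e <- e - (1 - h) * d       # retain (1-h) of each drop
      excess[i] <- e
    }
    r <- r_load + excess
  } else {
    r <- r_load
  }

  if (noise$resistance_sd_kohm > 0) {
    r <- with_seed(noise$seed, {
      r + stats::rnorm(length(r), 0, noise$resistance_sd_kohm)
    })
    r <- pmax(r, 1e-6)  # resistance must stay positive
  }
  new_resistance_trace(strain$t_s, r, dt)
}

#' Sensory coefficient of a resistance reading
#'
#' The percent relative resistance change of the gauge,
#' `(R - R0) / R0 * 100`.
#'
#' @param R0_kohm Baseline resistance, kOhm (> 0).
#' @param R_kohm Measured resistance(s), kOhm.
#' @return Percent relative change (vectorised over `R_kohm`).
#' @examples
#' sensory_coefficient(100, 200)  # 100%
#' @export
sensory_coefficient <- function(R0_kohm, R_kohm) {
  check_number(R0_kohm, "R0_kohm", 0, strict_lower = TRUE)
  (R_kohm - R0_kohm) / R0_kohm * 100
}

#' Plot a resistance trace
#'
#' @param object A `resistance_trace` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.resistance_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_s, .data$resistance_kohm)) +
    ggplot2::geom_line(colour = "#1b9e77") +
    ggplot2::labs(x = "Time (s)", y = "Resistance (kOhm)") +
    ggplot2::theme_minimal()
}
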