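#' Constant-speed testing-machine stretch protocol
#'
#' Describes the cyclic clamp-displacement programme of a tensile testing
#' machine used as a mechanical breath simulator: the clamps move apart at a
#' constant beam speed until `stretch_distance_mm` is reached, then return at
#' the same speed, giving a triangular elongation wave. The cycle frequency in
#' cycles per minute is `beam_speed / (2 * stretch_distance)`, so a 10 mm
#' stretch at 160 mm/min simulates 8 breaths per minute.
#'
#' @param gauge_length_mm Distance between the clamps, mm (default 100).
#' @param stretch_distance_mm Peak elongation per cycle, mm; must not exceed
#'   the gauge length.
#' @param beam_speed_mm_min Constant crosshead speed, mm/min; 0 means no
#'   motion.
#' @param duration_s Protocol duration, s.
#' @return An object of class `instron_protocol`.
#' @examples
#' instron_protocol(stretch_distance_mm = 10, beam_speed_mm_min = 240)
#' @export
instron_protocol <- function(gauge_length_mm = 100,
                             stretch_distance_mm = 10,
                             beam_speed_mm_min = 240,
                             duration_s = 60) {
  check_number(gauge_length_mm, "gauge_length_mm", 0, strict_lower = TRUE)
  check_number(stretch_distance_mm, "stretch_distance_mm", 0,
               strict_lower = TRUE)
  check_number(beam_speed_mm_min, "beam_speed_mm_min", 0)
  check_number(duration_s, "duration_s", 0, strict_lower = TRUE)
  if (stretch_distance_mm > gauge_length_mm) {
    rlang::abort("`stretch_distance_mm` must not exceed `gauge_length_mm`.")
  }
  structure(
    list(gauge_length_mm = gauge_length_mm,
         stretch_distance_mm = stretch_distance_mm,
         beam_speed_mm_min = beam_speed_mm_min,
         duration_s = duration_s),
    class = "instron_protocol"
  )
}

#' @export
print.instron_protocol <- function(x, ...) {
  cpm <- if (x$beam_speed_mm_min > 0) {
    x$beam_speed_mm_min / (2 * x$stretch_distance_mm)
  } else 0
  cat(sprintf(
    "<instron_protocol> gauge %g mm, stretch %g mm, speed %g mm/min (%g cycles/min), %g s\n",
    x$gauge_length_mm, x$stretch_distance_mm, x$beam_speed_mm_min, cpm,
    x$duration_s))
  invisible(x)
}

#' Stochastic human-breathing strain profile
#'
#' Parameterises a synthetic chest-expansion waveform: raised-cosine elongation
#' pulses of height `depth_mm`, paced by a piecewise-constant rate schedule,
#' with optional additive Gaussian noise, linear baseline drift and
#' Poisson-timed motion artifacts. A zero rate anywhere in the schedule
#' produces a flat (apnoeic) segment. The same profile and seed always
#' reproduce the identical trace.
#'
#' @param rate_schedule Data frame (or tibble) with columns `start_s` and
#'   `rate_bpm`: the breathing rate in breaths per minute from each start time
#'   onwards. A single number is shorthand for a constant rate from t = 0.
#' @param depth_mm Peak elongation of one breath, mm.
#' @param inspiration_fraction Fraction of the breath period spent inhaling
#'   (rising), strictly between 0 and 1.
#' @param artifact_rate_per_min Expected number of motion-artifact bumps per
#'   minute (Poisson-timed).
#' @param artifact_amplitude_mm Peak height of an artifact bump, mm.
#' @param artifact_width_s Width of an artifact bump, s.
#' @param drift_slope_mm_min Linear baseline drift, mm per minute.
#' @param noise_sd_mm Standard deviation of additive Gaussian elongation
#'   noise, mm (must be >= 0).
#' @param seed Integer seed controlling noise and artifacts.
#' @return An object of class `breathing_profile`.
#' @examples
#' breathing_profile(rate_schedule = 12, depth_mm = 10)
#' @export
breathing_profile <- function(rate_schedule = 12,
                              depth_mm = 10,
                              inspiration_fraction = 0.4,
                              artifact_rate_per_min = 0,
                              artifact_amplitude_mm = 0,
                              artifact_width_s = 0.5,
                              drift_slope_mm_min = 0,
                              noise_sd_mm = 0,
                              seed = 1L) {
  if (is.numeric(rate_schedule) && is.null(dim(rate_schedule)) &&
      length(rate_schedule) == 1L) {
    rate_schedule <- tibble::tibble(start_s = 0, rate_bpm = rate_schedule)
  }
  rate_schedule <- tibble::as_tibble(rate_schedule)
  if (!all(c("start_s", "rate_bpm") %in% names(rate_schedule))) {
    rlang::abort("`rate_schedule` needs columns `start_s` and `rate_bpm`.")
  }
  if (nrow(rate_schedule) < 1L || any(rate_schedule$rate_bpm < 0)) {
    rlang::abort("`rate_schedule` rates must be >= 0.")
  }
  rate_schedule <- dplyr::arrange(rate_schedule, .data$start_s)
  check_number(depth_mm, "depth_mm", 0, strict_lower = TRUE)
  check_number(inspiration_fraction, "inspiration_fraction", 0, 1,
               strict_lower = TRUE)
  if (inspiration_fraction >= 1) {
    rlang::abort("`inspiration_fraction` must be < 1.")
  }
  check_number(artifact_rate_per_min, "artifact_rate_per_min", 0)
  check_number(artifact_amplitude_mm, "artifact_amplitude_mm", 0)
  check_number(artifact_width_s, "artifact_width_s", 0, strict_lower = TRUE)
  check_number(drift_slope_mm_min, "drift_slope_mm_min")
  check_number(noise_sd_mm, "noise_sd_mm", 0)
  structure(
    list(rate_schedule = rate_schedule,
         depth_mm = depth_mm,
         inspiration_fraction = inspiration_fraction,
         artifact_rate_per_min = artifact_rate_per_min,
         artifact_amplitude_mm = artifact_amplitude_mm,
         artifact_width_s = artifact_width_s,
         drift_slope_mm_min = drift_slope_mm_min,
         noise_sd_mm = noise_sd_mm,
         seed = as.integer(seed)),
    class = "breathing_profile"
  )
}

#' @export
print.breathing_profile <- function(x, ...) {
  cat(sprintf(
    "<breathing_profile> depth %g mm, %d schedule segment(s), noise sd %g mm, seed %d\n",
    x$depth_mm, nrow(x$rate_schedule), x$noise_sd_mm, x$seed))
  invisible(x)
}

new_strain_trace <- function(t, elongation, dt) {
  out <- tibble::tibble(t_s = t, elongation_mm = elongation)
  attr(out, "dt") <- dt
  class(out) <- c("strain_trace", class(out))
  out
}

#' Triangular stretch waveform of a constant-speed testing machine
#'
#' Samples the clamp elongation of an [instron_protocol()] on a uniform time
#' grid. The elongation ramps 0 -> stretch -> 0 at constant speed, so the
#' wave is triangular with cycle period `2 * stretch_distance / speed`.
#'
#' @param protocol An [instron_protocol()].
#' @param dt Sampling interval, s (default 0.05 s, i.e. 20 Hz). Must not
#'   exceed the half-cycle duration, otherwise the wave would be aliased.
#' @return A tibble with columns `t_s` and `elongation_mm` (class
#'   `strain_trace`).
#' @examples
#' tr <- instron_waveform(instron_protocol(beam_speed_mm_min = 160))
#' range(tr$elongation_mm)
#' @export
instron_waveform <- function(protocol, dt = 0.05) {
  stopifnot(inherits(protocol, "instron_protocol"))
  check_number(dt, "dt", 0, strict_lower = TRUE)
  speed_mm_s <- protocol$beam_speed_mm_min / 60
  t <- seq(0, protocol$duration_s, by = dt)
  if (speed_mm_s == 0) {
    return(new_strain_trace(t, rep(0, length(t)), dt))
  }
  half_cycle_s <- protocol$stretch_distance_mm / speed_mm_s
  if (dt > half_cycle_s) {
    rlang::abort(sprintf(
      "`dt` (%g s) exceeds the half-cycle duration (%g s); the triangular wave would alias.",
      dt, half_cycle_s))
  }
  period_s <- 2 * half_cycle_s
  phase <- (t %% period_s) / period_s                  # 0..1 within a cycle
  elong <- protocol$stretch_distance_mm *
    (1 - abs(2 * phase - 1))                           # triangle 0->max->0
  new_strain_trace(t, elong, dt)
}

# Elongation of a single raised-cosine breath at phase u in [0, 1), with
# asymmetric inspiration fraction f: rise over [0, f], fall over [f, 1].
breath_pulse <- function(u, f) {
  ifelse(u < f,
         0.5 * (1 - cos(pi * u / f)),
         0.5 * (1 + cos(pi * (u - f) / (1 - f))))
}

#' Synthetic human-breathing strain waveform
#'
#' Generates a chest-expansion elongation trace from a [breathing_profile()]:
#' consecutive raised-cosine breath pulses paced by the rate schedule, plus
#' seeded Gaussian noise, linear drift and Poisson-timed artifact bumps.
#' Elongation is clipped at zero so the strain-trace invariant (elongation
#' >= 0) always holds. Only breaths whose full period fits inside `duration_s`
#' are emitted, so a constant integer rate r over 60 s yields exactly r
#' pulses.
#'
#' @param profile A [breathing_profile()].
#' @param duration_s Trace duration, s.
#' @param dt Sampling interval, s (default 0.05).
#' @return A `strain_trace` tibble (`t_s`, `elongation_mm`).
#' @examples
#' tr <- breathing_waveform(breathing_profile(rate_schedule = 12), 60)
#' max(tr$elongation_mm)
#' @export
breathing_waveform <- function(profile, duration_s = 60, dt = 0.05) {
  stopifnot(inherits(profile, "breathing_profile"))
  check_number(duration_s, "duration_s", 0, strict_lower = TRUE)
  check_number(dt, "dt", 0, strict_lower = TRUE)

  sched <- profile$rate_schedule
  seg_end <- c(sched$start_s[-1], Inf)
  rate_at <- function(time) {
    i <- findInterval(time, sched$start_s)
    if (i < 1L) 0 else sched$rate_bpm[i]
  }

  # Sequential breath onsets: each breath occupies 60/rate seconds; zero-rate
  # segments are skipped (apnea).
  onsets <- numeric(0)
  periods <- numeric(0)
  now <- min(sched$start_s[1], 0)
  eps <- 1e-9
  while (now < duration_s - eps) {
    r <- rate_at(now)
    if (r <= 0) {
      i <- findInterval(now, sched$start_s)
      nxt <- if (i >= 1L && is.finite(seg_end[i])) seg_end[i] else duration_s
      now <- max(nxt, now + dt)
      next
    }
    period <- 60 / r
    if (now + period <= duration_s + eps) {
      onsets <- c(onsets, now)
      periods <- c(periods, period)
    }
    now <- now + period
  }

  t <- seq(0, duration_s, by = dt)
  elong <- numeric(length(t))
  f <- profile$inspiration_fraction
  for (k in seq_along(onsets)) {
    idx <- which(t >= onsets[k] - eps & t < onsets[k] + periods[k] - eps)
    u <- (t[idx] - onsets[k]) / periods[k]
    elong[idx] <- elong[idx] + profile$depth_mm * breath_pulse(u, f)
  }

  elong <- elong + profile$drift_slope_mm_min * t / 60

  with_seed(profile$seed, {
    if (profile$artifact_rate_per_min > 0 &&
        profile$artifact_amplitude_mm > 0) {
      n_art <- stats::rpois(1, profile$artifact_rate_per_min * duration_s / 60)
      if (n_art > 0) {
        art_t <- sort(stats::runif(n_art, 0, duration_s))
        w <- profile$artifact_width_s
        for (a in art_t) {
          idx <- which(t >= a & t < a + w)
          u <- (t[idx] - a) / w
          elong[idx] <- elong[idx] +
            profile$artifact_amplitude_mm * 0.5 * (1 - cos(2 * pi * u))
        }
      }
    }
    if (profile$noise_sd_mm > 0) {
      elong <- elong + stats::rnorm(length(t), 0, profile$noise_sd_mm)
    }
  })

  new_strain_trace(t, pmax(elong, 0), dt)
}

#' Plot a strain trace
#'
#' @param object A `strain_trace` tibble from [instron_waveform()] or
#'   [breathing_waveform()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.strain_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_s, .data$elongation_mm)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "Time (s)", y = "Elongation (mm)") +
    ggplot2::theme_minimal()
}
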