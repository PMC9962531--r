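#' Breath-detector configuration
#'
#' The detector follows the slope of the reconstructed sensor resistance with
#' a delta variable (previous minus current sample). A rising run accumulates
#' resistance rise since the last trough; when the rise ends, a peak (breath)
#' is marked only if the accumulated rise reached the susceptibility
#' threshold. The susceptibility defaults to 80 kOhm, which controls the
#' algorithm's stability against small fluctuations; counting uses
#' consecutive (tumbling) windows of `window_s` seconds, by default one
#' minute.
#'
#' @param susceptibility_kohm Minimum accumulated resistance rise to mark a
#'   peak, kOhm (> 0; default 80).
#' @param window_s Counting-window length, s (default 60).
#' @param mode `"cumulative"` (default: threshold on the rise accumulated
#'   since the last trough) or `"per_sample"` (threshold on the single-step
#'   rise preceding the turn, a stricter reading of the original firmware).
#' @param smooth_n Optional moving-average pre-filter width in samples; 1
#'   (default) disables smoothing, matching the original program.
#' @return An object of class `detector_config`.
#' @examples
#' detector_config()
#' @export
detector_config <- function(susceptibility_kohm = 80, window_s = 60,
                            mode = c("cumulative", "per_sample"),
                            smooth_n = 1L) {
  mode <- match.arg(mode)
  check_number(susceptibility_kohm, "susceptibility_kohm", 0,
               strict_lower = TRUE)
  check_number(window_s, "window_s", 0, strict_lower = TRUE)
  check_number(smooth_n, "smooth_n", 1)
  structure(list(susceptibility_kohm = susceptibility_kohm,
                 window_s = window_s, mode = mode,
                 smooth_n = as.integer(smooth_n)),
            class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf("<detector_config> susceptibility %g kOhm, window %g s, mode %s\n",
              x$susceptibility_kohm, x$window_s, x$mode))
  invisible(x)
}

#' Detect breaths in a resistance trace
#'
#' Scans the samples in order, maintaining `delta = previous - current`
#' resistance. `delta <= 0` means the resistance is rising (inhalation; flat
#' samples count as rising), `delta > 0` that it is falling (exhalation). At
#' the first falling sample after a rising run, a peak is marked at the
#' preceding sample iff the rise accumulated since the last trough reached
#' the susceptibility threshold; the accumulator then resets. Peak counts are
#' tallied over consecutive half-open windows `[k*window, (k+1)*window)`
#' starting at the first sample time.
#'
#' @param trace A `resistance_trace` tibble (`t_s`, `resistance_kohm`) on a
#'   uniform grid with at least 2 samples and no flagged/missing samples.
#' @param cfg A [detector_config()].
#' @return An object of class `breath_events` with elements `peaks` (tibble
#'   `peak_time_s`, `rise_kohm`), `windows` (tibble `window_start_s`,
#'   `count`), `window_s` and `duration_s`.
#' @examples
#' gr <- fit_gauge_response(gauge_calibration_points())
#' st <- instron_waveform(instron_protocol(beam_speed_mm_min = 240))
#' ev <- detect_breaths(acquire(resistance_at(st, gr)))
#' breaths_per_minute(ev)
#' @export
detect_breaths <- function(trace, cfg = detector_config()) {
  stopifnot(inherits(cfg, "detector_config"))
  if (!all(c("t_s", "resistance_kohm") %in% names(trace))) {
    rlang::abort("`trace` needs columns `t_s` and `resistance_kohm`.")
  }
  if ("open_circuit" %in% names(trace) && any(trace$open_circuit)) {
    rlang::abort(paste(
      "`trace` contains open-circuit (flagged) samples;",
      "drop or repair them before detection."))
  }
  r <- trace$resistance_kohm
  if (any(!is.finite(r))) {
    rlang::abort("`trace` resistance must be finite for detection.")
  }
  check_uniform_grid(trace$t_s, "trace")
  t <- trace$t_s

  if (cfg$smooth_n > 1L) {
    k <- cfg$smooth_n
    r <- as.numeric(stats::filter(r, rep(1 / k, k), sides = 2))
    keep <- !is.na(r)
    r <- r[keep]
    t <- t[keep]
  }

  n <- length(r)
  peak_t <- numeric(0)
  peak_rise <- numeric(0)
  rise <- 0
  last_step <- 0
  for (i in 2:n) {
    d <- r[i] - r[i - 1]            # -delta of the firmware
    if (d >= 0) {                   # delta <= 0: rising (flat counts as rise)
      rise <- rise + d
      last_step <- d
    } else {                        # delta > 0: rising run (if any) has ended
      if (rise > 0) {
        marked <- if (cfg$mode == "cumulative") {
          rise >= cfg$susceptibility_kohm
        } else {
          last_step >= cfg$susceptibility_kohm
        }
        if (marked) {
          peak_t <- c(peak_t, t[i - 1])
          peak_rise <- c(peak_rise, rise)
        }
      }
      rise <- 0
      last_step <- 0
    }
  }

  duration <- t[n] - t[1]
  starts <- seq(t[1], t[n], by = cfg$window_s)
  windows <- tibble::tibble(
    window_start_s = starts,
    count = vapply(starts, function(s0) {
      sum(peak_t >= s0 & peak_t < s0 + cfg$window_s)
    }, integer(1))
  )

  structure(
    list(peaks = tibble::tibble(peak_time_s = peak_t, rise_kohm = peak_rise),
         windows = windows,
         window_s = cfg$window_s,
         duration_s = duration,
         t_range = range(t)),
    class = "breath_events"
  )
}

#' @export
print.breath_events <- function(x, ...) {
  cat(sprintf("<breath_events> %d peak(s) over %g s; window %g s\n",
              nrow(x$peaks), x$duration_s, x$window_s))
  invisible(x)
}

#' @export
tidy.breath_events <- function(x, ...) x$peaks

#' @export
glance.breath_events <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x$peaks),
    duration_s = x$duration_s,
    window_s = x$window_s,
    rate_bpm = tryCatch(breaths_per_minute(x, allow_partial = TRUE),
                        error = function(e) NA_real_)
  )
}

#' Breaths per minute from detected events
#'
#' Returns the peak count of the most recent complete counting window. For
#' traces shorter than one window, the count can be scaled by
#' `60 / duration` when `allow_partial = TRUE`; otherwise the situation is
#' signalled as an error. `rolling = TRUE` instead counts peaks in the
#' trailing `window_s` seconds of the trace.
#'
#' @param events A [detect_breaths()] result.
#' @param allow_partial Scale a shorter-than-window trace up to 60 s?
#' @param rolling Use a trailing window ending at the last sample instead of
#'   tumbling windows?
#' @return Breaths per minute (numeric).
#' @export
breaths_per_minute <- function(events, allow_partial = FALSE,
                               rolling = FALSE) {
  stopifnot(inherits(events, "breath_events"))
  w <- events$window_s
  if (rolling) {
    t_end <- events$t_range[2]
    n <- sum(events$peaks$peak_time_s > t_end - w &
               events$peaks$peak_time_s <= t_end)
    return(n * 60 / w)
  }
  complete <- events$windows$window_start_s + w <=
    events$t_range[1] + events$duration_s + 1e-9
  if (!any(complete)) {
    if (!allow_partial) {
      rlang::abort(paste(
        "No complete counting window; rerun with `allow_partial = TRUE`",
        "to scale the partial count."))
    }
    return(nrow(events$peaks) * 60 / events$duration_s)
  }
  last <- max(which(complete))
  events$windows$count[last] * 60 / w
}

#' Respiratory-rate reference ranges by age group
#'
#' The default classification table, with half-open bands `[min_bpm,
#' max_bpm)`. Adult bands close the gaps of the clinical reference ranges
#' conservatively: apnea up to about two breaths per minute, bradypnea below
#' normal (the clinical band is 8--10), normal 12--16, hyperpnea around 20
#' (band 17--24), tachypnea above 24. Pediatric groups use age-specific
#' normal ranges (e.g. newborn and infant 30--60, toddler 24--40,
#' preschooler 22--34, school age 18--30) with rates below labelled
#' bradypnea and above labelled tachypnea. The table can be overridden in
#' [classify_rate()].
#'
#' @return A tibble with columns `age_group`, `label`, `min_bpm`, `max_bpm`;
#'   a rate r is labelled by the row with `min_bpm <= r < max_bpm`.
#' @examples
#' respiratory_rate_table()
#' @export
respiratory_rate_table <- function() {
  from_breaks <- function(group, breaks, labels) {
    tibble::tibble(age_group = group, label = labels,
                   min_bpm = breaks[-length(breaks)], max_bpm = breaks[-1])
  }
  adult_labels <- c("apnea", "bradypnea", "normal", "hyperpnea", "tachypnea")
  ped_labels <- c("apnea", "bradypnea", "normal", "tachypnea")
  dplyr::bind_rows(
    from_breaks("adult", c(0, 3, 12, 17, 25, Inf), adult_labels),
    from_breaks("adolescent", c(0, 3, 12, 17, 25, Inf), adult_labels),
    from_breaks("newborn", c(0, 3, 30, 61, Inf), ped_labels),
    from_breaks("infant", c(0, 3, 30, 61, Inf), ped_labels),
    from_breaks("toddler", c(0, 3, 24, 41, Inf), ped_labels),
    from_breaks("preschooler", c(0, 3, 22, 35, Inf), ped_labels),
    from_breaks("school_age", c(0, 3, 18, 31, Inf), ped_labels)
  )
}

#' Classify a respiratory rate
#'
#' Labels a rate as apnea, bradypnea, normal, hyperpnea or tachypnea using
#' the configured range table for the given age group. Bands are half-open
#' `[min_bpm, max_bpm)`, so adult defaults give 9 -> bradypnea, 14 ->
#' normal, 20 -> hyperpnea, 25 -> tachypnea.
#'
#' @param rate_bpm Respiratory rate(s), breaths per minute (>= 0).
#' @param age_group One of the groups in the table (default `"adult"`).
#' @param table A range table as returned by [respiratory_rate_table()].
#' @return A tibble with columns `rate_bpm`, `age_group`, `label`.
#' @examples
#' classify_rate(c(9, 14, 25))
#' classify_rate(45, "newborn")
#' @export
classify_rate <- function(rate_bpm, age_group = "adult",
                          table = respiratory_rate_table()) {
  if (any(rate_bpm < 0)) rlang::abort("`rate_bpm` must be >= 0.")
  groups <- unique(table$age_group)
  if (!age_group %in% groups) {
    rlang::abort(sprintf("Unknown age_group '%s'. Valid groups: %s.",
                         age_group, paste(groups, collapse = ", ")))
  }
  bands <- table[table$age_group == age_group, ]
  label <- vapply(rate_bpm, function(r) {
    hit <- which(r >= bands$min_bpm & r < bands$max_bpm)
    if (length(hit) == 0) NA_character_ else bands$label[hit[1]]
  }, character(1))
  tibble::tibble(rate_bpm = rate_bpm, age_group = age_group, label = label)
}

#' Plot detected breaths over their counting windows
#'
#' @param object A `breath_events` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.breath_events <- function(object, ...) {
  ggplot2::ggplot(object$windows,
                  ggplot2::aes(.data$window_start_s, .data$count)) +
    ggplot2::geom_col(fill = "#7570b3", width = 0.8 * object$window_s) +
    ggplot2::geom_rug(data = object$peaks,
                      ggplot2::aes(x = .data$peak_time_s), inherit.aes = FALSE,
                      sides = "b") +
    ggplot2::labs(x = "Window start (s)", y = "Breaths per window") +
    ggplot2::theme_minimal()
}
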