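#' Built-in breath-simulator scenarios
#'
#' The four testing-machine breath-simulation protocols used to validate the
#' counting chain: a 10 cm gauge stretched by 10 mm at beam speeds of
#' 160/240/400/480 mm/min, giving 8, 12, 20 and 24 cycles (simulated breaths)
#' per minute respectively.
#'
#' @return A tibble with columns `name`, `beam_speed_mm_min`,
#'   `expected_rate_bpm`.
#' @examples
#' scenario_presets()
#' @export
scenario_presets <- function() {
  tibble::tibble(
    name = c("bradypnea", "normal", "hyperpnea", "tachypnea"),
    beam_speed_mm_min = c(160, 240, 400, 480),
    expected_rate_bpm = c(8, 12, 20, 24)
  )
}

#' Assemble a full-chain scenario configuration
#'
#' Bundles a stimulus (exactly one of an [instron_protocol()] or a
#' [breathing_profile()]) with the sensor, acquisition and detector settings
#' into a single self-describing configuration for [run_scenario()].
#'
#' @param name Scenario label.
#' @param stimulus An `instron_protocol` or `breathing_profile`.
#' @param sensor A [fit_gauge_response()] object.
#' @param acquisition An [acquisition_config()].
#' @param detector A [detector_config()].
#' @param noise A [noise_spec()] applied to the sensor resistance.
#' @param duration_s Trace duration, s (breathing stimulus only; an
#'   `instron_protocol` carries its own duration).
#' @param dt Sampling interval, s.
#' @param age_group Age group for rate classification.
#' @param expected_rate_bpm Optional expected breaths per minute; carried
#'   into the result for comparison.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name = "scenario",
                            stimulus = instron_protocol(),
                            sensor = fit_gauge_response(gauge_calibration_points()),
                            acquisition = acquisition_config(),
                            detector = detector_config(),
                            noise = noise_spec(),
                            duration_s = 60,
                            dt = 0.05,
                            age_group = "adult",
                            expected_rate_bpm = NULL) {
  if (!inherits(stimulus, "instron_protocol") &&
      !inherits(stimulus, "breathing_profile")) {
    rlang::abort(
      "`stimulus` must be an instron_protocol or a breathing_profile.")
  }
  stopifnot(inherits(sensor, "gauge_response"),
            inherits(acquisition, "acquisition_config"),
            inherits(detector, "detector_config"),
            inherits(noise, "noise_spec"))
  check_number(duration_s, "duration_s", 0, strict_lower = TRUE)
  check_number(dt, "dt", 0, strict_lower = TRUE)
  if (!is.null(expected_rate_bpm)) {
    check_number(expected_rate_bpm, "expected_rate_bpm", 0)
  }
  structure(
    list(name = name, stimulus = stimulus, sensor = sensor,
         acquisition = acquisition, detector = detector, noise = noise,
         duration_s = duration_s, dt = dt, age_group = age_group,
         expected_rate_bpm = expected_rate_bpm),
    class = "scenario_config"
  )
}

#' One of the four built-in breath-simulator scenarios
#'
#' Convenience constructor: looks up a preset from [scenario_presets()] and
#' builds the corresponding [scenario_config()] with default sensor,
#' acquisition and detector settings and noise disabled.
#'
#' @param name One of `"bradypnea"`, `"normal"`, `"hyperpnea"`,
#'   `"tachypnea"`.
#' @param ... Overrides passed on to [scenario_config()].
#' @return A `scenario_config`.
#' @examples
#' run_scenario(scenario_instron("normal"))$rate_bpm
#' @export
scenario_instron <- function(name, ...) {
  presets <- scenario_presets()
  row <- presets[presets$name == name, ]
  if (nrow(row) != 1L) {
    rlang::abort(sprintf("Unknown scenario '%s'. Choose one of: %s.", name,
                         paste(presets$name, collapse = ", ")))
  }
  scenario_config(
    name = name,
    stimulus = instron_protocol(gauge_length_mm = 100,
                                stretch_distance_mm = 10,
                                beam_speed_mm_min = row$beam_speed_mm_min,
                                duration_s = 60),
    expected_rate_bpm = row$expected_rate_bpm,
    ...
  )
}

#' Run a full sensing-chain scenario
#'
#' Executes stimulus -> sensor resistance -> divider/ADC acquisition ->
#' breath detection -> rate classification, returning every intermediate
#' trace. Deterministic given the seeds inside the configuration. When
#' `out_dir` is given, the strain, resistance and acquired traces plus the
#' detected peaks and a one-row summary are written there as CSVs.
#'
#' @param cfg A [scenario_config()].
#' @param out_dir Optional output directory for CSVs.
#' @param verbose Narrate the chain to the console?
#' @return An object of class `scenario_result`: list with `config`,
#'   `strain`, `resistance`, `acquired`, `events`, `rate_bpm`,
#'   `classification` and `summary` (one-row tibble).
#' @examples
#' res <- run_scenario(scenario_instron("bradypnea"))
#' res$summary
#' @export
run_scenario <- function(cfg, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  strain <- if (inherits(cfg$stimulus, "instron_protocol")) {
    instron_waveform(cfg$stimulus, dt = cfg$dt)
  } else {
    breathing_waveform(cfg$stimulus, duration_s = cfg$duration_s, dt = cfg$dt)
  }
  say("[%s] generated %d strain samples (dt = %g s)", cfg$name,
      nrow(strain), cfg$dt)

  resistance <- resistance_at(strain, cfg$sensor, cfg$noise)
  acquired <- acquire(resistance, cfg$acquisition)
  if (any(acquired$open_circuit)) {
    say("[%s] %d open-circuit samples flagged and dropped", cfg$name,
        sum(acquired$open_circuit))
    acquired_det <- acquired[!acquired$open_circuit, ]
  } else {
    acquired_det <- acquired
  }
  events <- detect_breaths(acquired_det, cfg$detector)
  rate <- breaths_per_minute(events, allow_partial = TRUE)
  cls <- classify_rate(rate, cfg$age_group)
  say("[%s] %d peaks -> %g breaths/min (%s)", cfg$name, nrow(events$peaks),
      rate, cls$label)

  summary <- tibble::tibble(
    name = cfg$name,
    n_samples = nrow(strain),
    n_peaks = nrow(events$peaks),
    rate_bpm = rate,
    label = cls$label,
    expected_rate_bpm = cfg$expected_rate_bpm %||% NA_real_,
    rate_matches_expected = if (is.null(cfg$expected_rate_bpm)) NA else
      isTRUE(all.equal(rate, cfg$expected_rate_bpm))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_strain_trace(strain, file.path(out_dir,
                                         paste0(cfg$name, "_strain.csv")))
    write_resistance_trace(resistance,
                           file.path(out_dir,
                                     paste0(cfg$name, "_resistance.csv")))
    write_resistance_trace(acquired,
                           file.path(out_dir,
                                     paste0(cfg$name, "_acquired.csv")))
    readr::write_csv(events$peaks,
                     file.path(out_dir, paste0(cfg$name, "_peaks.csv")))
    readr::write_csv(summary,
                     file.path(out_dir, paste0(cfg$name, "_summary.csv")))
  }

  structure(
    list(config = cfg, strain = strain, resistance = resistance,
         acquired = acquired, events = events, rate_bpm = rate,
         classification = cls, summary = summary),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> '%s': %d peaks, %g breaths/min (%s)\n",
              x$config$name, nrow(x$events$peaks), x$rate_bpm,
              x$classification$label))
  invisible(x)
}

#' @export
glance.scenario_result <- function(x, ...) x$summary

#' Plot a scenario's acquired resistance with detected peaks
#'
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_result <- function(object, ...) {
  acq <- object$acquired
  pk <- object$events$peaks
  pk$resistance_kohm <- acq$resistance_kohm[match(pk$peak_time_s, acq$t_s)]
  ggplot2::ggplot(acq, ggplot2::aes(.data$t_s, .data$resistance_kohm)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = pk,
                        ggplot2::aes(.data$peak_time_s,
                                     .data$resistance_kohm),
                        colour = "#d95f02", size = 2) +
    ggplot2::labs(
      x = "Time (s)", y = "Reconstructed resistance (kOhm)",
      title = sprintf("%s: %g breaths/min", object$config$name,
                      object$rate_bpm)) +
    ggplot2::theme_minimal()
}

#' Device-versus-reference agreement on paired breath counts
#'
#' Computes the mean absolute error and mean bias (device minus reference)
#' over paired counts from a wearable device and a reference system.
#'
#' @param pairs Data frame with columns `device` and `reference`
#'   (non-negative counts); any other columns (e.g. a condition label) are
#'   kept in the result. At least one pair.
#' @return An object of class `agreement_result`: list with `pairs` (with a
#'   `difference` column added), `mae` and `bias`.
#' @examples
#' agreement(respiratory_agreement_pairs())
#' @export
agreement <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("device", "reference") %in% names(pairs))) {
    rlang::abort("`pairs` needs columns `device` and `reference`.")
  }
  if (nrow(pairs) < 1L) rlang::abort("`pairs` must contain at least one pair.")
  if (any(pairs$device < 0) || any(pairs$reference < 0)) {
    rlang::abort("Counts must be non-negative.")
  }
  pairs <- dplyr::mutate(pairs, difference = .data$device - .data$reference)
  structure(
    list(pairs = pairs,
         mae = mean(abs(pairs$difference)),
         bias = mean(pairs$difference)),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> %d pairs: MAE %.3f, bias %+.3f breaths/min\n",
              nrow(x$pairs), x$mae, x$bias))
  invisible(x)
}

#' @export
tidy.agreement_result <- function(x, ...) x$pairs

#' @export
glance.agreement_result <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs), mae = x$mae, bias = x$bias)
}

#' Bland-Altman-style plot of an agreement result
#'
#' @param object An `agreement_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_result <- function(object, ...) {
  df <- dplyr::mutate(object$pairs,
                      mean_count = (.data$device + .data$reference) / 2)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_count, .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 2) +
    ggplot2::geom_point(size = 2, colour = "#1b9e77") +
    ggplot2::labs(x = "Mean of device and reference (breaths/min)",
                  y = "Device - reference (breaths/min)") +
    ggplot2::theme_minimal()
}

#' Packaged shirt-versus-reference respiratory-rate pairs
#'
#' The paired breath counts recorded with the sensing shirt and a reference
#' system across exercise intensities (MET, metabolic equivalent of task;
#' carried as a label only). Shipped as a CSV fixture under `extdata`.
#'
#' @return A tibble with columns `met`, `device`, `reference`.
#' @examples
#' respiratory_agreement_pairs()
#' @export
respiratory_agreement_pairs <- function() {
  path <- system.file("extdata", "respiratory_agreement_pairs.csv",
                      package = "pneumotex", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
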