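test_that("constant and sub-threshold traces yield no peaks", {
  cfg <- detector_config(susceptibility_kohm = 80)
  expect_equal(nrow(detect_breaths(make_resistance(rep(150, 100)),
                                   cfg)$peaks), 0)
  # 40 kOhm oscillation amplitude stays below an 80 kOhm threshold
  t <- seq(0, 60, by = 0.05)
  osc <- make_resistance(150 + 20 * sin(2 * pi * t / 5))
  expect_equal(nrow(detect_breaths(osc, cfg)$peaks), 0)
})

test_that("a single supra-threshold excursion is exactly one peak", {
  up <- seq(150, 250, length.out = 50)      # 100 kOhm rise
  down <- seq(250, 150, length.out = 50)[-1]
  tr <- make_resistance(c(up, down, rep(150, 20)))
  ev <- detect_breaths(tr, detector_config(susceptibility_kohm = 80))
  expect_equal(nrow(ev$peaks), 1)
  expect_equal(ev$peaks$rise_kohm, 100, tolerance = 1e-9)
  # the peak is timestamped at the apex sample
  expect_equal(ev$peaks$peak_time_s, tr$t_s[50])
})

test_that("flat samples inside a rise do not break the accumulated rise", {
  # rise 50, plateau, rise 50 more, then fall: one 100 kOhm rising run
  r <- c(seq(150, 200, length.out = 20), rep(200, 10),
         seq(200, 250, length.out = 20), seq(250, 150, length.out = 20))
  ev <- detect_breaths(make_resistance(r),
                       detector_config(susceptibility_kohm = 80))
  expect_equal(nrow(ev$peaks), 1)
})

test_that("full chain at 240 mm/min counts 12 breaths per minute", {
  res <- run_scenario(scenario_instron("normal"))
  expect_equal(nrow(res$events$peaks), 12)
  expect_equal(res$rate_bpm, 12)
})

test_that("detection is invariant to a constant resistance offset", {
  t <- seq(0, 60, by = 0.05)
  base <- 150 + 60 * pmax(sin(2 * pi * t / 6), 0) +
    45 * pmax(sin(2 * pi * t / 6 + 0.4), 0)
  for (offset in c(-40, 0, 35, 500)) {
    tr <- make_resistance(base + offset)
    ev <- detect_breaths(tr, detector_config(susceptibility_kohm = 80))
    if (offset == -40) ref <- ev
    expect_equal(ev$peaks$peak_time_s, ref$peaks$peak_time_s,
                 info = sprintf("offset %g", offset))
    expect_equal(ev$windows$count, ref$windows$count)
  }
})

test_that("peak count is non-increasing in susceptibility", {
  res <- run_scenario(scenario_instron("tachypnea"))
  trace <- res$acquired
  counts <- vapply(c(10, 40, 80, 95, 200), function(s) {
    nrow(detect_breaths(trace, detector_config(susceptibility_kohm = s))$peaks)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[[5]], 0)  # threshold above the full dynamic range
})

test_that("clean full-chain simulations recover the generator rate exactly", {
  gr <- default_gauge()
  for (rate in c(4, 7, 10, 14, 18, 22, 26, 30)) {
    st <- breathing_waveform(breathing_profile(rate_schedule = rate,
                                               depth_mm = 10), 60)
    ev <- detect_breaths(acquire(resistance_at(st, gr)))
    expect_equal(breaths_per_minute(ev), rate, info = sprintf("rate %g", rate))
  }
})

test_that("artifact bumps change counts only when supra-threshold", {
  gr <- default_gauge()
  # an apnoeic profile isolates the artifacts from real breaths
  apnea <- function(amp, seed = 5L) {
    breathing_profile(rate_schedule = tibble::tibble(start_s = 0,
                                                     rate_bpm = 0),
                      depth_mm = 10, artifact_rate_per_min = 6,
                      artifact_amplitude_mm = amp, seed = seed)
  }
  chain <- function(profile) {
    detect_breaths(acquire(resistance_at(breathing_waveform(profile, 60), gr)))
  }

  # sub-threshold artifacts: 2 mm bumps (~10 kOhm rise) mark no peaks
  expect_equal(nrow(chain(apnea(2))$peaks), 0)

  # supra-threshold 10 mm bumps each add exactly one false breath, provided
  # the bumps land apart and inside the trace (verified by replaying the
  # generator's artifact draw)
  art_t <- replay_artifact_times(apnea(10), 60)
  stopifnot(length(art_t) > 0, all(diff(art_t) > 1),
            all(art_t < 59), all(art_t > 0.5))
  expect_equal(nrow(chain(apnea(10))$peaks), length(art_t))

  # superimposed on breathing, sub-threshold artifacts leave counts alone
  # when they fall clear of the inspiratory upslopes (an artifact landing on
  # an inspiration can split its rising run and suppress that breath)
  clean <- breathing_profile(rate_schedule = 12, depth_mm = 10, seed = 8L)
  noisy <- breathing_profile(rate_schedule = 12, depth_mm = 10,
                             artifact_rate_per_min = 6,
                             artifact_amplitude_mm = 2, seed = 8L)
  art <- replay_artifact_times(noisy, 60)
  phase <- art %% 5  # breaths at 12/min: inspiration covers [5k, 5k + 2)
  stopifnot(all(phase > 2 & phase + noisy$artifact_width_s < 5))
  expect_equal(nrow(chain(noisy)$peaks), nrow(chain(clean)$peaks))
})

test_that("breaths_per_minute uses the last complete window and scales partials", {
  t <- seq(0, 120, by = 0.05)
  tr <- make_resistance(150 + 80 * pmax(sin(2 * pi * t / 5), 0) +
                          20 * pmax(sin(2 * pi * t / 5 + 0.3), 0))
  ev <- detect_breaths(tr, detector_config(susceptibility_kohm = 80))
  expect_equal(breaths_per_minute(ev), 12)  # 5 s period -> 12 per window

  short <- make_resistance(tr$resistance_kohm[t <= 30])
  ev_s <- detect_breaths(short, detector_config(susceptibility_kohm = 80))
  expect_error(breaths_per_minute(ev_s), "complete")
  expect_equal(breaths_per_minute(ev_s, allow_partial = TRUE),
               nrow(ev_s$peaks) * 2)
})

test_that("window-boundary peaks belong to the window containing them", {
  # peaks exactly at t = 0, 60 with window 60: [0,60) and [60,120)
  ev <- structure(
    list(peaks = tibble::tibble(peak_time_s = c(0, 59.99, 60),
                                rise_kohm = 100),
         windows = NULL, window_s = 60, duration_s = 120, t_range = c(0, 120)),
    class = "breath_events")
  # rebuild windows exactly as the detector does
  tr <- make_resistance(rep(150, 2401))
  full <- detect_breaths(tr, detector_config())
  expect_equal(full$windows$window_start_s[1:2], c(0, 60))
  w1 <- sum(ev$peaks$peak_time_s >= 0 & ev$peaks$peak_time_s < 60)
  w2 <- sum(ev$peaks$peak_time_s >= 60 & ev$peaks$peak_time_s < 120)
  expect_equal(c(w1, w2), c(2, 1))
})

test_that("degenerate traces are rejected", {
  expect_error(detect_breaths(make_resistance(numeric(0))), "at least 2")
  expect_error(detect_breaths(make_resistance(150)), "at least 2")
  bad <- tibble::tibble(t_s = c(0, 1, 3), resistance_kohm = c(1, 2, 3))
  expect_error(detect_breaths(bad), "uniform")
})

test_that("per-sample mode requires a single-step rise above threshold", {
  # gradual 100 kOhm rise over many samples: cumulative mode fires,
  # per-sample mode does not
  r <- c(seq(150, 250, length.out = 100), seq(250, 150, length.out = 50))
  cum <- detect_breaths(make_resistance(r),
                        detector_config(susceptibility_kohm = 80))
  per <- detect_breaths(make_resistance(r),
                        detector_config(susceptibility_kohm = 80,
                                        mode = "per_sample"))
  expect_equal(nrow(cum$peaks), 1)
  expect_equal(nrow(per$peaks), 0)
  # a single 90 kOhm jump fires in both modes
  r2 <- c(150, 150, 240, 150, 150)
  per2 <- detect_breaths(make_resistance(r2),
                         detector_config(susceptibility_kohm = 80,
                                         mode = "per_sample"))
  expect_equal(nrow(per2$peaks), 1)
})

test_that("rate classification follows the configured range table", {
  expect_equal(classify_rate(c(9, 14, 20, 25))$label,
               c("bradypnea", "normal", "hyperpnea", "tachypnea"))
  expect_equal(classify_rate(2)$label, "apnea")
  expect_equal(classify_rate(45, "newborn")$label, "normal")
  expect_equal(classify_rate(45, "toddler")$label, "tachypnea")
  expect_equal(classify_rate(20, "school_age")$label, "normal")
  expect_error(classify_rate(10, "elder"), "Valid groups")

  # user-overridable table
  custom <- tibble::tibble(age_group = "adult",
                           label = c("low", "high"),
                           min_bpm = c(0, 15), max_bpm = c(15, Inf))
  expect_equal(classify_rate(c(3, 30), table = custom)$label,
               c("low", "high"))
})
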