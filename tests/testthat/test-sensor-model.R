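test_that("fitted gauge response interpolates every calibration point", {
  gr <- default_gauge()
  pts <- gauge_calibration_points()
  expect_equal(gauge_coefficient(gr, pts$stretch_mm), pts$coefficient_pct,
               tolerance = 1e-12)
  expect_equal(gauge_coefficient(gr, 0), 0)
})

test_that("interpolant agrees with an independent Fritsch-Carlson oracle", {
  gr <- default_gauge()
  pts <- gauge_calibration_points()
  q <- c(1, 2.5, 7.5, 9.9, 12.3, 14, 17.7, 19.9)
  oracle <- fc_interpolate(c(0, pts$stretch_mm), c(0, pts$coefficient_pct), q)
  expect_equal(gauge_coefficient(gr, q), oracle, tolerance = 1e-10)
  # bracketing by monotonicity at the midpoint between two knots
  v <- gauge_coefficient(gr, 7.5)
  expect_gt(v, 27.49)
  expect_lt(v, 61.93)
})

test_that("gauge curve is non-decreasing, with power-law extrapolation", {
  gr <- default_gauge()
  grid <- seq(0, 30, by = 0.05)
  expect_true(all(diff(gauge_coefficient(gr, grid)) >= -1e-12))
  # beyond the last knot the curve continues as a power law through it
  p <- gr$extrapolation_exponent
  expect_equal(gauge_coefficient(gr, 25), 136.91 * (25 / 20)^p,
               tolerance = 1e-12)
})

test_that("non-monotone calibration sets are rejected, naming the pair", {
  bad <- tibble::tibble(stretch_mm = c(5, 10, 15),
                        coefficient_pct = c(30, 25, 40))
  expect_error(fit_gauge_response(bad), "5 mm.*10 mm|not monotone")
  expect_error(fit_gauge_response(tibble::tibble(stretch_mm = 5,
                                                 coefficient_pct = 10)),
               "at least 2")
  expect_error(fit_gauge_response(tibble::tibble(stretch_mm = c(0, 5),
                                                 coefficient_pct = c(0, 10))),
               "> 0")
})

test_that("linear mode fits the stated linear growth without exact interpolation", {
  gr <- default_gauge(mode = "linear")
  grid <- seq(0, 25, 0.5)
  vals <- gauge_coefficient(gr, grid)
  expect_equal(vals, grid * vals[length(vals)] / 25, tolerance = 1e-12)
  expect_gt(max(abs(gauge_coefficient(gr, c(5, 10, 15, 20)) -
                      gauge_calibration_points()$coefficient_pct)), 0.1)
})

test_that("hold at a calibration stretch reproduces R0 * (1 + coeff/100)", {
  gr <- default_gauge(R0_kohm = 150)
  hold <- make_strain(rep(10, 50))
  rt <- resistance_at(hold, gr)
  # 61.93% at 10 mm: 150 * 1.6193 = 242.895 kOhm
  expect_equal(unique(rt$resistance_kohm), 242.895, tolerance = 1e-9)

  flat <- make_strain(rep(0, 50))
  expect_equal(unique(resistance_at(flat, gr)$resistance_kohm), 150)
})

test_that("sensory coefficient is the percent relative resistance change", {
  expect_equal(sensory_coefficient(100, 200), 100)
  expect_equal(sensory_coefficient(150, 150), 0)
  expect_equal(sensory_coefficient(150, 242.895), 61.93, tolerance = 1e-9)
  expect_error(sensory_coefficient(0, 100), "> 0")
})

test_that("round trip: held stretch -> resistance -> coefficient recovers the curve", {
  gr <- default_gauge(R0_kohm = 150)
  for (s in c(gauge_calibration_points()$stretch_mm, 7.5, 12.5)) {
    rt <- resistance_at(make_strain(rep(s, 10)), gr)
    got <- sensory_coefficient(150, rt$resistance_kohm[5])
    expect_equal(got, gauge_coefficient(gr, s),
                 tolerance = 1e-9, info = sprintf("stretch %g", s))
  }
})

test_that("noise-free resistance is monotone in held elongation", {
  gr <- default_gauge()
  holds <- seq(0, 25, by = 0.5)
  r <- vapply(holds, function(s) {
    resistance_at(make_strain(rep(s, 5)), gr)$resistance_kohm[3]
  }, numeric(1))
  expect_true(all(diff(r) >= -1e-12))
})

test_that("hysteresis loop closes after relaxation and has non-negative area", {
  # one full load-unload triangle, then a rest long past 5 * tau
  cyc <- instron_waveform(instron_protocol(stretch_distance_mm = 10,
                                           beam_speed_mm_min = 240,
                                           duration_s = 5), dt = 0.01)
  rest <- make_strain(rep(0, 1500), dt = 0.01)
  rest$t_s <- rest$t_s + max(cyc$t_s) + 0.01
  full <- dplyr::bind_rows(cyc, rest)
  class(full) <- class(cyc)

  gr_h <- default_gauge(hysteresis_ratio = 0.7, relaxation_tau_s = 1)
  rt <- resistance_at(full, gr_h)
  expect_equal(rt$resistance_kohm[nrow(rt)], 150, tolerance = 1e-3)

  # loop area over one cycle: integral of (r_up - r_down) d(elongation)
  gr_1 <- default_gauge(hysteresis_ratio = 1)
  one <- instron_waveform(instron_protocol(stretch_distance_mm = 10,
                                           beam_speed_mm_min = 240,
                                           duration_s = 5), dt = 0.01)
  area <- function(gr) {
    r <- resistance_at(one, gr)$resistance_kohm
    -sum(0.5 * (r[-1] + r[-length(r)]) * diff(one$elongation_mm))
  }
  expect_equal(area(gr_1), 0, tolerance = 1e-9)
  expect_gt(area(gr_h), 0)
  # unloading branch sits above the loading branch
  r_h <- resistance_at(one, gr_h)$resistance_kohm
  r_1 <- resistance_at(one, gr_1)$resistance_kohm
  expect_true(all(r_h - r_1 >= -1e-12))
})

test_that("resistance noise is seeded, clipped positive, and reproducible", {
  gr <- default_gauge()
  st <- make_strain(rep(2, 200))
  a <- resistance_at(st, gr, noise_spec(5, seed = 9L))
  b <- resistance_at(st, gr, noise_spec(5, seed = 9L))
  expect_identical(a$resistance_kohm, b$resistance_kohm)
  expect_true(all(a$resistance_kohm > 0))
  expect_gt(stats::sd(a$resistance_kohm), 0)
  expect_error(noise_spec(-1), ">= 0")
})

test_that("tidy and glance report the calibration fit", {
  gr <- default_gauge()
  td <- tidy(gr)
  expect_equal(td$residual_pct, rep(0, 4), tolerance = 1e-12)
  gl <- glance(gr)
  expect_equal(gl$R0_kohm, 150)
  expect_equal(gl$n_points, 4L)
  expect_lt(gl$max_abs_residual_pct, 1e-10)
})

test_that("calibration CSV fixture matches the packaged table", {
  path <- system.file("extdata", "gauge_calibration_cotton_mwcnt_ppy.csv",
                      package = "pneumotex")
  pts <- read_calibration_points(path)
  expect_equal(pts$stretch_mm, gauge_calibration_points()$stretch_mm)
  expect_equal(pts$coefficient_pct, gauge_calibration_points()$coefficient_pct)
})
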