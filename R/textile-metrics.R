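#' Surface mass (mass per unit area) of a fabric sample
#'
#' `M_p = m / (La * Sa)` in g/m^2, from the mass of the acclimatised sample
#' and its length and width.
#'
#' @param m_g Sample mass, g (> 0).
#' @param La_m Sample length, m (> 0).
#' @param Sa_m Sample width, m (> 0).
#' @return Surface mass, g/m^2.
#' @examples
#' surface_mass(12.6092, 0.2, 0.2)  # a 400 cm^2 sample
#' @export
surface_mass <- function(m_g, La_m, Sa_m) {
  check_number(m_g, "m_g", 0, strict_lower = TRUE)
  check_number(La_m, "La_m", 0, strict_lower = TRUE)
  check_number(Sa_m, "Sa_m", 0, strict_lower = TRUE)
  m_g / (La_m * Sa_m)
}

#' Air permeability of a fabric sample
#'
#' `R = (qv_mean / A) * 167` in mm/s, from the mean air flow through the
#' test head and its area; 167 is the conversion factor from dm^3/min over
#' cm^2 to mm/s.
#'
#' @param qv_mean_dm3_min Arithmetic-mean air flow, dm^3/min (>= 0).
#' @param A_cm2 Test area, cm^2 (> 0); the common permeability-tester head
#'   is 20 cm^2.
#' @return Air permeability, mm/s.
#' @examples
#' air_permeability(8.24, 20)
#' @export
air_permeability <- function(qv_mean_dm3_min, A_cm2 = 20) {
  check_number(qv_mean_dm3_min, "qv_mean_dm3_min", 0)
  check_number(A_cm2, "A_cm2", 0, strict_lower = TRUE)
  qv_mean_dm3_min / A_cm2 * 167
}

#' Thermal resistance of a fabric on a guarded hot plate
#'
#' `Rct = (Tm - Ta) * A / (H - dHc) - Rct0` in m^2 K/W: plate-to-air
#' temperature difference times plate area over the corrected heating power,
#' minus the bare-plate resistance.
#'
#' @param Tm_C Measuring-plate temperature, degrees C.
#' @param Ta_C Air temperature, degrees C.
#' @param A_m2 Plate area, m^2 (> 0).
#' @param H_W Heating power, W.
#' @param dHc_W Heating-power correction, W; `H - dHc` must be > 0.
#' @param Rct0 Thermal resistance of the uncovered plate, m^2 K/W.
#' @return Thermal resistance, m^2 K/W.
#' @examples
#' thermal_resistance(35, 20, 1, 15, 0, 0)
#' @export
thermal_resistance <- function(Tm_C, Ta_C, A_m2, H_W, dHc_W = 0, Rct0 = 0) {
  check_number(Tm_C, "Tm_C")
  check_number(Ta_C, "Ta_C")
  check_number(A_m2, "A_m2", 0, strict_lower = TRUE)
  check_number(H_W, "H_W")
  check_number(dHc_W, "dHc_W")
  check_number(Rct0, "Rct0")
  if (H_W - dHc_W <= 0) {
    rlang::abort("`H_W - dHc_W` must be > 0 (corrected heating power).")
  }
  (Tm_C - Ta_C) * A_m2 / (H_W - dHc_W) - Rct0
}

#' Replicate summary statistics: mean, sd, coefficient of variation
#'
#' The summary used for replicate textile measurements: arithmetic mean,
#' sample standard deviation (n - 1 denominator) and cv = sd / mean.
#'
#' @param values Numeric vector of at least 2 replicate measurements.
#' @return A tibble with columns `n`, `mean`, `sd`, `cv` (cv is `NA` when
#'   the mean is 0).
#' @examples
#' summarize_replicates(c(27.1, 27.9, 27.5))
#' @export
summarize_replicates <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || any(!is.finite(values))) {
    rlang::abort("`values` must be >= 2 finite numbers.")
  }
  m <- mean(values)
  s <- stats::sd(values)
  tibble::tibble(n = length(values), mean = m, sd = s,
                 cv = if (m != 0) s / m else NA_real_)
}
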