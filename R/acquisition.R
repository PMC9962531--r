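#' Voltage-divider and ADC configuration
#'
#' Parameters of the microcontroller-side measurement front end: the known
#' series resistor `R1` between the analog pin and ground, the supply voltage
#' `U` across the divider, and the ADC bit depth and reference voltage. The
#' defaults (R1 = 10 kOhm, U = 5 V, 10-bit ADC referenced to the supply)
#' match a typical Arduino prototype.
#'
#' @param R1_kohm Known divider resistor, kOhm (> 0).
#' @param U_volts Supply voltage, V (> 0).
#' @param bits ADC resolution, bits (>= 1).
#' @param Uref_volts ADC reference voltage, V; defaults to the supply.
#' @return An object of class `acquisition_config`.
#' @examples
#' acquisition_config()
#' @export
acquisition_config <- function(R1_kohm = 10, U_volts = 5, bits = 10,
                               Uref_volts = U_volts) {
  check_number(R1_kohm, "R1_kohm", 0, strict_lower = TRUE)
  check_number(U_volts, "U_volts", 0, strict_lower = TRUE)
  check_number(bits, "bits", 1)
  if (bits != round(bits)) rlang::abort("`bits` must be an integer.")
  check_number(Uref_volts, "Uref_volts", 0, strict_lower = TRUE)
  structure(list(R1_kohm = R1_kohm, U_volts = U_volts, bits = as.integer(bits),
                 Uref_volts = Uref_volts),
            class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("<acquisition_config> R1 = %g kOhm, U = %g V, %d-bit ADC (Uref %g V)\n",
              x$R1_kohm, x$U_volts, x$bits, x$Uref_volts))
  invisible(x)
}

#' Divider midpoint voltage for a given sensor resistance
#'
#' The sensor `R2` sits between the supply and the midpoint; the known `R1`
#' between midpoint and ground. The midpoint voltage is
#' `U1 = U * R1 / (R1 + R2)`: strictly decreasing in `R2` and bounded in
#' (0, U].
#'
#' @param R2_kohm Sensor resistance(s), kOhm (>= 0).
#' @param cfg An [acquisition_config()].
#' @return Midpoint voltage(s), V.
#' @examples
#' divider_voltage(10, acquisition_config())  # symmetric divider: 2.5 V
#' @export
divider_voltage <- function(R2_kohm, cfg = acquisition_config()) {
  stopifnot(inherits(cfg, "acquisition_config"))
  if (any(R2_kohm < 0)) rlang::abort("`R2_kohm` must be >= 0.")
  cfg$U_volts * cfg$R1_kohm / (cfg$R1_kohm + R2_kohm)
}

#' Quantize an analog voltage to ADC counts
#'
#' `counts = round(u1 * (2^bits - 1) / Uref)`, rounding half away from zero
#' and clipping to the representable range `[0, 2^bits - 1]`.
#'
#' @param u1_volts Analog voltage(s), V (>= 0).
#' @param cfg An [acquisition_config()].
#' @return Integer ADC counts.
#' @examples
#' adc_quantize(2.5, acquisition_config())  # 512 at 10 bits / 5 V
#' @export
adc_quantize <- function(u1_volts, cfg = acquisition_config()) {
  stopifnot(inherits(cfg, "acquisition_config"))
  if (any(u1_volts < 0)) rlang::abort("`u1_volts` must be >= 0.")
  full_scale <- 2^cfg$bits - 1
  counts <- floor(u1_volts * full_scale / cfg$Uref_volts + 0.5)
  as.integer(pmin(pmax(counts, 0), full_scale))
}

#' Reconstruct the sensor resistance from the measured midpoint voltage
#'
#' Inverts the divider: `R2 = R1 * U / U1 - R1`. Accepts either the analog
#' voltage (`u1_volts`) or raw ADC counts (`counts`, converted through the
#' reference voltage first). A zero voltage or zero counts would imply an
#' open circuit (infinite resistance) and is rejected; [acquire()] flags such
#' samples instead of erroring.
#'
#' @param u1_volts Midpoint voltage(s), V (> 0). Give either this or `counts`.
#' @param counts Raw ADC counts (> 0).
#' @param cfg An [acquisition_config()].
#' @return Reconstructed resistance(s), kOhm.
#' @examples
#' estimate_resistance(u1_volts = 2.5)  # 10 kOhm
#' @export
estimate_resistance <- function(u1_volts = NULL, counts = NULL,
                                cfg = acquisition_config()) {
  stopifnot(inherits(cfg, "acquisition_config"))
  if (is.null(u1_volts) == is.null(counts)) {
    rlang::abort("Give exactly one of `u1_volts` or `counts`.")
  }
  if (!is.null(counts)) {
    if (any(counts <= 0)) {
      rlang::abort("Zero counts imply an open circuit; resistance is out of range.")
    }
    u1_volts <- counts * cfg$Uref_volts / (2^cfg$bits - 1)
  }
  if (any(u1_volts <= 0)) {
    rlang::abort("Zero midpoint voltage implies an open circuit; resistance is out of range.")
  }
  cfg$R1_kohm * cfg$U_volts / u1_volts - cfg$R1_kohm
}

#' Pass a resistance trace through the simulated measurement chain
#'
#' Composes divider, ADC quantization and in-microcontroller reconstruction:
#' the output is the resistance as the firmware sees it, including
#' quantization error. Samples that quantize to zero counts (open circuit)
#' are flagged in the `open_circuit` column and carry `NA` resistance rather
#' than a non-finite value.
#'
#' @param trace A `resistance_trace` tibble (`t_s`, `resistance_kohm`).
#' @param cfg An [acquisition_config()].
#' @return A `resistance_trace` tibble with columns `t_s`, `resistance_kohm`
#'   (reconstructed), `counts` and `open_circuit`.
#' @examples
#' gr <- fit_gauge_response(gauge_calibration_points())
#' st <- instron_waveform(instron_protocol(beam_speed_mm_min = 240))
#' acq <- acquire(resistance_at(st, gr))
#' range(acq$counts)
#' @export
acquire <- function(trace, cfg = acquisition_config()) {
  stopifnot(inherits(cfg, "acquisition_config"))
  if (!all(c("t_s", "resistance_kohm") %in% names(trace))) {
    rlang::abort("`trace` needs columns `t_s` and `resistance_kohm`.")
  }
  if (any(!is.finite(trace$resistance_kohm)) ||
      any(trace$resistance_kohm <= 0)) {
    rlang::abort("`trace` resistance must be finite and > 0.")
  }
  dt <- check_uniform_grid(trace$t_s, "trace")
  u1 <- divider_voltage(trace$resistance_kohm, cfg)
  counts <- adc_quantize(u1, cfg)
  open <- counts == 0L
  r_hat <- rep(NA_real_, length(counts))
  if (any(!open)) {
    r_hat[!open] <- estimate_resistance(counts = counts[!open], cfg = cfg)
  }
  out <- tibble::tibble(t_s = trace$t_s, resistance_kohm = r_hat,
                        counts = counts, open_circuit = open)
  attr(out, "dt") <- dt
  class(out) <- c("resistance_trace", class(out))
  out
}
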