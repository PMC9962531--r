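# Headered-CSV readers/writers for the trace and calibration formats.
# All files use '.' as decimal separator and a header row.

#' Read and write strain traces as CSV
#'
#' Strain-trace CSVs have columns `t_s,elongation_mm`. Reading validates the
#' uniform-grid and non-negative-elongation invariants.
#'
#' @param path File path.
#' @param trace A `strain_trace` tibble.
#' @return `read_strain_trace()` returns a `strain_trace` tibble;
#'   `write_strain_trace()` returns `path` invisibly.
#' @export
read_strain_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("t_s", "elongation_mm") %in% names(df))) {
    rlang::abort("Strain-trace CSV needs columns `t_s,elongation_mm`.")
  }
  if (any(df$elongation_mm < 0)) {
    rlang::abort("Strain-trace elongation must be >= 0.")
  }
  dt <- check_uniform_grid(df$t_s, path)
  new_strain_trace(df$t_s, df$elongation_mm, dt)
}

#' @rdname read_strain_trace
#' @export
write_strain_trace <- function(trace, path) {
  readr::write_csv(trace[, c("t_s", "elongation_mm")], path)
  invisible(path)
}

#' Read and write resistance traces as CSV
#'
#' Resistance-trace CSVs have columns `t_s,resistance_kohm` (extra columns
#' such as `counts` and `open_circuit` from [acquire()] are preserved on
#' write and restored on read when present).
#'
#' @param path File path.
#' @param trace A `resistance_trace` tibble.
#' @return `read_resistance_trace()` returns a `resistance_trace` tibble;
#'   `write_resistance_trace()` returns `path` invisibly.
#' @export
read_resistance_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("t_s", "resistance_kohm") %in% names(df))) {
    rlang::abort("Resistance-trace CSV needs columns `t_s,resistance_kohm`.")
  }
  dt <- check_uniform_grid(df$t_s, path)
  out <- tibble::as_tibble(df)
  attr(out, "dt") <- dt
  class(out) <- c("resistance_trace", class(out))
  out
}

#' @rdname read_resistance_trace
#' @export
write_resistance_trace <- function(trace, path) {
  keep <- intersect(c("t_s", "resistance_kohm", "counts", "open_circuit"),
                    names(trace))
  readr::write_csv(trace[, keep], path)
  invisible(path)
}

#' Read gauge calibration points from CSV
#'
#' Calibration CSVs have columns `stretch_mm,coefficient_pct`.
#'
#' @param path File path.
#' @return A tibble suitable for [fit_gauge_response()].
#' @export
read_calibration_points <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("stretch_mm", "coefficient_pct") %in% names(df))) {
    rlang::abort("Calibration CSV needs columns `stretch_mm,coefficient_pct`.")
  }
  tibble::as_tibble(df)
}
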