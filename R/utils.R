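# Internal helpers shared across modules.

#' @importFrom rlang abort
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows group_by summarise n
#' @importFrom purrr map map_dbl map2
NULL

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so simulation determinism never leaks into user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_zero_len = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    rlang::abort(sprintf("`%s` must be > %g (got %g).", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    rlang::abort(sprintf("`%s` must be >= %g (got %g).", name, lower, x))
  }
  if (x > upper) {
    rlang::abort(sprintf("`%s` must be <= %g (got %g).", name, upper, x))
  }
  invisible(x)
}

# A uniform-grid time series: strictly increasing t with constant dt.
check_uniform_grid <- function(t, name = "trace", tol = 1e-9) {
  if (length(t) < 2L) {
    rlang::abort(sprintf("`%s` must contain at least 2 samples.", name))
  }
  if (any(!is.finite(t))) {
    rlang::abort(sprintf("`%s` time column contains non-finite values.", name))
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    rlang::abort(sprintf("`%s` time column must be strictly increasing.", name))
  }
  if (max(dt) - min(dt) > tol * max(dt)) {
    rlang::abort(sprintf("`%s` must be on a uniform time grid.", name))
  }
  mean(dt)
}

trace_dt <- function(trace) {
  attr(trace, "dt") %||% check_uniform_grid(trace$t_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
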