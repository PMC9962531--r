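# YAML round-trip for stimulus configurations, so scenarios can be driven
# from plain-text files (key/value mirrors of the constructor arguments).

#' Read a stimulus configuration from a YAML file
#'
#' The file must contain a top-level `kind:` of either `instron` or
#' `breathing`; the remaining keys mirror the arguments of
#' [instron_protocol()] or [breathing_profile()] (for a breathing profile,
#' `rate_schedule` may be a single number or a list of `{start_s, rate_bpm}`
#' maps).
#'
#' @param path YAML file path.
#' @return An `instron_protocol` or `breathing_profile`.
#' @export
read_stimulus_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  kind <- cfg$kind
  if (is.null(kind) || !kind %in% c("instron", "breathing")) {
    rlang::abort("Config needs `kind: instron` or `kind: breathing`.")
  }
  cfg$kind <- NULL
  if (kind == "instron") {
    do.call(instron_protocol, cfg)
  } else {
    if (!is.null(cfg$rate_schedule) && is.list(cfg$rate_schedule)) {
      cfg$rate_schedule <- dplyr::bind_rows(
        lapply(cfg$rate_schedule, tibble::as_tibble))
    }
    do.call(breathing_profile, cfg)
  }
}

#' Write a stimulus configuration to a YAML file
#'
#' @param stimulus An `instron_protocol` or `breathing_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_config <- function(stimulus, path) {
  if (inherits(stimulus, "instron_protocol")) {
    out <- c(list(kind = "instron"), unclass(stimulus))
  } else if (inherits(stimulus, "breathing_profile")) {
    out <- c(list(kind = "breathing"), unclass(stimulus))
    out$rate_schedule <- lapply(seq_len(nrow(stimulus$rate_schedule)),
                                function(i) as.list(stimulus$rate_schedule[i, ]))
  } else {
    rlang::abort("`stimulus` must be an instron_protocol or breathing_profile.")
  }
  yaml::write_yaml(out, path)
  invisible(path)
}
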