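# The ten exogenous input signal patterns S1-S10: pure functions of time,
# each one combination of fast/slow initiation and fast/slow (or absent)
# decay. Definitions live in inst/extdata/signals.json.

.hub_env <- new.env(parent = emptyenv())

load_signal_table <- function() {
  if (is.null(.hub_env$signals)) {
    path <- system.file("extdata", "signals.json", package = "hubsens",
                        mustWork = TRUE)
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)$patterns
    .hub_env$signals <- stats::setNames(
      lapply(raw, function(p)
        structure(p[c("id", "rise", "decay", "amplitude", "baseline",
                      "beta_on", "beta_off", "t_switch")],
                  class = "signal_pattern")),
      vapply(raw, `[[`, "", "id"))
  }
  .hub_env$signals
}

#' All ten input signal patterns
#' @return named list of `signal_pattern` objects, S1 to S10.
#' @export
signal_patterns <- function() load_signal_table()

#' A single input signal pattern
#' @param id pattern label, `"S1"` to `"S10"`.
#' @return a `signal_pattern` object.
#' @export
signal_pattern <- function(id) {
  tab <- load_signal_table()
  if (!(is.character(id) && length(id) == 1L && id %in% names(tab)))
    stop("unknown signal pattern id", call. = FALSE)
  tab[[id]]
}

#' A constant input signal
#'
#' Convenience pattern with s(t) = level for all t, used by the toy and
#' validation systems.
#' @param level non-negative signal level.
#' @export
constant_signal <- function(level = 1) {
  stopifnot(is.numeric(level), level >= 0)
  structure(list(id = sprintf("const%g", level), rise = "none",
                 decay = "none", amplitude = 0, baseline = level,
                 beta_on = 1, beta_off = 0, t_switch = 1e6),
            class = "signal_pattern")
}

#' Evaluate an input signal pattern
#'
#' s(t) rises as baseline + amplitude * (1 - exp(-beta_on t)) until the
#' switch time, then decays exponentially at rate beta_off. Values are
#' non-negative and finite on the whole observation window.
#'
#' @param pattern a `signal_pattern`.
#' @param t time(s) in minutes, non-negative.
#' @return numeric vector of signal concentrations.
#' @export
signal_value <- function(pattern, t) {
  stopifnot(inherits(pattern, "signal_pattern"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("signal time must be finite and >= 0", call. = FALSE)
  up <- pattern$baseline + pattern$amplitude * (1 - exp(-pattern$beta_on * t))
  s_ts <- pattern$baseline +
    pattern$amplitude * (1 - exp(-pattern$beta_on * pattern$t_switch))
  down <- s_ts * exp(-pattern$beta_off * (t - pattern$t_switch))
  pmax(ifelse(t <= pattern$t_switch, up, down), 0)
}

#' @export
print.signal_pattern <- function(x, ...) {
  cat("<signal_pattern> ", x$id, ": ", x$rise, " initiation / ", x$decay,
      " decay (beta_on=", x$beta_on, ", beta_off=", x$beta_off,
      ", t_switch=", x$t_switch, " min)\n", sep = "")
  invisible(x)
}
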