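# Local log-sensitivity of the output time integral:
# s_log = d ln q / d ln p_i, computed by a one-sided forward finite
# difference with a 0.1% increase in each reaction's rate constant,
# q = integral of X*(t) over [0, 300] min by composite trapezoid on a
# 0.5-min quadrature grid.

#' Time integral of the output trajectory
#'
#' q = integral of X*(t) dt by the composite trapezoid rule on the
#' trajectory's own grid. The grid should be dense (sub-minute), not the
#' 30-min sampling grid.
#'
#' @param traj a `hub_trajectory` (or any list with `times` and `output`).
#' @return non-negative scalar, concentration x min.
#' @export
time_integral <- function(traj) {
  t <- traj$times
  y <- traj$output
  if (length(t) < 2) stop("trajectory too short for quadrature",
                          call. = FALSE)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Local log-sensitivities of the output time integral
#'
#' For each reaction's rate constant p_i,
#' s_log = (q(p_i (1 + rel_step)) / q(p) - 1) / rel_step,
#' the forward (increase-only) finite-difference estimate of
#' d ln q / d ln p_i. Only the rate constants (k1, k2a, ...) are perturbed
#' and each sensitivity is reported under its reaction's label; Michaelis
#' constants are included when `perturb = "all"`.
#'
#' @param model a `hub_model`.
#' @param params named positive parameter vector.
#' @param pattern a `signal_pattern`.
#' @param rel_step relative perturbation, default 0.001 (0.1%).
#' @param perturb `"rates"` (one rate constant per reaction, default) or
#'   `"all"` (every parameter, reported under its own name).
#' @param quad_times quadrature grid for q.
#' @param rtol,atol solver tolerances (tight by default so the quadrature
#'   noise stays well below the 0.1% perturbation signal).
#' @return named vector of log-sensitivities; a perturbed integration
#'   failure yields `NA` for that entry; base failure raises an
#'   integration error; q = 0 raises an error.
#' @export
local_sensitivity <- function(model, params = model$params, pattern,
                              rel_step = 0.001,
                              perturb = c("rates", "all"),
                              quad_times = seq(0, 300, by = 0.5),
                              rtol = 1e-10, atol = 1e-10, maxsteps = 10000) {
  stopifnot(rel_step > 0)
  perturb <- match.arg(perturb)
  params <- resolve_params(model, params)
  base <- integrate_ode(model, params, pattern, sample_times = quad_times,
                        rtol = rtol, atol = atol, maxsteps = maxsteps)
  q0 <- time_integral(base)
  if (q0 <= 0)
    stop("undefined sensitivity: zero output integral", call. = FALSE)

  targets <- if (perturb == "rates") {
    stats::setNames(unname(model$rate_params), model$labels)
  } else {
    stats::setNames(model$param_names, model$param_names)
  }
  s <- vapply(targets, function(pn) {
    p2 <- params
    p2[[pn]] <- p2[[pn]] * (1 + rel_step)
    q1 <- tryCatch(
      time_integral(integrate_ode(model, p2, pattern,
                                  sample_times = quad_times,
                                  rtol = rtol, atol = atol,
                                  maxsteps = maxsteps)),
      hubsens_integration_error = function(e) NA_real_)
    (q1 / q0 - 1) / rel_step
  }, 0)
  attr(s, "q") <- q0
  s
}

#' Sensitivity table over a collection of parameter sets
#'
#' One record per (parameter set, signal pattern, reaction): the output
#' integral q and the log-sensitivity s_log of q to the reaction's rate
#' constant. Sets whose base integration fails (or whose q is zero) are
#' dropped entirely; perturbed failures drop the affected records. The
#' number of excluded sets is reported in a message and stored as an
#' attribute.
#'
#' @param model a `hub_model`.
#' @param sets a `hub_param_sets` data frame (labels filled by the fit
#'   step, or `"unclassified"`).
#' @param patterns signal patterns (default: all ten).
#' @param rel_step relative perturbation.
#' @param quad_step quadrature resolution in minutes.
#' @return a `sensitivity_table`: data frame with columns `set_id`,
#'   `label`, `pattern`, `reaction`, `q`, `s_log`.
#' @export
build_sensitivity_table <- function(model, sets,
                                    patterns = signal_patterns(),
                                    rel_step = 0.001, quad_step = 0.5,
                                    rtol = 1e-10, atol = 1e-10,
                                    maxsteps = 10000) {
  stopifnot(inherits(model, "hub_model"))
  if (nrow(sets) == 0) {
    warning("empty parameter-set input; empty sensitivity table")
    return(empty_sensitivity_table(model))
  }
  quad_times <- seq(0, 300, by = quad_step)
  rows <- vector("list", nrow(sets) * length(patterns))
  n_excluded <- 0L
  k <- 0L
  for (i in seq_len(nrow(sets))) {
    pv <- param_values(sets, i)
    failed <- FALSE
    for (pat in patterns) {
      s <- tryCatch(
        local_sensitivity(model, pv, pat, rel_step = rel_step,
                          quad_times = quad_times, rtol = rtol,
                          atol = atol, maxsteps = maxsteps),
        hubsens_integration_error = function(e) NULL,
        error = function(e) NULL)
      if (is.null(s)) { failed <- TRUE; break }
      q0 <- attr(s, "q")
      keep <- is.finite(s)
      if (!any(keep)) { failed <- TRUE; break }
      k <- k + 1L
      rows[[k]] <- data.frame(
        set_id = sets$id[i], label = sets$label[i], pattern = pat$id,
        reaction = names(s)[keep], q = q0, s_log = unname(s[keep]),
        stringsAsFactors = FALSE)
    }
    if (failed) {
      n_excluded <- n_excluded + 1L
      # drop any partial records for this set
      while (k > 0 && length(rows) >= k && !is.null(rows[[k]]) &&
             rows[[k]]$set_id[1] == sets$id[i]) {
        rows[[k]] <- NULL
        k <- k - 1L
      }
    }
  }
  if (n_excluded > 0)
    message(n_excluded, " parameter set(s) excluded for integration failure")
  tab <- if (k == 0) empty_sensitivity_table(model) else
    do.call(rbind, rows[seq_len(k)])
  structure(tab, class = c("sensitivity_table", "data.frame"),
            model_id = model$id, reactions = model$labels,
            pattern_ids = vapply(patterns, `[[`, "", "id"),
            rel_step = rel_step, n_excluded = n_excluded)
}

empty_sensitivity_table <- function(model) {
  structure(
    data.frame(set_id = character(0), label = character(0),
               pattern = character(0), reaction = character(0),
               q = numeric(0), s_log = numeric(0), stringsAsFactors = FALSE),
    class = c("sensitivity_table", "data.frame"),
    model_id = model$id, reactions = model$labels, n_excluded = 0L)
}

#' Sensitivity analysis of fitted parameter ensembles
#'
#' Generic; the `hub_fit` method computes the sensitivity table for the
#' fitted sets with the requested label.
#'
#' @param x object to analyse.
#' @param ... passed on to methods.
#' @export
sensitivity <- function(x, ...) UseMethod("sensitivity")

#' @rdname sensitivity
#' @param label_filter `"positive"`, `"negative"`, `"all"` or
#'   `"classified"` (positive + negative).
#' @param rel_step relative perturbation.
#' @export
sensitivity.hub_fit <- function(x, label_filter = c("positive", "classified",
                                                    "negative", "all"),
                                rel_step = 0.001, ...) {
  label_filter <- match.arg(label_filter)
  keep <- switch(label_filter,
                 positive = x$sets$label == "positive",
                 negative = x$sets$label == "negative",
                 classified = x$sets$label %in% c("positive", "negative"),
                 all = rep(TRUE, nrow(x$sets)))
  sets <- x$sets[keep, , drop = FALSE]
  attr(sets, "param_names") <- attr(x$sets, "param_names")
  attr(sets, "model_id") <- attr(x$sets, "model_id")
  build_sensitivity_table(x$model, sets, rel_step = rel_step, ...)
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat("<sensitivity_table> model ", attr(x, "model_id"), ": ", nrow(x),
      " records (", length(unique(x$set_id)), " sets x patterns x reactions)",
      "\n", sep = "")
  if (nrow(x)) {
    rng <- range(x$s_log)
    cat("  s_log range: [", format(rng[1], digits = 3), ", ",
        format(rng[2], digits = 3), "]\n", sep = "")
  }
  invisible(x)
}
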