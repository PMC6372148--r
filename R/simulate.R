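# Deterministic ODE integration (lsoda on the compiled right-hand side)
# and chemical Langevin simulation by Euler-Maruyama, plus the generator
# of replicate-ensemble control data.

#' Default sampling grid: every 30 min over (0, 300]
#' @export
control_sample_times <- function() seq(30, 300, by = 30)

#' Integrate a hub model deterministically
#'
#' Solves the reaction-network ODE dX/dt = v a(X, s(t)) with the
#' stiff-capable lsoda solver (compiled right-hand side). A solver failure
#' (non-convergence, step-size underflow, non-finite states) raises a
#' condition of class `hubsens_integration_error` carrying `set_id`, so
#' callers can apply the exclusion rule for failed parameter sets.
#'
#' @param model a `hub_model`.
#' @param params named positive parameter vector (defaults to the model's
#'   original values).
#' @param pattern a `signal_pattern`.
#' @param sample_times increasing time grid (min), starting at 0 or later.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param maxsteps lsoda step budget between output times.
#' @param set_id optional identifier attached to error conditions.
#' @return a `hub_trajectory`: list with `times`, `states` (time x species),
#'   `output` (X* at the sample times), `pattern_id`, `model_id`.
#' @export
integrate_ode <- function(model, params = model$params, pattern,
                          sample_times = seq(0, 300, by = 0.5),
                          rtol = 1e-8, atol = 1e-8, maxsteps = 10000,
                          set_id = NULL) {
  stopifnot(inherits(model, "hub_model"), inherits(pattern, "signal_pattern"))
  params <- resolve_params(model, params)
  if (any(!is.finite(params)) || any(params <= 0))
    stop("parameters must be positive and finite", call. = FALSE)
  if (is.unsorted(sample_times, strictly = TRUE) || any(sample_times < 0))
    stop("sample_times must be strictly increasing and >= 0", call. = FALSE)

  times <- sample_times
  prepend0 <- times[1] > 0
  if (prepend0) times <- c(0, times)
  if (length(times) == 1L) {  # degenerate request: initial state only
    states <- matrix(model$init, nrow = 1,
                     dimnames = list(NULL, model$species))
    return(new_trajectory(model, pattern, sample_times, states))
  }

  enc <- encode_model(model, params, pattern)
  .Call("C_set_model", enc, PACKAGE = "hubsens")
  out <- try(suppressWarnings(
    deSolve::lsoda(y = unname(model$init), times = times,
                   func = "hub_derivs", parms = NULL,
                   dllname = "hubsens", initfunc = "hub_init",
                   rtol = rtol, atol = atol, maxsteps = maxsteps)),
    silent = TRUE)

  ok <- !inherits(out, "try-error") &&
    nrow(out) == length(times) &&
    all(is.finite(out[, -1, drop = FALSE])) &&
    attr(out, "istate")[1] >= 0
  if (!ok)
    stop(errorCondition(
      paste0("ODE integration failed",
             if (!is.null(set_id)) paste0(" for set ", set_id)),
      class = c("hubsens_integration_error", "hubsens_error"),
      set_id = set_id))

  states <- out[, -1, drop = FALSE]
  if (prepend0) states <- states[-1, , drop = FALSE]
  colnames(states) <- model$species
  new_trajectory(model, pattern, sample_times, states)
}

new_trajectory <- function(model, pattern, times, states) {
  structure(list(times = times, states = states,
                 output = unname(states[, model$output_index]),
                 pattern_id = pattern$id, model_id = model$id),
            class = "hub_trajectory")
}

#' @export
print.hub_trajectory <- function(x, ...) {
  cat("<hub_trajectory> ", x$model_id, " / ", x$pattern_id, ": ",
      length(x$times), " time points over [",
      min(x$times), ", ", max(x$times), "] min\n", sep = "")
  invisible(x)
}

boundary_code <- function(boundary) {
  match(match.arg(boundary, c("clip", "reflect", "none")),
        c("clip", "reflect", "none")) - 1L
}

#' Simulate a hub model with the chemical Langevin equation
#'
#' Fixed-step Euler-Maruyama integration of
#' dX = sum_j v_j a_j dt + sum_j v_j sqrt(a_j dt) eta_j, with independent
#' standard-normal increments per reaction per step. The diffusion term uses
#' the square root of each propensity (Gillespie's chemical Langevin form);
#' `noise_scale` rescales it globally and 0 recovers fixed-step Euler.
#' Negative excursions are handled by the boundary policy (default: clip
#' to zero before the next propensity evaluation).
#'
#' @inheritParams integrate_ode
#' @param dt Euler-Maruyama step (min); must divide the sampling interval.
#' @param seed optional integer seed (set via `set.seed`); identical seeds
#'   give bit-identical trajectories.
#' @param noise_scale global multiplier of the diffusion term.
#' @param boundary `"clip"`, `"reflect"` or `"none"`.
#' @return a `hub_trajectory`.
#' @export
simulate_cle <- function(model, params = model$params, pattern,
                         dt = 0.01, sample_times = seq(0, 300, by = 30),
                         seed = NULL, noise_scale = 1,
                         boundary = "clip") {
  stopifnot(inherits(model, "hub_model"), inherits(pattern, "signal_pattern"),
            dt > 0)
  params <- resolve_params(model, params)
  check_dt_grid(dt, sample_times)
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_model(model, params, pattern)
  states <- .Call("C_cle_path", enc, unname(model$init), as.numeric(dt),
                  as.numeric(sample_times), as.numeric(noise_scale),
                  boundary_code(boundary), PACKAGE = "hubsens")
  if (any(!is.finite(states)))
    stop(errorCondition("stochastic state diverged",
                        class = c("hubsens_stochastic_error", "hubsens_error")))
  colnames(states) <- model$species
  new_trajectory(model, pattern, sample_times, states)
}

check_dt_grid <- function(dt, sample_times) {
  steps <- sample_times / dt
  if (any(abs(steps - round(steps)) > 1e-8))
    stop("dt must divide every sample time", call. = FALSE)
  invisible(TRUE)
}

#' Generate replicate-ensemble control data
#'
#' Runs `n_replicates` chemical Langevin simulations of the model at its
#' original parameter values for every signal pattern, samples the output
#' X* every 30 min for 300 min, and summarises each time point by its
#' ensemble mean, standard deviation and standard error
#' (SE = SD / sqrt(n_replicates)). These summaries are the reproducibility
#' reference ("control data") that candidate parameter sets are scored
#' against.
#'
#' Randomness policy: one root seed; each (pattern) ensemble runs under a
#' deterministically derived substream seed (`seed + 1000 * pattern index`),
#' with replicates drawn sequentially inside the substream.
#'
#' @param model a `hub_model` carrying its original parameter values.
#' @param n_replicates ensemble size (paper-scale default 1000).
#' @param dt Euler-Maruyama step in min.
#' @param seed root integer seed (required for reproducibility).
#' @param noise_scale global diffusion multiplier.
#' @param patterns list of signal patterns (default: all ten).
#' @param sample_times sampling grid, default 30, 60, ..., 300 min.
#' @param max_retry redraw budget for diverging replicates.
#' @return object of class `control_data`: per pattern the `mean`, `sd`,
#'   `se` vectors and the norm of the mean vector, plus run metadata.
#' @export
generate_control_data <- function(model, n_replicates = 1000, dt = 0.01,
                                  seed = 1L, noise_scale = 1,
                                  patterns = signal_patterns(),
                                  sample_times = control_sample_times(),
                                  max_retry = 10L) {
  stopifnot(inherits(model, "hub_model"), n_replicates >= 2)
  check_dt_grid(dt, sample_times)
  per_pattern <- vector("list", length(patterns))
  names(per_pattern) <- vapply(patterns, `[[`, "", "id")
  for (i in seq_along(patterns)) {
    set.seed(derive_seed(seed, i))
    enc <- encode_model(model, model$params, patterns[[i]])
    reps <- .Call("C_cle_ensemble", enc, unname(model$init), as.numeric(dt),
                  as.numeric(sample_times), as.numeric(noise_scale),
                  boundary_code("clip"), as.integer(n_replicates),
                  as.integer(model$output_index), as.integer(max_retry),
                  PACKAGE = "hubsens")
    m <- colMeans(reps)
    s <- apply(reps, 2, stats::sd)
    per_pattern[[i]] <- list(mean = m, sd = s,
                             se = s / sqrt(n_replicates),
                             norm_mean = sqrt(sum(m^2)))
  }
  structure(list(model_id = model$id, n_replicates = n_replicates,
                 sample_times = sample_times, patterns = per_pattern,
                 dt = dt, rng_seed = seed, noise_scale = noise_scale),
            class = "control_data")
}

derive_seed <- function(seed, index) {
  (as.integer(seed) + 1000L * as.integer(index)) %% .Machine$integer.max
}

#' @export
print.control_data <- function(x, ...) {
  cat("<control_data> model ", x$model_id, ": ", length(x$patterns),
      " patterns x ", length(x$sample_times), " sample times, ",
      x$n_replicates, " CLE replicates (dt=", x$dt, " min, seed=",
      x$rng_seed, ")\n", sep = "")
  peak <- vapply(x$patterns, function(p) max(p$mean), 0)
  cat("  peak mean X* by pattern: ",
      paste(sprintf("%s=%.1f", names(x$patterns), peak), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Control data as a long data frame
#' @param x a `control_data` object.
#' @return data frame with columns pattern, time, mean, sd, se.
#' @export
as.data.frame.control_data <- function(x, ...) {
  do.call(rbind, lapply(names(x$patterns), function(pid) {
    p <- x$patterns[[pid]]
    data.frame(pattern = pid, time = x$sample_times,
               mean = p$mean, sd = p$sd, se = p$se,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
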