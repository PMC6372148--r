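# Scoring of candidate parameter sets against control data: scale-invariant
# cosine fitness, per-pattern scaling factor alpha, and the banded
# positive/negative classification of reproducibility.

vec_norm <- function(x) sqrt(sum(x^2))

#' Cosine-error fitness
#'
#' Sum over signal patterns of 1 - cos^2 between the simulated and control
#' output vectors:
#' fitness = sum_i (1 - (<sim_i, ctrl_i> / (||sim_i|| ||ctrl_i||))^2).
#' The score is invariant to positive rescaling of either vector, lies in
#' [0, N] for N patterns, and is 0 iff every simulated vector is collinear
#' with its control counterpart. A zero-norm simulated vector contributes 1
#' (orthogonal-equivalent, with a warning); a zero-norm control vector is a
#' configuration error.
#'
#' @param sim_vectors list (or matrix columns) of per-pattern simulated
#'   output vectors.
#' @param control_vectors list of per-pattern control mean vectors, same
#'   lengths.
#' @return non-negative scalar fitness.
#' @export
cosine_fitness <- function(sim_vectors, control_vectors) {
  sim_vectors <- as_vector_list(sim_vectors)
  control_vectors <- as_vector_list(control_vectors)
  stopifnot(length(sim_vectors) == length(control_vectors))
  total <- 0
  for (i in seq_along(sim_vectors)) {
    x <- sim_vectors[[i]]
    y <- control_vectors[[i]]
    if (length(x) != length(y))
      stop("pattern ", i, ": vector length mismatch", call. = FALSE)
    ny <- vec_norm(y)
    if (ny == 0)
      stop("zero-norm control vector in pattern ", i, call. = FALSE)
    nx <- vec_norm(x)
    if (nx == 0) {
      warning("zero-norm simulated vector in pattern ", i,
              "; scored as orthogonal")
      total <- total + 1
    } else {
      total <- total + (1 - (sum(x * y) / (nx * ny))^2)
    }
  }
  total
}

as_vector_list <- function(v) {
  if (is.matrix(v)) lapply(seq_len(ncol(v)), function(j) v[, j])
  else if (is.list(v)) v
  else list(v)
}

#' Scaling factor alpha
#'
#' alpha = ||control mean vector|| / ||simulated vector||: the positive
#' factor that maps the simulation onto the amplitude scale of the control
#' data, so that alpha * sim has the same norm as the control mean.
#'
#' @param sim_vector simulated output vector with positive norm.
#' @param control_mean_vector control ensemble mean vector.
#' @return positive scalar.
#' @export
scaling_factor <- function(sim_vector, control_mean_vector) {
  ns <- vec_norm(sim_vector)
  if (ns == 0)
    stop(errorCondition("undefined scaling factor: zero-norm simulation",
                        class = c("hubsens_scaling_error", "hubsens_error")))
  vec_norm(control_mean_vector) / ns
}

#' Classify a simulation against control data
#'
#' A parameter set is "positive" (reproducible) iff, for every signal
#' pattern and every sample time, its alpha-scaled output lies inside
#' [mean - band, mean + band] of the control ensemble; otherwise it is
#' negative. Sets whose integration failed are flagged `excluded` and
#' counted in neither class. By default each pattern is scaled by its own
#' alpha; `scaling = "global"` uses one pooled factor.
#'
#' @param sim_vectors named list of per-pattern simulated output vectors on
#'   the control sampling grid (unscaled).
#' @param control a `control_data` object.
#' @param band `"sd"` (default) or `"se"`: the half-width of the acceptance
#'   band at each time point.
#' @param scaling `"per_pattern"` or `"global"` alpha.
#' @param set_id optional identifier.
#' @param excluded flag a set whose simulation failed; yields label
#'   `"excluded"` without banding.
#' @return a `fitness_report`: fitness, per-pattern alpha, label,
#'   per-pattern pass mask.
#' @export
classify <- function(sim_vectors, control, band = c("sd", "se"),
                     scaling = c("per_pattern", "global"),
                     set_id = NULL, excluded = FALSE) {
  stopifnot(inherits(control, "control_data"))
  band <- match.arg(band)
  scaling <- match.arg(scaling)
  if (control$n_replicates < 1)
    stop("control data with no replicates", call. = FALSE)
  pids <- names(control$patterns)

  if (excluded) {
    return(new_fitness_report(set_id, NA_real_,
                              stats::setNames(rep(NA_real_, length(pids)), pids),
                              "excluded",
                              stats::setNames(rep(NA, length(pids)), pids),
                              band, TRUE))
  }

  sim_vectors <- as_vector_list(sim_vectors)
  if (is.null(names(sim_vectors)) && length(sim_vectors) == length(pids))
    names(sim_vectors) <- pids
  miss <- setdiff(pids, names(sim_vectors))
  if (length(miss))
    stop("simulation missing patterns: ", paste(miss, collapse = ", "),
         call. = FALSE)

  ctrl_means <- lapply(control$patterns, `[[`, "mean")
  fitness <- cosine_fitness(sim_vectors[pids], ctrl_means)

  alphas <- vapply(pids, function(pid) {
    ns <- vec_norm(sim_vectors[[pid]])
    if (ns == 0) NA_real_ else control$patterns[[pid]]$norm_mean / ns
  }, 0)
  if (scaling == "global") {
    g <- sqrt(sum(vapply(control$patterns, `[[`, 0, "norm_mean")^2)) /
      sqrt(sum(vapply(sim_vectors[pids], function(v) sum(v^2), 0)))
    alphas[] <- g
  }

  pass <- vapply(pids, function(pid) {
    a <- alphas[[pid]]
    if (!is.finite(a)) return(FALSE)
    p <- control$patterns[[pid]]
    half <- if (band == "sd") p$sd else p$se
    scaled <- a * sim_vectors[[pid]]
    all(scaled >= p$mean - half & scaled <= p$mean + half)
  }, TRUE)

  label <- if (all(pass)) "positive" else "negative"
  new_fitness_report(set_id, fitness, alphas, label, pass, band, FALSE)
}

new_fitness_report <- function(set_id, fitness, alphas, label, pass,
                               band, excluded) {
  structure(list(set_id = set_id, fitness = fitness,
                 alpha_per_pattern = alphas, label = label,
                 pattern_pass_mask = pass, band = band,
                 excluded = excluded),
            class = "fitness_report")
}

#' @export
print.fitness_report <- function(x, ...) {
  cat("<fitness_report>",
      if (!is.null(x$set_id)) paste0(" set ", x$set_id), " label=", x$label,
      " fitness=", format(x$fitness, digits = 4), "\n", sep = "")
  if (!x$excluded)
    cat("  patterns passing band (", x$band, "): ",
        sum(x$pattern_pass_mask), "/", length(x$pattern_pass_mask),
        "\n", sep = "")
  invisible(x)
}

# Simulate a candidate on the control grid and classify it.
# Returns a fitness_report; integration failures become excluded reports.
evaluate_candidate <- function(model, params, control, band = "sd",
                               scaling = "per_pattern", set_id = NULL,
                               patterns = signal_patterns(),
                               rtol = 1e-8, atol = 1e-8, maxsteps = 10000) {
  sims <- tryCatch(
    lapply(patterns[names(control$patterns)], function(pat)
      integrate_ode(model, params, pat,
                    sample_times = control$sample_times,
                    rtol = rtol, atol = atol, maxsteps = maxsteps,
                    set_id = set_id)$output),
    hubsens_integration_error = function(e) NULL)
  if (is.null(sims))
    return(classify(list(), control, band = band, scaling = scaling,
                    set_id = set_id, excluded = TRUE))
  classify(sims, control, band = band, scaling = scaling, set_id = set_id)
}
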