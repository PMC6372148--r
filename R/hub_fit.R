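# The central model-fitting surface: fit_hub() assembles candidate
# parameter sets (genetic local search and/or random sampling), classifies
# every set against the control data, and returns a classed object with
# the usual modelling methods.

#' Fit reproducible parameter ensembles of a hub model
#'
#' Collects candidate kinetic parameter sets for `model` — by the hybrid
#' genetic local search ([estimate_parameters()]), by log-uniform random
#' sampling ([random_sample_params()]), or both — simulates each candidate
#' across all signal patterns, and classifies it positive (reproducible:
#' its alpha-scaled output stays inside the control band at every sample
#' time of every pattern), negative, or excluded (integration failure).
#'
#' @param model a `hub_model`.
#' @param control a `control_data` object for the same model; if `NULL`
#'   it is generated at the model's original parameter values with
#'   `n_replicates` replicates.
#' @param method `"search"`, `"random"` or `"both"`.
#' @param config a [search_config()] for the genetic local search.
#' @param n_random number of random sets when method includes sampling.
#' @param band classification band half-width, `"sd"` or `"se"`.
#' @param scaling alpha scaling, `"per_pattern"` or `"global"`.
#' @param n_replicates ensemble size if control data must be generated.
#' @return an object of class `hub_fit` with components `model`, `control`,
#'   `sets` (a `hub_param_sets` data frame with fitness and labels),
#'   `alphas` (per-set, per-pattern scaling factors) and `history`.
#' @seealso [sensitivity()], [coef.hub_fit()], [predict.hub_fit()]
#' @export
fit_hub <- function(model, control = NULL,
                    method = c("search", "random", "both"),
                    config = search_config(), n_random = 1000,
                    band = c("sd", "se"),
                    scaling = c("per_pattern", "global"),
                    n_replicates = 1000) {
  stopifnot(inherits(model, "hub_model"))
  method <- match.arg(method)
  band <- match.arg(band)
  scaling <- match.arg(scaling)
  if (is.null(control))
    control <- generate_control_data(model, n_replicates = n_replicates,
                                     seed = config$seed)

  sets <- NULL
  history <- NULL
  if (method %in% c("search", "both")) {
    est <- estimate_parameters(model, control, config)
    history <- attr(est, "history")
    sets <- est
  }
  if (method %in% c("random", "both")) {
    rnd <- random_sample_params(model, n_random,
                                seed = derive_seed(config$seed, 555L))
    sets <- if (is.null(sets)) rnd else rbind_param_sets(model, sets, rnd)
  }

  patterns <- signal_patterns()
  n <- nrow(sets)
  alphas <- matrix(NA_real_, nrow = n, ncol = length(control$patterns),
                   dimnames = list(sets$id, names(control$patterns)))
  for (i in seq_len(n)) {
    rep <- evaluate_candidate(model, param_values(sets, i), control,
                              band = band, scaling = scaling,
                              set_id = sets$id[i], patterns = patterns)
    sets$fitness[i] <- rep$fitness
    sets$label[i] <- rep$label
    alphas[i, ] <- rep$alpha_per_pattern
  }

  structure(list(model = model, control = control, sets = sets,
                 alphas = alphas, history = history, band = band,
                 scaling = scaling, call = match.call()),
            class = "hub_fit")
}

rbind_param_sets <- function(model, a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  out$id <- make.unique(out$id)
  structure(out, class = c("hub_param_sets", "data.frame"),
            model_id = model$id, param_names = attr(a, "param_names"))
}

label_counts <- function(fit) {
  table(factor(fit$sets$label,
               levels = c("positive", "negative", "excluded",
                          "unclassified")))
}

#' @export
print.hub_fit <- function(x, ...) {
  cnt <- label_counts(x)
  cat("<hub_fit> model ", x$model$id, " (", x$model$name, ")\n", sep = "")
  cat("  ", nrow(x$sets), " parameter sets (",
      paste(sprintf("%s: %d", names(cnt), as.integer(cnt)), collapse = ", "),
      ")\n", sep = "")
  ok <- is.finite(x$sets$fitness)
  if (any(ok))
    cat("  best cosine fitness: ",
        format(min(x$sets$fitness[ok]), digits = 4),
        " (band = ", x$band, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.hub_fit <- function(object, ...) {
  cnt <- label_counts(object)
  ok <- is.finite(object$sets$fitness)
  structure(list(model_id = object$model$id, counts = cnt,
                 fitness_quantiles = if (any(ok))
                   stats::quantile(object$sets$fitness[ok],
                                   c(0, .25, .5, .75, 1)) else NULL,
                 n_positive = as.integer(cnt[["positive"]]),
                 band = object$band,
                 best = utils::head(
                   object$sets[order(object$sets$fitness), ], 5)),
            class = "summary.hub_fit")
}

#' @export
print.summary.hub_fit <- function(x, ...) {
  cat("Hub-model parameter ensemble, model", x$model_id, "\n")
  cat("  labels:",
      paste(sprintf("%s=%d", names(x$counts), as.integer(x$counts)),
            collapse = "  "), "\n")
  if (!is.null(x$fitness_quantiles)) {
    cat("  cosine fitness quantiles:\n")
    print(signif(x$fitness_quantiles, 4))
  }
  cat("  best sets:\n")
  print(x$best[, c("id", "provenance", "fitness", "label")])
  invisible(x)
}

#' Best-fitting parameter values
#' @param object a `hub_fit`.
#' @param which `"best"` (lowest fitness) or a set id.
#' @param log return log coordinates.
#' @param ... unused.
#' @return named parameter vector.
#' @export
coef.hub_fit <- function(object, which = "best", log = FALSE, ...) {
  i <- resolve_set(object, which)
  param_values(object$sets, i, log = log)
}

resolve_set <- function(object, which) {
  if (identical(which, "best")) which.min(object$sets$fitness)
  else {
    i <- match(which, object$sets$id)
    if (is.na(i)) stop("unknown set id '", which, "'", call. = FALSE)
    i
  }
}

#' Predicted (deterministic) trajectory of a fitted set
#' @param object a `hub_fit`.
#' @param pattern signal pattern id.
#' @param which `"best"` or a set id.
#' @param times output grid in minutes.
#' @param scaled multiply the output by the set's per-pattern alpha.
#' @param ... unused.
#' @return a `hub_trajectory` (with alpha-scaled output if requested).
#' @export
predict.hub_fit <- function(object, pattern = "S1", which = "best",
                            times = seq(0, 300, by = 0.5), scaled = FALSE,
                            ...) {
  i <- resolve_set(object, which)
  traj <- integrate_ode(object$model, param_values(object$sets, i),
                        signal_pattern(pattern), sample_times = times)
  if (scaled) {
    a <- object$alphas[i, pattern]
    traj$output <- a * traj$output
  }
  traj
}

#' Residuals of a fitted set against the control means
#' @param object a `hub_fit`.
#' @param which `"best"` or a set id.
#' @param ... unused.
#' @return matrix (pattern x sample time) of alpha-scaled simulation minus
#'   control mean.
#' @export
residuals.hub_fit <- function(object, which = "best", ...) {
  i <- resolve_set(object, which)
  ctrl <- object$control
  res <- t(vapply(names(ctrl$patterns), function(pid) {
    traj <- integrate_ode(object$model, param_values(object$sets, i),
                          signal_pattern(pid),
                          sample_times = ctrl$sample_times)
    object$alphas[i, pid] * traj$output - ctrl$patterns[[pid]]$mean
  }, numeric(length(ctrl$sample_times))))
  colnames(res) <- ctrl$sample_times
  res
}

#' Stochastic replicates of a fitted set
#' @param object a `hub_fit`.
#' @param nsim number of CLE replicates.
#' @param seed integer seed.
#' @param pattern signal pattern id.
#' @param which `"best"` or a set id.
#' @param dt Euler-Maruyama step.
#' @param ... unused.
#' @return matrix (replicate x sample time) of simulated X*.
#' @export
simulate.hub_fit <- function(object, nsim = 1, seed = NULL, pattern = "S1",
                             which = "best", dt = 0.01, ...) {
  i <- resolve_set(object, which)
  if (!is.null(seed)) set.seed(seed)
  ctrl <- object$control
  enc <- encode_model(object$model, param_values(object$sets, i),
                      signal_pattern(pattern))
  out <- .Call("C_cle_ensemble", enc, unname(object$model$init),
               as.numeric(dt), as.numeric(ctrl$sample_times),
               as.numeric(ctrl$noise_scale), boundary_code("clip"),
               as.integer(nsim), as.integer(object$model$output_index),
               10L, PACKAGE = "hubsens")
  colnames(out) <- ctrl$sample_times
  out
}

#' Plot a fitted set against the control band
#' @param x a `hub_fit`.
#' @param pattern signal pattern id.
#' @param which `"best"` or a set id.
#' @param ... passed to `plot`.
#' @export
plot.hub_fit <- function(x, pattern = "S1", which = "best", ...) {
  ctrl <- x$control
  p <- ctrl$patterns[[pattern]]
  tt <- ctrl$sample_times
  i <- resolve_set(x, which)
  traj <- integrate_ode(x$model, param_values(x$sets, i),
                        signal_pattern(pattern), sample_times = tt)
  scaled <- x$alphas[i, pattern] * traj$output
  ylim <- range(p$mean + p$sd, p$mean - p$sd, scaled, 0)
  graphics::plot(tt, p$mean, type = "p", pch = 16, ylim = ylim,
                 xlab = "time (min)", ylab = paste0("X* (", pattern, ")"),
                 main = paste("model", x$model$id, "- set", x$sets$id[i]),
                 ...)
  graphics::arrows(tt, p$mean - p$sd, tt, p$mean + p$sd, angle = 90,
                   code = 3, length = 0.03,
                   col = grDevices::adjustcolor("black", 0.6))
  graphics::lines(tt, scaled, col = "red", lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = c("control mean +/- SD", "scaled simulation"),
                   pch = c(16, NA), lty = c(NA, 1),
                   col = c("black", "red"))
  invisible(x)
}
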