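# Candidate parameter-set generation: log-uniform random sampling over the
# search box, and a hybrid genetic local search (generational GA in
# log-parameter space with Nelder-Mead refinement and a minimum-distance
# diversity filter) minimising the cosine fitness.

#' Search-box bounds in log space
#'
#' All parameters are searched in natural-log coordinates on [-15, 5]
#' (values between exp(-15) and exp(5)).
#' @export
log_bounds <- function() c(-15, 5)

#' Draw random parameter sets
#'
#' Each coordinate is drawn independently and uniformly in natural-log
#' space over the search box; values are exp(log values) exactly.
#'
#' @param model a `hub_model`.
#' @param n number of sets.
#' @param seed integer seed (draws are reproducible).
#' @param bounds log-space box, default [-15, 5].
#' @return a `hub_param_sets` data frame: columns `id`, `provenance`,
#'   `fitness`, `label`, then one `log_<name>` column per parameter.
#' @export
random_sample_params <- function(model, n, seed = 1L, bounds = log_bounds()) {
  stopifnot(inherits(model, "hub_model"), n >= 1)
  set.seed(seed)
  d <- length(model$param_names)
  logs <- matrix(stats::runif(n * d, bounds[1], bounds[2]), nrow = n)
  new_param_sets(model, logs, provenance = "random", prefix = "R")
}

new_param_sets <- function(model, log_matrix, provenance, prefix = "P",
                           fitness = NA_real_, label = "unclassified") {
  colnames(log_matrix) <- paste0("log_", model$param_names)
  n <- nrow(log_matrix)
  out <- data.frame(
    id = sprintf("%s%04d", prefix, seq_len(n)),
    provenance = rep_len(provenance, n), fitness = rep_len(fitness, n),
    label = rep_len(label, n), stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(log_matrix))
  structure(out, class = c("hub_param_sets", "data.frame"),
            model_id = model$id, param_names = model$param_names)
}

#' Parameter values of stored sets
#'
#' @param sets a `hub_param_sets` data frame.
#' @param i row index (single set) or missing for all sets.
#' @param log return log coordinates instead of natural values.
#' @return a named vector (single set) or matrix (all sets).
#' @export
param_values <- function(sets, i = NULL, log = FALSE) {
  pn <- attr(sets, "param_names")
  cols <- paste0("log_", pn)
  m <- as.matrix(sets[, cols, drop = FALSE])
  colnames(m) <- pn
  if (!log) m <- exp(m)
  if (is.null(i)) m else stats::setNames(m[i, ], pn)
}

#' Configuration of the genetic local search
#'
#' @param pop_size population size.
#' @param generations number of generations.
#' @param p_crossover per-pair uniform-crossover probability.
#' @param p_mutation per-coordinate Gaussian mutation probability.
#' @param mutation_sd mutation step (log units).
#' @param tournament_k tournament size for selection.
#' @param n_elite individuals copied unchanged each generation (guarantees
#'   monotone best fitness).
#' @param local_every refine elites by Nelder-Mead every this many
#'   generations (0 disables intermediate refinement).
#' @param local_maxit Nelder-Mead iteration budget per refinement (0
#'   disables local search entirely).
#' @param diversity_radius minimum pairwise log-space distance between
#'   returned candidates.
#' @param n_candidates target number of candidates returned.
#' @param seed mandatory integer seed.
#' @param bounds log-space search box.
#' @param redraw_control regenerate the control data (fresh CLE ensemble)
#'   at the start of the estimation round, using a seed derived from `seed`.
#' @return a `search_config` list.
#' @export
search_config <- function(pop_size = 64, generations = 80,
                          p_crossover = 0.9, p_mutation = 0.2,
                          mutation_sd = 0.6, tournament_k = 3,
                          n_elite = 4, local_every = 10, local_maxit = 50,
                          diversity_radius = 0.5,
                          n_candidates = 100, seed = 1L,
                          bounds = log_bounds(), redraw_control = FALSE) {
  cfg <- as.list(environment())
  stopifnot(pop_size >= 1, generations >= 0, n_candidates >= 1,
            !is.null(seed))
  structure(cfg, class = "search_config")
}

# Cosine fitness of one log-parameter vector against control means.
# Integration failure => worst-case fitness N and excluded flag.
ga_objective <- function(model, control, patterns, bounds) {
  pids <- names(control$patterns)
  ctrl_means <- lapply(control$patterns, `[[`, "mean")
  npat <- length(pids)
  function(logp) {
    logp <- pmin(pmax(logp, bounds[1]), bounds[2])
    params <- stats::setNames(exp(logp), model$param_names)
    sims <- tryCatch(
      lapply(patterns[pids], function(pat)
        integrate_ode(model, params, pat,
                      sample_times = control$sample_times)$output),
      hubsens_integration_error = function(e) NULL)
    if (is.null(sims)) return(npat + 1)   # worst case + exclusion margin
    suppressWarnings(cosine_fitness(sims, ctrl_means))
  }
}

#' Estimate candidate parameter sets by genetic local search
#'
#' A generational GA in log-parameter space (tournament selection, uniform
#' crossover, Gaussian mutation, elitism) hybridised with Nelder-Mead local
#' refinement of the elites, minimising the cosine fitness against the
#' control means. The archive of elites across generations is refined,
#' sorted by fitness and filtered so that no two returned sets lie within
#' `diversity_radius` of each other in log space.
#'
#' @param model a `hub_model`.
#' @param control a `control_data` object for the same model.
#' @param config a [search_config()].
#' @param patterns signal patterns (default: all ten).
#' @return a `hub_param_sets` data frame with provenance `"estimated"`,
#'   fitness filled in, plus attributes `history` (best fitness per
#'   generation) and `config`.
#' @export
estimate_parameters <- function(model, control, config = search_config(),
                                patterns = signal_patterns()) {
  stopifnot(inherits(model, "hub_model"), inherits(control, "control_data"),
            inherits(config, "search_config"))
  if (control$model_id != model$id)
    stop("control data were generated for model ", control$model_id,
         call. = FALSE)
  set.seed(config$seed)
  if (isTRUE(config$redraw_control))
    control <- generate_control_data(
      model, n_replicates = control$n_replicates, dt = control$dt,
      seed = derive_seed(config$seed, 777L),
      noise_scale = control$noise_scale,
      sample_times = control$sample_times)

  d <- length(model$param_names)
  lo <- config$bounds[1]; hi <- config$bounds[2]
  fn <- ga_objective(model, control, patterns, config$bounds)
  clampm <- function(m) pmin(pmax(m, lo), hi)

  pop <- matrix(stats::runif(config$pop_size * d, lo, hi),
                nrow = config$pop_size)
  fit <- apply(pop, 1, fn)
  history <- numeric(config$generations)
  archive <- pop
  archive_fit <- fit

  refine <- function(par) {
    res <- stats::optim(par, fn, method = "Nelder-Mead",
                        control = list(maxit = config$local_maxit))
    list(par = clampm(res$par), value = fn(clampm(res$par)))
  }

  gen <- 0
  while (gen < config$generations) {
    gen <- gen + 1
    ord <- order(fit)
    elite_idx <- ord[seq_len(min(config$n_elite, config$pop_size))]
    newpop <- pop[elite_idx, , drop = FALSE]
    while (nrow(newpop) < config$pop_size) {
      pick <- function() {
        cand <- sample.int(config$pop_size, min(config$tournament_k,
                                                config$pop_size))
        cand[which.min(fit[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      child <- p1
      if (stats::runif(1) < config$p_crossover) {
        take <- stats::runif(d) < 0.5
        child[take] <- p2[take]
      }
      mut <- stats::runif(d) < config$p_mutation
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, config$mutation_sd)
      newpop <- rbind(newpop, clampm(child))
    }
    children <- newpop[-seq_along(elite_idx), , drop = FALSE]
    newfit <- c(fit[elite_idx],
                if (nrow(children)) apply(children, 1, fn) else numeric(0))
    pop <- newpop; fit <- newfit

    if (config$local_every > 0 && config$local_maxit > 0 &&
        gen %% config$local_every == 0) {
      best <- which.min(fit)
      r <- refine(pop[best, ])
      if (r$value <= fit[best]) {
        pop[best, ] <- r$par
        fit[best] <- r$value
      }
    }
    history[gen] <- min(fit)
    archive <- rbind(archive, pop)
    archive_fit <- c(archive_fit, fit)
  }

  # distinct archived individuals, best-first
  ord <- order(archive_fit)
  seen <- archive[ord, , drop = FALSE]
  seen_fit <- archive_fit[ord]
  keep <- !duplicated(round(seen, 10))
  seen <- seen[keep, , drop = FALSE]; seen_fit <- seen_fit[keep]

  # greedy diversity filter in log space, then Nelder-Mead refinement of
  # every selected endpoint (candidates = refined global-search endpoints)
  chosen <- integer(0)
  for (i in seq_len(nrow(seen))) {
    if (length(chosen) >= config$n_candidates) break
    if (length(chosen) == 0) {
      chosen <- i
    } else {
      dmin <- min(sqrt(rowSums(
        (seen[chosen, , drop = FALSE] -
           matrix(seen[i, ], nrow = length(chosen), ncol = d,
                  byrow = TRUE))^2)))
      if (dmin >= config$diversity_radius) chosen <- c(chosen, i)
    }
  }
  if (length(chosen) < config$n_candidates)
    warning("diversity radius admits only ", length(chosen), " of ",
            config$n_candidates, " requested candidates")
  cand <- seen[chosen, , drop = FALSE]
  cand_fit <- seen_fit[chosen]
  if (config$local_maxit > 0) {
    for (i in seq_len(nrow(cand))) {
      r <- refine(cand[i, ])
      if (r$value < cand_fit[i]) {
        cand[i, ] <- r$par
        cand_fit[i] <- r$value
      }
    }
  }

  ord <- order(cand_fit)
  out <- new_param_sets(model, cand[ord, , drop = FALSE],
                        provenance = "estimated", prefix = "E",
                        fitness = cand_fit[ord])
  attr(out, "history") <- history
  attr(out, "config") <- config
  out
}
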