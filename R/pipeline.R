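# End-to-end orchestration behind a single run configuration: control data
# -> candidate generation (sampling + search) -> classification ->
# sensitivities -> trend statistics, with CSV artifacts and JSON manifests
# per stage.

PIPELINE_STAGES <- c("control", "sample", "estimate", "classify",
                     "sensitivity", "analyze")

#' Pipeline run configuration
#'
#' @param model_ids models to run, subset of M1-M4.
#' @param seed root seed; every stage derives its streams from it.
#' @param outdir output directory for stage artifacts.
#' @param profile `"quick"` (desk scale: 100 replicates, 1000 random sets,
#'   100 candidates) or `"paper"` (1000 / 10000 / 1000).
#' @param n_replicates,n_random,n_candidates explicit overrides of the
#'   profile scales.
#' @param dt Euler-Maruyama step (min).
#' @param band classification band, `"sd"` or `"se"`.
#' @param scaling alpha scaling mode.
#' @param rel_step sensitivity perturbation.
#' @param noise_scale CLE diffusion multiplier.
#' @param search extra arguments for [search_config()].
#' @return a `run_config` list.
#' @export
run_config <- function(model_ids = "M1", seed = 1L, outdir = "hubsens-run",
                       profile = c("quick", "paper"),
                       n_replicates = NULL, n_random = NULL,
                       n_candidates = NULL, dt = 0.01,
                       band = "sd", scaling = "per_pattern",
                       rel_step = 0.001, noise_scale = 1,
                       search = list()) {
  profile <- match.arg(profile)
  scale <- switch(profile,
                  quick = list(n_replicates = 100, n_random = 1000,
                               n_candidates = 100),
                  paper = list(n_replicates = 1000, n_random = 10000,
                               n_candidates = 1000))
  stopifnot(all(model_ids %in% HUB_MODEL_IDS))
  cfg <- list(model_ids = model_ids, seed = as.integer(seed),
              outdir = outdir, profile = profile,
              n_replicates = n_replicates %||% scale$n_replicates,
              n_random = n_random %||% scale$n_random,
              n_candidates = n_candidates %||% scale$n_candidates,
              dt = dt, band = band, scaling = scaling,
              rel_step = rel_step, noise_scale = noise_scale,
              search = search)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

stage_file <- function(config, model_id, stage, ext = "csv") {
  file.path(config$outdir, sprintf("%s_%s.%s", model_id, stage, ext))
}

write_manifest <- function(config, model_id, stage, inputs, outputs) {
  manifest <- list(
    stage = stage, model = model_id, seed = config$seed,
    config = unclass(config),
    inputs = as.list(if (length(inputs))
      stats::setNames(as.character(tools::md5sum(inputs)), basename(inputs))
      else NULL),
    outputs = basename(outputs))
  jsonlite::write_json(manifest,
                       stage_file(config, model_id, paste0(stage, "_manifest"),
                                  "json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

require_inputs <- function(config, model_id, stage, files) {
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    need <- sub("^.*_(\\w+)\\.csv$", "\\1", missing[1])
    stop("stage '", stage, "' requires outputs of stage '", need,
         "'; run that stage first (missing: ",
         paste(basename(missing), collapse = ", "), ")", call. = FALSE)
  }
  invisible(files)
}

read_sets_csv <- function(model, path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("hub_param_sets", "data.frame"),
            model_id = model$id, param_names = model$param_names)
}

control_from_csv <- function(model_id, csv, sidecar) {
  df <- utils::read.csv(csv, stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(sidecar)
  pats <- split(df, df$pattern)
  pats <- pats[unique(df$pattern)]
  per <- lapply(pats, function(p) {
    p <- p[order(p$time), ]
    list(mean = p$mean, sd = p$sd, se = p$se,
         norm_mean = sqrt(sum(p$mean^2)))
  })
  structure(list(model_id = model_id, n_replicates = meta$n_replicates,
                 sample_times = sort(unique(df$time)), patterns = per,
                 dt = meta$dt, rng_seed = meta$seed,
                 noise_scale = meta$noise_scale),
            class = "control_data")
}

#' Run one pipeline stage
#'
#' Stages: `control` (CLE replicate ensembles at the original parameters),
#' `sample` (log-uniform random sets), `estimate` (genetic local search),
#' `classify` (fitness + positive/negative labels for all candidate sets),
#' `sensitivity` (log-sensitivity table of labeled sets), `analyze`
#' (dominance percentages, z-scores, PCA, integral-sensitivity
#' correlations). Each stage writes CSV artifacts plus a JSON manifest
#' (config snapshot, seed, input hashes) into `config$outdir`, checks that
#' its prerequisite stage outputs exist, and is deterministic given the
#' same configuration.
#'
#' @param stage one of the stage names above.
#' @param config a [run_config()].
#' @param dry_run print the execution plan without computing.
#' @return (invisibly) the paths of the files written.
#' @export
run_stage <- function(stage, config, dry_run = FALSE) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  stopifnot(inherits(config, "run_config"))
  if (dry_run) {
    for (m in config$model_ids)
      cat("would run stage '", stage, "' for model ", m, " -> ",
          stage_file(config, m, stage), "\n", sep = "")
    return(invisible(character(0)))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (m in config$model_ids)
    written <- c(written, run_stage_one(stage, config, m))
  invisible(written)
}

run_stage_one <- function(stage, config, model_id) {
  model <- hub_model(model_id)
  out <- stage_file(config, model_id, stage)
  f <- function(s) stage_file(config, model_id, s)

  if (stage == "control") {
    ctrl <- generate_control_data(model, n_replicates = config$n_replicates,
                                  dt = config$dt, seed = config$seed,
                                  noise_scale = config$noise_scale)
    utils::write.csv(as.data.frame(ctrl), out, row.names = FALSE)
    side <- stage_file(config, model_id, "control_meta", "json")
    jsonlite::write_json(list(model = model_id, seed = config$seed,
                              dt = config$dt,
                              n_replicates = config$n_replicates,
                              noise_scale = config$noise_scale),
                         side, auto_unbox = TRUE, digits = NA)
    write_manifest(config, model_id, stage, character(0), c(out, side))
    return(c(out, side))
  }

  if (stage == "sample") {
    sets <- random_sample_params(model, config$n_random,
                                 seed = derive_seed(config$seed, 555L))
    utils::write.csv(as.data.frame(sets), out, row.names = FALSE)
    write_manifest(config, model_id, stage, character(0), out)
    return(out)
  }

  if (stage == "estimate") {
    ins <- require_inputs(config, model_id, stage,
                          c(f("control"),
                            stage_file(config, model_id, "control_meta",
                                       "json")))
    ctrl <- control_from_csv(model_id, ins[1], ins[2])
    cfg <- do.call(search_config,
                   utils::modifyList(list(seed = config$seed,
                                          n_candidates = config$n_candidates),
                                     config$search))
    est <- estimate_parameters(model, ctrl, cfg)
    utils::write.csv(as.data.frame(est), out, row.names = FALSE)
    write_manifest(config, model_id, stage, ins, out)
    return(out)
  }

  if (stage == "classify") {
    ins <- require_inputs(config, model_id, stage,
                          c(f("control"),
                            stage_file(config, model_id, "control_meta",
                                       "json"),
                            f("sample"), f("estimate")))
    ctrl <- control_from_csv(model_id, ins[1], ins[2])
    sets <- rbind_param_sets(model,
                             read_sets_csv(model, ins[4]),
                             read_sets_csv(model, ins[3]))
    for (i in seq_len(nrow(sets))) {
      rep <- evaluate_candidate(model, param_values(sets, i), ctrl,
                                band = config$band,
                                scaling = config$scaling,
                                set_id = sets$id[i])
      sets$fitness[i] <- rep$fitness
      sets$label[i] <- rep$label
    }
    utils::write.csv(as.data.frame(sets), out, row.names = FALSE)
    write_manifest(config, model_id, stage, ins, out)
    return(out)
  }

  if (stage == "sensitivity") {
    ins <- require_inputs(config, model_id, stage, f("classify"))
    sets <- read_sets_csv(model, ins)
    sets <- sets[sets$label %in% c("positive", "negative"), , drop = FALSE]
    attr(sets, "param_names") <- model$param_names
    tab <- build_sensitivity_table(model, sets, rel_step = config$rel_step)
    utils::write.csv(as.data.frame(tab), out, row.names = FALSE)
    write_manifest(config, model_id, stage, ins, out)
    return(out)
  }

  # analyze
  ins <- require_inputs(config, model_id, stage, f("sensitivity"))
  tab <- utils::read.csv(ins, stringsAsFactors = FALSE)
  attr(tab, "model_id") <- model_id
  outs <- character(0)
  pats <- unique(tab$pattern)
  labs <- "positive"
  if (!any(tab$label == "positive")) {
    warning("no positive sets for model ", model_id,
            "; trend statistics computed over all classified sets")
    labs <- c("positive", "negative")
  }
  dom <- do.call(rbind, lapply(pats, function(p) {
    d <- pairwise_dominance(tab, p, label_filter = labs)
    d$pattern <- p
    d
  }))
  p_dom <- stage_file(config, model_id, "dominance")
  utils::write.csv(dom, p_dom, row.names = FALSE)
  outs <- c(outs, p_dom)

  z <- zscore_across_reactions(tab, pats[[min(3, length(pats))]],
                               label_filter = labs)
  p_z <- stage_file(config, model_id, "zscore")
  utils::write.csv(data.frame(set_id = rownames(z), z,
                              check.names = FALSE),
                   p_z, row.names = FALSE)
  outs <- c(outs, p_z)

  pos <- tab[tab$label == "positive", , drop = FALSE]
  if (length(unique(pos$set_id)) >= 3) {
    pca <- sensitivity_pca(tab, label_filter = "positive")
    p_pca <- stage_file(config, model_id, "pca_scores")
    utils::write.csv(data.frame(set_id = rownames(pca$scores), pca$scores,
                                check.names = FALSE),
                     p_pca, row.names = FALSE)
    outs <- c(outs, p_pca)
  }

  corr <- integral_sensitivity_correlation(tab, label_filter = labs)
  p_corr <- stage_file(config, model_id, "correlation")
  utils::write.csv(corr, p_corr, row.names = FALSE)
  outs <- c(outs, p_corr)

  write_manifest(config, model_id, stage, ins, outs)
  outs
}

#' Run the full pipeline
#' @param config a [run_config()].
#' @param dry_run print the execution plan only.
#' @return (invisibly) all files written.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  written <- character(0)
  for (st in PIPELINE_STAGES)
    written <- c(written, run_stage(st, config, dry_run = dry_run))
  invisible(written)
}
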