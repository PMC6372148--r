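# Signaling-hub model definitions: four motifs (M1-M4) loaded from the
# versioned JSON files under inst/extdata/models, plus a documented
# constructor for user-defined networks (used for the toy/test systems).

RATE_TYPES <- c(mass_action = 0L, mm = 1L, mm_signal = 2L, mm_mod = 3L,
                zero_order = 4L, zero_order_signal = 5L, linear = 6L)

HUB_MODEL_IDS <- c("M1", "M2", "M3", "M4")

#' Build a signaling-hub model
#'
#' Loads one of the four canonical hub motifs: M1 reversible reaction,
#' M2 cycle, M3 negative feedback loop, M4 incoherent feedforward loop.
#' The returned object carries the species, conserved pools, reactions
#' (Michaelis-Menten or mass-action rate laws), stoichiometry, the output
#' variable X* and the reference ("original") parameter values used to
#' generate control data.
#'
#' @param id one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @return an object of class `hub_model`.
#' @export
hub_model <- function(id) {
  if (!(is.character(id) && length(id) == 1L && id %in% HUB_MODEL_IDS))
    stop("unknown model id: ", deparse(substitute(id)),
         " (expected one of ", paste(HUB_MODEL_IDS, collapse = ", "), ")",
         call. = FALSE)
  path <- system.file("extdata", "models", paste0(id, ".json"),
                      package = "hubsens", mustWork = TRUE)
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  reactions <- lapply(spec$reactions, function(r) {
    list(label = r$label, type = r$type,
         from = r$from, to = r$to,
         substrate = r$substrate, modifier = r$modifier,
         k_name = r$k$name, k_value = r$k$value,
         km_name = if (!is.null(r$km)) r$km$name else NA_character_,
         km_value = if (!is.null(r$km)) r$km$value else NA_real_,
         drift = TRUE, noise = TRUE)
  })
  define_hub_model(
    id = spec$id,
    name = spec$name,
    species = vapply(spec$species, function(s) s$name, ""),
    init = vapply(spec$species, function(s) as.numeric(s$init), 0),
    reactions = reactions,
    output = spec$output,
    pools = lapply(spec$pools, function(p)
      list(members = unlist(p$members), total = p$total))
  )
}

#' Define a hub-style reaction network
#'
#' Extension point for networks beyond the four built-in motifs, and the
#' constructor used internally by [hub_model()]. Each reaction is a list with
#' fields `label`, `type` (one of `mass_action`, `mm`, `mm_signal`, `mm_mod`,
#' `zero_order`, `zero_order_signal`), `from`/`to` species (either may be
#' `NULL` for birth/death steps), `substrate`, optional `modifier`, the rate
#' constant (`k_name`, `k_value`) and, for Michaelis-Menten types, the
#' Michaelis constant (`km_name`, `km_value`). Optional logical fields
#' `drift` and `noise` switch the reaction's contribution to the
#' deterministic drift and the Langevin diffusion term (both default `TRUE`).
#'
#' @param id model label.
#' @param species character vector of species names.
#' @param init named or positional numeric vector of initial amounts.
#' @param reactions list of reaction specifications (see Details).
#' @param output name of the output species X*.
#' @param pools list of conserved pools, each `list(members=, total=)`.
#' @param name optional descriptive name.
#' @return an object of class `hub_model`.
#' @export
define_hub_model <- function(id, species, init, reactions, output,
                             pools = list(), name = id) {
  stopifnot(is.character(species), length(species) >= 1L,
            length(init) == length(species))
  init <- stats::setNames(as.numeric(init), species)
  if (!output %in% species)
    stop("output species '", output, "' not among species", call. = FALSE)

  labels <- vapply(reactions, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicate reaction labels", call. = FALSE)

  reactions <- lapply(reactions, function(r) {
    if (!r$type %in% names(RATE_TYPES))
      stop("unknown rate law type '", r$type, "'", call. = FALSE)
    r$drift <- if (is.null(r$drift)) TRUE else isTRUE(r$drift)
    r$noise <- if (is.null(r$noise)) TRUE else isTRUE(r$noise)
    if (is.null(r$km_name)) r$km_name <- NA_character_
    if (is.null(r$km_value)) r$km_value <- NA_real_
    for (fld in c("from", "to", "substrate", "modifier"))
      if (!is.null(r[[fld]]) && !is.na(r[[fld]]) && !r[[fld]] %in% species)
        stop("reaction ", r$label, ": unknown species '", r[[fld]], "'",
             call. = FALSE)
    r
  })

  # original (reference) parameter vector, k's then km's in reaction order
  pnames <- character(0)
  pvals <- numeric(0)
  for (r in reactions) {
    pnames <- c(pnames, r$k_name)
    pvals <- c(pvals, r$k_value)
    if (!is.na(r$km_name)) {
      pnames <- c(pnames, r$km_name)
      pvals <- c(pvals, r$km_value)
    }
  }
  if (anyDuplicated(pnames))
    stop("each parameter name must appear in exactly one reaction",
         call. = FALSE)
  params <- stats::setNames(pvals, pnames)

  # stoichiometry matrix, species x reactions
  stoich <- matrix(0L, nrow = length(species), ncol = length(reactions),
                   dimnames = list(species, labels))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    if (!is.null(r$from)) stoich[r$from, j] <- stoich[r$from, j] - 1L
    if (!is.null(r$to))   stoich[r$to, j]   <- stoich[r$to, j] + 1L
  }

  structure(
    list(id = id, name = name, species = species, init = init,
         pools = pools, output = output,
         output_index = match(output, species),
         reactions = reactions, labels = labels,
         params = params, param_names = pnames,
         # the rate constant perturbed for each reaction's sensitivity
         rate_params = stats::setNames(
           vapply(reactions, `[[`, "", "k_name"), labels),
         stoich = stoich),
    class = "hub_model")
}

#' @export
print.hub_model <- function(x, ...) {
  cat("<hub_model> ", x$id, ": ", x$name, "\n", sep = "")
  cat("  species: ", paste(x$species, collapse = ", "),
      "  (output: ", x$output, ")\n", sep = "")
  cat("  reactions:", paste(x$labels, collapse = ", "), "\n")
  cat("  parameters:",
      paste(sprintf("%s=%g", x$param_names, x$params), collapse = ", "),
      "\n")
  invisible(x)
}

#' Reaction table of a hub model
#'
#' @param model a `hub_model`.
#' @return data frame with one row per reaction.
#' @export
hub_reactions <- function(model) {
  stopifnot(inherits(model, "hub_model"))
  data.frame(
    label = model$labels,
    type = vapply(model$reactions, `[[`, "", "type"),
    rate_param = vapply(model$reactions, `[[`, "", "k_name"),
    km_param = vapply(model$reactions, `[[`, "", "km_name"),
    stringsAsFactors = FALSE)
}

#' Stoichiometry matrix
#' @param model a `hub_model`.
#' @return integer matrix, species by reactions.
#' @export
stoichiometry <- function(model) {
  stopifnot(inherits(model, "hub_model"))
  model$stoich
}

#' Evaluate reaction rates (propensities)
#'
#' Evaluates every reaction's rate law at a given species state, signal
#' level and parameter vector. Mass-action rates are linear in their
#' substrate; Michaelis-Menten rates saturate.
#'
#' @param model a `hub_model`.
#' @param state named (or model-ordered) non-negative species vector.
#' @param s signal concentration, a non-negative scalar.
#' @param params named positive parameter vector; defaults to the model's
#'   original values.
#' @return named vector of non-negative reaction rates.
#' @export
evaluate_rates <- function(model, state, s, params = model$params) {
  stopifnot(inherits(model, "hub_model"))
  state <- resolve_state(model, state)
  params <- resolve_params(model, params)
  if (any(state < 0)) stop("negative species state", call. = FALSE)
  if (any(params <= 0)) stop("non-positive parameter value", call. = FALSE)
  if (!is.finite(s) || s < 0) stop("invalid signal value", call. = FALSE)

  a <- vapply(model$reactions, function(r) {
    k <- params[[r$k_name]]
    S <- if (is.null(r$substrate)) 1 else state[[r$substrate]]
    M <- if (is.null(r$modifier)) 1 else state[[r$modifier]]
    switch(r$type,
           mass_action = k * S,
           mm = k * S / (params[[r$km_name]] + S),
           mm_signal = k * s * S / (params[[r$km_name]] + S),
           mm_mod = k * M * S / (params[[r$km_name]] + S),
           zero_order = k,
           zero_order_signal = k * s,
           linear = k * S)
  }, 0)
  stats::setNames(a, model$labels)
}

resolve_state <- function(model, state) {
  if (!is.null(names(state))) {
    miss <- setdiff(model$species, names(state))
    if (length(miss))
      stop("state is missing species: ", paste(miss, collapse = ", "),
           call. = FALSE)
    state <- state[model$species]
  } else if (length(state) != length(model$species)) {
    stop("state has wrong length", call. = FALSE)
  } else {
    names(state) <- model$species
  }
  as.numeric(state) -> v
  stats::setNames(v, model$species)
}

resolve_params <- function(model, params) {
  if (!is.null(names(params))) {
    miss <- setdiff(model$param_names, names(params))
    if (length(miss))
      stop("params is missing: ", paste(miss, collapse = ", "), call. = FALSE)
    params <- params[model$param_names]
  } else if (length(params) != length(model$param_names)) {
    stop("params has wrong length", call. = FALSE)
  } else {
    names(params) <- model$param_names
  }
  stats::setNames(as.numeric(params), model$param_names)
}

# Flatten model + params + signal pattern into the numeric encoding the
# compiled code consumes (layout documented in src/hub.c).
encode_model <- function(model, params, pattern) {
  params <- resolve_params(model, params)
  enc <- c(length(model$species), length(model$reactions),
           pattern$amplitude, pattern$beta_on, pattern$beta_off,
           pattern$t_switch, pattern$baseline)
  for (r in model$reactions) {
    idx <- function(sp) if (is.null(sp)) 0L else match(sp, model$species)
    enc <- c(enc,
             RATE_TYPES[[r$type]],
             params[[r$k_name]],
             if (is.na(r$km_name)) 0 else params[[r$km_name]],
             idx(r$substrate), idx(r$modifier), idx(r$from), idx(r$to),
             as.integer(r$drift), as.integer(r$noise))
  }
  as.numeric(enc)
}
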