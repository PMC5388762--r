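#' Load and validate a metabolic network model
#'
#' Reads a structured network configuration (YAML file or an equivalent R
#' list) defining species, compartments, reactions, rate laws and kinetic
#' constants, and returns a validated `pdac_network` object. Validation
#' collects *every* violation before failing, so a broken configuration is
#' reported in full rather than one error at a time.
#'
#' Species are one of three types: `dynamic` (mass-balanced ODE states),
#' `fixed` (held constant, e.g. the mitochondrial adenylate and NAD pools) and
#' `boundary` (set by the experimental protocol, e.g. media glucose).
#'
#' @param config path to a YAML configuration, or a list with the same
#'   structure (see `inst/extdata/pdac_network.yaml` for the schema).
#' @return a `pdac_network` object.
#' @export
load_network <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  errs <- character(0)
  bad <- function(...) errs[[length(errs) + 1L]] <<- paste0(...)

  ## ---- species ----
  sp <- cfg$species
  species <- data.frame(
    id = vapply(sp, `[[`, "", "id"),
    compartment = vapply(sp, `[[`, "", "compartment"),
    type = vapply(sp, function(s) s$type %||% "dynamic", ""),
    conc = vapply(sp, function(s) as.numeric(s$conc %||% NA_real_), 0),
    pool = vapply(sp, function(s) s$pool %||% sub("^m", "", s$id), ""),
    lhs_copy_of = vapply(sp, function(s) s$lhs_copy_of %||% NA_character_, ""),
    stringsAsFactors = FALSE)
  dup <- species$id[duplicated(paste(species$id, species$compartment))]
  for (d in dup) bad("duplicate species id within compartment: ", d)
  if (anyDuplicated(species$id))
    bad("duplicate species id: ",
        paste(unique(species$id[duplicated(species$id)]), collapse = ", "))
  neg <- species$id[!is.na(species$conc) & species$conc < 0]
  for (d in neg) bad("negative initial concentration for species: ", d)
  if (!all(species$type %in% c("dynamic", "fixed", "boundary")))
    bad("species type must be dynamic/fixed/boundary")

  ## ---- reactions ----
  rxs <- lapply(cfg$reactions, function(r) {
    list(id = r$id,
         pathway = r$pathway %||% "",
         form = r$form,
         akt_modulated = isTRUE(r$akt_modulated),
         explicit_vr = isTRUE(r$explicit_vr),
         stoich = unlist(r$stoich),
         subs = as.character(unlist(r$substrates)),
         pros = as.character(unlist(r$products)),
         modifiers = lapply(r$modifiers %||% list(), function(m)
           list(type = m$type, species = m$species)),
         params = lapply(r$params, as.numeric))
  })
  ids <- vapply(rxs, `[[`, "", "id")
  if (anyDuplicated(ids))
    bad("duplicate reaction id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (r in rxs) {
    if (!r$form %in% .RATE_FORMS)
      bad("reaction ", r$id, ": unknown rate-law form '", r$form, "'")
    if (!length(r$stoich))
      bad("reaction ", r$id, ": empty stoichiometry")
    unk <- setdiff(names(r$stoich), species$id)
    if (length(unk))
      bad("reaction ", r$id, ": stoichiometry references undeclared metabolite ",
          paste(unk, collapse = ", "))
    roles <- c(r$subs, r$pros)
    out <- setdiff(roles, names(r$stoich))
    if (length(out))
      bad("reaction ", r$id, ": rate-law role not among participants: ",
          paste(out, collapse = ", "))
    munk <- setdiff(vapply(r$modifiers, `[[`, "", "species"), species$id)
    if (length(munk))
      bad("reaction ", r$id, ": modifier references undeclared metabolite ",
          paste(munk, collapse = ", "))
    for (pn in names(r$params)) {
      val <- r$params[[pn]]
      if (!is.finite(val) || val <= 0)
        bad("reaction ", r$id, ": kinetic constant ", pn,
            " must be strictly positive (got ", val, ")")
    }
    if (r$explicit_vr && is.null(r$params$Vr))
      bad("reaction ", r$id, ": explicit_vr set but no Vr declared")
    if (r$explicit_vr && is.null(r$params$Veq))
      bad("reaction ", r$id, ": explicit_vr set but no Veq declared")
    if (is.null(r$params$Vf))
      bad("reaction ", r$id, ": no forward velocity Vf declared")
  }
  if (length(errs))
    stop("network validation failed with ", length(errs), " problem(s):\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)

  ## ---- assembled structures ----
  nsp <- nrow(species); nrx <- length(rxs)
  S <- matrix(0, nsp, nrx, dimnames = list(species$id, ids))
  for (j in seq_len(nrx)) S[names(rxs[[j]]$stoich), j] <- rxs[[j]]$stoich

  inv <- unlist(lapply(rxs, function(r) {
    p <- unlist(r$params)
    names(p) <- paste0(r$id, ".", names(p))
    p
  }))

  growth <- if (is.null(cfg$growth))
    c(alpha_atp = 0, alpha_glc = 0, alpha_gln = 0, alpha_d = 0,
      k_ap = 1, k_gc = 1, k_gn = 1, K_CC = 1)
  else unlist(cfg$growth)
  model <- structure(list(
    name = cfg$metadata$name %||% "network",
    metadata = cfg$metadata,
    species = species,
    reactions = rxs,
    reaction_ids = ids,
    S = S,
    inventory = inv,
    growth = growth,
    akt = list(basal = cfg$akt$basal %||% 0.2, span = cfg$akt$span %||% 0.8),
    panel = as.character(unlist(cfg$panel)),
    defaults = cfg$defaults %||% list(),
    ## mutable simulation state
    akt_level = 1,
    knockdown = stats::setNames(numeric(nrx), ids),
    constrained = stats::setNames(logical(nrx), ids),
    vf_override = stats::setNames(rep(NA_real_, nrx), ids),
    vr_override = stats::setNames(rep(NA_real_, nrx), ids)
  ), class = "pdac_network")
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference pancreatic-cancer metabolic network
#'
#' Loads the packaged reference configuration: 46 dynamic metabolites in
#' cytosolic, mitochondrial and extracellular compartments, 53 enzymatic
#' reactions (glycolysis, glutaminolysis, TCA cycle, PPP, shuttles), 71
#' forward/reverse maximal velocities and 372 kinetic parameters in total.
#'
#' @return a validated `pdac_network`.
#' @export
reference_network <- function() {
  load_network(system.file("extdata", "pdac_network.yaml",
                           package = "pdacmet", mustWork = TRUE))
}

#' Structural counts of a network model
#'
#' @param model a `pdac_network`.
#' @return list with `metabolites` (dynamic species), `reactions`,
#'   `velocities` (forward plus explicit reverse maximal velocities),
#'   `parameters` (full kinetic inventory incl. velocities) and `states`
#'   (ODE count: dynamic metabolites + cell number).
#' @export
network_counts <- function(model) {
  nvel <- sum(vapply(model$reactions, function(r) 1L + as.integer(r$explicit_vr), 0L))
  list(metabolites = sum(model$species$type == "dynamic"),
       reactions = length(model$reactions),
       velocities = nvel,
       parameters = length(model$inventory),
       states = sum(model$species$type == "dynamic") + 1L)
}

#' Flat kinetic-parameter inventory
#'
#' @param model a `pdac_network`.
#' @return named numeric vector, names of the form `<reaction>.<constant>`.
#' @export
parameter_inventory <- function(model) model$inventory

#' @export
print.pdac_network <- function(x, ...) {
  ct <- network_counts(x)
  cat("<pdac_network> ", x$name, "\n",
      "  metabolites: ", ct$metabolites, " dynamic (+",
      sum(x$species$type == "fixed"), " fixed, ",
      sum(x$species$type == "boundary"), " boundary)\n",
      "  reactions:   ", ct$reactions, "  velocities: ", ct$velocities,
      "  parameters: ", ct$parameters, "\n",
      "  constrained Vr: ", sum(x$constrained),
      "  knockdowns: ", sum(x$knockdown > 0),
      "  AKT level: ", x$akt_level, "\n", sep = "")
  invisible(x)
}

#' Effective forward/reverse velocities
#'
#' Resolves the current effective velocities of every reaction: nominal (or
#' estimation-stage override) values, scaled by active knockdowns
#' (`Vf * (1 - alpha)`) and AKT modulation
#' (`Vf * (basal + span * akt_level)` for AKT-modulated reactions).
#' Equilibrium-constrained reverse velocities track `Vf_eff / Veq`.
#'
#' @param model a `pdac_network`.
#' @return list of numeric vectors `vf`, `vr` (0 where no explicit reverse
#'   velocity exists).
#' @export
effective_velocities <- function(model) {
  n <- length(model$reactions)
  vf <- numeric(n); vr <- numeric(n)
  for (i in seq_len(n)) {
    r <- model$reactions[[i]]
    f <- model$vf_override[i]
    if (is.na(f)) f <- r$params$Vf
    f <- f * (1 - model$knockdown[i])
    if (r$akt_modulated)
      f <- f * (model$akt$basal + model$akt$span * model$akt_level)
    vf[i] <- f
    if (r$explicit_vr) {
      if (model$constrained[i]) {
        vr[i] <- f / r$params$Veq
      } else {
        b <- model$vr_override[i]
        vr[i] <- if (is.na(b)) r$params$Vr else b
      }
    }
  }
  list(vf = vf, vr = vr)
}

#' AKT-modulated glycolytic activity
#'
#' GLUT1, HK and PFK are modelled with 20% basal activity plus 80%
#' AKT-driven activity: their effective maximal velocity is
#' `Vmax * (0.2 + 0.8 * akt_level)`.
#'
#' @param model a `pdac_network` containing AKT-modulated reactions.
#' @param akt_level fraction in \[0, 1\]; 1 = fully active AKT (default
#'   cancerous state), 0 = basal activity only.
#' @return the model with the AKT level applied.
#' @export
apply_akt_modulation <- function(model, akt_level) {
  if (!is.numeric(akt_level) || length(akt_level) != 1 ||
      is.na(akt_level) || akt_level < 0 || akt_level > 1)
    stop("akt_level must be a single number in [0, 1]")
  if (!any(vapply(model$reactions, `[[`, TRUE, "akt_modulated")))
    stop("model declares no AKT-modulated reactions")
  model$akt_level <- akt_level
  model
}

#' Simulate enzyme knockdown
#'
#' Reduces the forward maximal velocity of the target reaction(s) by the
#' knockdown fraction alpha: `Vf_eff = Vf * (1 - alpha)`. An
#' equilibrium-constrained reverse velocity is recomputed as `Vf_eff / Veq`;
#' all other parameters are untouched. `alpha = 0.85` emulates the average
#' shRNA GOT1 knockdown used for model training.
#'
#' @param model a `pdac_network`.
#' @param reaction_ids character vector of reaction ids to knock down.
#' @param alpha knockdown fraction in \[0, 1\] (1 = complete knockout).
#' @return the model with knockdowns applied.
#' @export
apply_knockdown <- function(model, reaction_ids, alpha = 0.85) {
  if (!is.numeric(alpha) || any(is.na(alpha)) || any(alpha < 0) || any(alpha > 1))
    stop("alpha must be in [0, 1]")
  unk <- setdiff(reaction_ids, model$reaction_ids)
  if (length(unk)) stop("unknown reaction id: ", paste(unk, collapse = ", "))
  model$knockdown[reaction_ids] <- alpha
  model
}

#' Names of the free velocity parameters
#'
#' Forward velocities of every reaction plus the explicit reverse velocities
#' that have not been bound by the equilibrium constraint `Vr = Vf/Veq`.
#'
#' @param model a `pdac_network`.
#' @return character vector of names like `"GAPDH.Vf"`, `"GAPDH.Vr"`.
#' @export
free_velocity_names <- function(model) {
  out <- character(0)
  for (r in model$reactions) {
    out <- c(out, paste0(r$id, ".Vf"))
    if (r$explicit_vr && !model$constrained[r$id])
      out <- c(out, paste0(r$id, ".Vr"))
  }
  out
}

#' Override velocity values (estimation stage)
#'
#' @param model a `pdac_network`.
#' @param values named numeric vector, names like `"HK.Vf"` / `"GAPDH.Vr"`.
#' @return the model with velocity overrides set.
#' @export
set_velocities <- function(model, values) {
  if (is.null(names(values))) stop("values must be named (e.g. 'HK.Vf')")
  for (nm in names(values)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% model$reaction_ids ||
        !parts[2] %in% c("Vf", "Vr"))
      stop("bad velocity name: ", nm)
    if (values[[nm]] < 0) stop("velocity must be non-negative: ", nm)
    if (parts[2] == "Vf") model$vf_override[parts[1]] <- values[[nm]]
    else model$vr_override[parts[1]] <- values[[nm]]
  }
  model
}

#' Current nominal velocity values (with overrides)
#'
#' @param model a `pdac_network`.
#' @param names which velocities to return; default all free velocities.
#' @return named numeric vector.
#' @export
get_velocities <- function(model, names = free_velocity_names(model)) {
  out <- numeric(length(names)); names(out) <- names
  for (nm in names) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    r <- model$reactions[[match(parts[1], model$reaction_ids)]]
    if (parts[2] == "Vf") {
      v <- model$vf_override[parts[1]]
      out[nm] <- if (is.na(v)) r$params$Vf else v
    } else {
      v <- model$vr_override[parts[1]]
      out[nm] <- if (is.na(v)) r$params$Vr else v
    }
  }
  out
}

#' Default initial state of a model
#'
#' Concentrations from the configuration (validated initial condition for the
#' reference network), with relative cell number 1.
#'
#' @param model a `pdac_network`.
#' @param ic optional named vector overriding dynamic metabolite
#'   concentrations.
#' @return named state vector over all species plus `C_N`.
#' @export
initial_state <- function(model, ic = NULL) {
  x <- stats::setNames(model$species$conc, model$species$id)
  if (!is.null(ic)) {
    unk <- setdiff(names(ic), model$species$id)
    if (length(unk)) stop("unknown species in ic: ", paste(unk, collapse = ", "))
    x[names(ic)] <- ic
  }
  c(x, C_N = 1)
}
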