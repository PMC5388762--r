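#' Experimental protocol
#'
#' A protocol fixes the simulation horizon, a piecewise-constant media
#' schedule for extracellular glucose and glutamine, enzyme knockdowns with
#' onset times, and the AKT activation level. Media segments must tile
#' `[0, duration]` without gaps.
#'
#' @param duration total simulated time (min).
#' @param media data.frame with columns `t_start` (min; first row must be 0,
#'   strictly increasing), `glc`, `gln` (mM). Each row holds until the next.
#' @param knockdowns data.frame with columns `reaction`, `alpha`
#'   (fraction in \[0,1\]) and optionally `onset` (min, default 0:
#'   cells pre-transduced as in shRNA experiments).
#' @param akt_level AKT activation fraction in \[0,1\].
#' @return a `pdac_protocol` object.
#' @export
protocol <- function(duration = 7200,
                     media = data.frame(t_start = 0, glc = 35, gln = 6),
                     knockdowns = NULL,
                     akt_level = 1) {
  if (duration < 0) stop("duration must be non-negative")
  if (!nrow(media) || media$t_start[1] != 0)
    stop("media schedule must start at t = 0")
  if (is.unsorted(media$t_start, strictly = TRUE))
    stop("media t_start must be strictly increasing")
  if (any(media$t_start > duration))
    stop("media segment starts beyond protocol duration")
  if (any(media$glc < 0) || any(media$gln < 0))
    stop("media concentrations must be non-negative")
  if (!is.null(knockdowns) && nrow(knockdowns)) {
    if (is.null(knockdowns$onset)) knockdowns$onset <- 0
    if (any(knockdowns$alpha < 0) || any(knockdowns$alpha > 1))
      stop("knockdown alpha must be in [0, 1]")
  } else knockdowns <- data.frame(reaction = character(0), alpha = numeric(0),
                                  onset = numeric(0))
  if (akt_level < 0 || akt_level > 1) stop("akt_level must be in [0, 1]")
  structure(list(duration = duration, media = media,
                 knockdowns = knockdowns, akt_level = akt_level),
            class = "pdac_protocol")
}

#' Complete-media protocol (35 mM glucose, 6 mM glutamine)
#'
#' @param days horizon in days (default 5).
#' @param knockdowns optional knockdown table (see [protocol()]).
#' @param glc,gln media concentrations (mM).
#' @export
protocol_complete <- function(days = 5, knockdowns = NULL, glc = 35, gln = 6) {
  protocol(duration = days * 1440,
           media = data.frame(t_start = 0, glc = glc, gln = gln),
           knockdowns = knockdowns)
}

#' Nutrient-deprivation protocol
#'
#' Complete media followed by glucose and glutamine withdrawal at
#' `t_switch` (default 24 h), for a 5-day horizon.
#'
#' @param days horizon in days.
#' @param t_switch deprivation onset (min).
#' @param knockdowns optional knockdown table.
#' @export
protocol_deprivation <- function(days = 5, t_switch = 1440, knockdowns = NULL) {
  protocol(duration = days * 1440,
           media = data.frame(t_start = c(0, t_switch),
                              glc = c(35, 0), gln = c(6, 0)),
           knockdowns = knockdowns)
}

#' Simulate the coupled metabolism + growth system
#'
#' Integrates the 46 metabolite ODEs plus the cell-number equation with a
#' stiff solver (default `lsoda`, relative tolerance 1e-8, absolute
#' tolerance 1e-12 mM so nutrient-depleted species approach zero cleanly). The solver is restarted at every media switch and
#' knockdown onset so discontinuities never cross an integration step.
#' Reaction fluxes are recorded at the output times.
#'
#' @param model a `pdac_network`.
#' @param init optional named vector of initial concentrations for (a subset
#'   of) the species; defaults to the configuration baseline. `C_N` starts
#'   at 1 (relative to inoculum).
#' @param proto a `pdac_protocol`.
#' @param times output times (min); default every 30 min over the protocol.
#' @param rtol,atol solver tolerances.
#' @param method deSolve integrator.
#' @param maxsteps maximal internal steps per output interval.
#' @return a `pdac_trajectory`: list with `times`, `conc` (time x species
#'   matrix, mM), `cell_number`, `flux` (time x reaction, mM/min) and the
#'   protocol.
#' @export
simulate <- function(model, init = NULL, proto = protocol_complete(),
                     times = NULL, rtol = 1e-8, atol = 1e-12,
                     method = "lsoda", maxsteps = 100000) {
  unk <- setdiff(proto$knockdowns$reaction, model$reaction_ids)
  if (length(unk)) stop("protocol knocks down unknown reaction: ",
                        paste(unk, collapse = ", "))
  if (any(vapply(model$reactions, `[[`, TRUE, "akt_modulated")))
    model <- apply_akt_modulation(model, proto$akt_level)
  ns <- nrow(model$species)
  nr <- length(model$reactions)
  state <- initial_state(model, init)

  if (is.null(times))
    times <- seq(0, proto$duration, by = min(30, max(proto$duration, 1)))
  times <- sort(unique(c(0, times[times <= proto$duration], proto$duration)))

  set_media <- function(state, t) {
    seg <- findInterval(t, proto$media$t_start)
    state[["GLC_e"]] <- proto$media$glc[seg]
    state[["GLN_e"]] <- proto$media$gln[seg]
    state
  }
  has_media <- all(c("GLC_e", "GLN_e") %in% model$species$id)

  if (proto$duration == 0) {
    if (has_media) state <- set_media(state, 0)
    rhs <- assemble_rhs(model, state)
    return(structure(list(times = 0,
                          conc = matrix(state[seq_len(ns)], 1,
                                        dimnames = list(NULL, model$species$id)),
                          cell_number = state[["C_N"]],
                          flux = matrix(rhs$flux, 1,
                                        dimnames = list(NULL, model$reaction_ids)),
                          protocol = proto, model = model$name),
                     class = "pdac_trajectory"))
  }

  brk <- sort(unique(c(0, proto$media$t_start, proto$knockdowns$onset,
                       proto$duration)))
  brk <- brk[brk <= proto$duration]
  if (brk[length(brk)] < proto$duration) brk <- c(brk, proto$duration)

  rows_t <- numeric(0); rows_y <- NULL; rows_f <- NULL
  for (k in seq_len(length(brk) - 1)) {
    t0 <- brk[k]; t1 <- brk[k + 1]
    mseg <- model
    kd <- proto$knockdowns[proto$knockdowns$onset <= t0, , drop = FALSE]
    if (nrow(kd))
      for (i in seq_len(nrow(kd)))
        mseg <- apply_knockdown(mseg, kd$reaction[i], kd$alpha[i])
    if (has_media) state <- set_media(state, t0)
    tt <- sort(unique(c(t0, times[times > t0 & times < t1], t1)))
    .Call(C_pdacmet_set_model, pack_model(mseg))
    out <- deSolve::ode(y = unname(state), times = tt,
                        func = "pdacmet_derivs", parms = NULL,
                        dllname = "pdacmet", initfunc = NULL,
                        nout = nr, rtol = rtol, atol = atol,
                        method = method, maxsteps = maxsteps)
    if (attr(out, "istate")[1] < 0)
      stop("integration failed in segment [", t0, ", ", t1,
           "] min at t = ", max(out[, 1]), " min")
    y <- out[, 2:(ns + 2), drop = FALSE]
    f <- out[, (ns + 3):(ns + 2 + nr), drop = FALSE]
    if (min(y) < -1e-9)
      stop("state fell below -1e-9 mM at t = ",
           out[which(apply(y, 1, min) < -1e-9)[1], 1], " min")
    keep <- if (k < length(brk) - 1) out[, 1] < t1 else rep(TRUE, nrow(out))
    keep <- keep & out[, 1] %in% times
    rows_t <- c(rows_t, out[keep, 1])
    rows_y <- rbind(rows_y, y[keep, , drop = FALSE])
    rows_f <- rbind(rows_f, f[keep, , drop = FALSE])
    state <- stats::setNames(y[nrow(y), ], names(state))
  }

  colnames(rows_y) <- c(model$species$id, "C_N")
  colnames(rows_f) <- model$reaction_ids
  structure(list(times = rows_t,
                 conc = rows_y[, seq_len(ns), drop = FALSE],
                 cell_number = unname(rows_y[, ns + 1]),
                 flux = rows_f,
                 protocol = proto, model = model$name),
            class = "pdac_trajectory")
}

#' @export
print.pdac_trajectory <- function(x, ...) {
  cat("<pdac_trajectory> ", length(x$times), " time points over ",
      max(x$times) / 1440, " days; ", ncol(x$conc), " species, ",
      ncol(x$flux), " reactions\n",
      "  final relative cell number: ",
      signif(x$cell_number[length(x$cell_number)], 4), "\n", sep = "")
  invisible(x)
}

#' Interpolate a trajectory at a time point
#'
#' @param traj a `pdac_trajectory`.
#' @param t_obs time (min) within the trajectory span.
#' @return list with `conc` (named vector), `flux`, `cell_number` at `t_obs`.
#' @export
trajectory_at <- function(traj, t_obs) {
  if (t_obs < min(traj$times) || t_obs > max(traj$times))
    stop("t_obs = ", t_obs, " outside trajectory span")
  ip <- function(mat) apply(mat, 2, function(col)
    stats::approx(traj$times, col, xout = t_obs)$y)
  list(conc = ip(traj$conc), flux = ip(traj$flux),
       cell_number = stats::approx(traj$times, traj$cell_number,
                                   xout = t_obs)$y)
}

#' Compartment-pooled metabolite fold-changes
#'
#' For each panel metabolite, sums the cytosolic and mitochondrial pools
#' (total cellular pool, as measured by metabolomics) in the knockdown and
#' control trajectories at the observation time and returns their ratio.
#'
#' @param kd,ctrl `pdac_trajectory` objects (knockdown and control) from the
#'   same model/protocol family, both covering `t_obs`.
#' @param model the `pdac_network` (provides the pool map).
#' @param panel character vector of pool names; defaults to the model's
#'   14-metabolite panel.
#' @param t_obs observation time (min), default 24 h after knockdown onset.
#' @return data.frame (`metabolite`, `fold_change`) with attributes `t_obs`
#'   and `pooling = "compartment-summed"`.
#' @export
compute_fold_change <- function(kd, ctrl, model, panel = model$panel,
                                t_obs = 1440) {
  dyn <- model$species[model$species$type == "dynamic", ]
  miss <- setdiff(panel, dyn$pool)
  if (length(miss)) stop("panel metabolite(s) not in model: ",
                         paste(miss, collapse = ", "))
  ckd <- trajectory_at(kd, t_obs)$conc
  cct <- trajectory_at(ctrl, t_obs)$conc
  fc <- vapply(panel, function(pn) {
    ids <- dyn$id[dyn$pool == pn]
    den <- sum(cct[ids])
    if (den <= 0) stop("control pool non-positive for ", pn)
    sum(ckd[ids]) / den
  }, 0)
  out <- data.frame(metabolite = panel, fold_change = unname(fc))
  attr(out, "t_obs") <- t_obs
  attr(out, "pooling") <- "compartment-summed"
  out
}

#' Baseline flux directions
#'
#' Sign of every reaction's net flux at the supplied state (default: the
#' model's validated baseline initial condition), defining the reference
#' arrow directions against which reversals are detected.
#'
#' @param model a `pdac_network`.
#' @param state optional named state vector (defaults to
#'   [initial_state()]).
#' @return named vector of +1/-1 per reaction.
#' @export
baseline_directions <- function(model, state = NULL) {
  if (is.null(state)) state <- initial_state(model)
  fl <- assemble_rhs(model, state)$flux
  ifelse(fl >= 0, 1, -1)
}

#' Detect flux reversals along a trajectory
#'
#' Returns the time intervals during which a reaction's net flux runs
#' opposite to its baseline direction, ignoring fluxes smaller than the
#' dead band (suppresses numerical sign chatter around zero).
#'
#' @param traj a `pdac_trajectory`.
#' @param baseline_signs named +1/-1 vector covering the trajectory's
#'   reactions, e.g. from [baseline_directions()].
#' @param deadband minimal |flux| (mM/min) for a sign to count.
#' @return data.frame with `reaction`, `t_start`, `t_end` (min), one row per
#'   reversal interval (empty if none).
#' @export
detect_flux_reversals <- function(traj, baseline_signs, deadband = 1e-9) {
  miss <- setdiff(colnames(traj$flux), names(baseline_signs))
  if (length(miss)) stop("baseline_signs missing reactions: ",
                         paste(miss, collapse = ", "))
  out <- list()
  for (rid in colnames(traj$flux)) {
    f <- traj$flux[, rid]
    rev <- (sign(f) == -baseline_signs[[rid]]) & (abs(f) > deadband)
    if (!any(rev)) next
    r <- rle(rev)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (i in which(r$values))
      out[[length(out) + 1]] <- data.frame(
        reaction = rid, t_start = traj$times[starts[i]],
        t_end = traj$times[ends[i]])
  }
  if (!length(out))
    return(data.frame(reaction = character(0), t_start = numeric(0),
                      t_end = numeric(0)))
  do.call(rbind, out)
}

#' Export a trajectory as a tidy table
#'
#' @param traj a `pdac_trajectory`.
#' @return data.frame with columns `time`, `variable`, `kind`
#'   (concentration/flux/cells), `value`.
#' @export
trajectory_table <- function(traj) {
  n <- length(traj$times)
  rbind(
    data.frame(time = rep(traj$times, ncol(traj$conc)),
               variable = rep(colnames(traj$conc), each = n),
               kind = "concentration", value = as.vector(traj$conc)),
    data.frame(time = rep(traj$times, ncol(traj$flux)),
               variable = rep(colnames(traj$flux), each = n),
               kind = "flux", value = as.vector(traj$flux)),
    data.frame(time = traj$times, variable = "C_N", kind = "cells",
               value = traj$cell_number))
}
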