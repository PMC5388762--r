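#' Knockdown fold-change objective
#'
#' The calibration observable: compartment-pooled fold-changes of the panel
#' metabolites under an enzyme knockdown relative to the no-knockdown
#' control, both simulated from the same initial condition.
#'
#' @param model a `pdac_network`.
#' @param ic named vector of initial metabolite concentrations (defaults to
#'   the configuration baseline).
#' @param kd_reaction,alpha knockdown descriptor (default GOT1 at 0.85).
#' @param t_obs observation time (min) after knockdown onset.
#' @param panel pool names to report (default: the model's panel).
#' @param ... further arguments to [simulate()].
#' @return named numeric vector of fold-changes.
#' @export
fold_change_objective <- function(model, ic = NULL, kd_reaction = "GOT1",
                                  alpha = 0.85, t_obs = 1440,
                                  panel = model$panel, ...) {
  pr_c <- protocol_complete(days = t_obs / 1440)
  pr_k <- protocol_complete(days = t_obs / 1440,
                            knockdowns = data.frame(reaction = kd_reaction,
                                                    alpha = alpha))
  tt <- c(0, t_obs / 2, t_obs)
  ctrl <- simulate(model, init = ic, proto = pr_c, times = tt, ...)
  kd <- simulate(model, init = ic, proto = pr_k, times = tt, ...)
  fc <- compute_fold_change(kd, ctrl, model, panel = panel, t_obs = t_obs)
  stats::setNames(fc$fold_change, fc$metabolite)
}

#' Forward/reverse velocity correlation analysis
#'
#' For every reversible reaction with an explicit reverse velocity that is
#' not yet equilibrium-constrained, measures how collinear the fold-change
#' objective's sensitivities to `Vf` and `Vr` are: the absolute cosine
#' similarity of the two central-finite-difference Jacobian columns (in log
#' parameter space), averaged over the initial-condition ensemble. A score
#' near 1 means the data constrain only a combination of the pair, so the
#' reverse velocity can be tied to the forward one through the equilibrium
#' constant.
#'
#' @param model a `pdac_network`.
#' @param ic_sets matrix of initial conditions (rows = sets), e.g. from
#'   [lhs_initial_conditions()].
#' @param rel_step relative finite-difference step (log space).
#' @param degenerate_tol sensitivity-norm floor (relative to the objective
#'   norm) below which a pair is reported as degenerate (`score = NA`)
#'   rather than silently scored.
#' @param ... passed to [fold_change_objective()].
#' @return data.frame with `reaction`, `score` (normalized to \[0, 1\]),
#'   `n_ic` (non-degenerate contributions), `degenerate` flag; ranked by
#'   score.
#' @export
pairwise_velocity_correlation <- function(model, ic_sets, rel_step = 0.02,
                                          degenerate_tol = 1e-9, ...) {
  if (is.null(dim(ic_sets))) ic_sets <- matrix(ic_sets, nrow = 1,
    dimnames = list(NULL, names(ic_sets)))
  if (nrow(ic_sets) < 2)
    stop("need at least 2 initial-condition sets")
  pairs <- vapply(model$reactions, function(r)
    r$explicit_vr && !model$constrained[r$id], TRUE)
  ids <- model$reaction_ids[pairs]
  if (!length(ids)) stop("model has no unconstrained reversible pair")

  sums <- stats::setNames(numeric(length(ids)), ids)
  cnts <- stats::setNames(integer(length(ids)), ids)
  h <- log(1 + rel_step)

  for (i in seq_len(nrow(ic_sets))) {
    ic <- ic_sets[i, ]
    base <- try(fold_change_objective(model, ic = ic, ...), silent = TRUE)
    if (inherits(base, "try-error")) next
    nb <- sqrt(sum(base^2))
    for (rid in ids) {
      col <- function(which) {
        v0 <- get_velocities(model, paste0(rid, ".", which))
        up <- try(fold_change_objective(
          set_velocities(model, stats::setNames(v0 * exp(h), names(v0))),
          ic = ic, ...), silent = TRUE)
        dn <- try(fold_change_objective(
          set_velocities(model, stats::setNames(v0 * exp(-h), names(v0))),
          ic = ic, ...), silent = TRUE)
        if (inherits(up, "try-error") || inherits(dn, "try-error"))
          return(NULL)
        (up - dn) / (2 * h)
      }
      jf <- col("Vf"); jr <- col("Vr")
      if (is.null(jf) || is.null(jr)) next
      nf <- sqrt(sum(jf^2)); nr2 <- sqrt(sum(jr^2))
      if (nf < degenerate_tol * nb || nr2 < degenerate_tol * nb) next
      sums[rid] <- sums[rid] + abs(sum(jf * jr)) / (nf * nr2)
      cnts[rid] <- cnts[rid] + 1L
    }
  }
  score <- ifelse(cnts > 0, sums / cnts, NA_real_)
  out <- data.frame(reaction = ids, score = unname(score),
                    n_ic = unname(cnts), degenerate = cnts == 0)
  out[order(-ifelse(is.na(out$score), -1, out$score)), ]
}

#' Constrain correlated reverse velocities through the equilibrium constant
#'
#' Every reaction scoring at or above the threshold has its reverse velocity
#' bound to `Vf / Veq` and removed from the free-parameter list.
#'
#' @param model a `pdac_network`.
#' @param report correlation report from
#'   [pairwise_velocity_correlation()].
#' @param threshold correlation threshold in (0, 1].
#' @return list with `model` (constrained) and `constrained` (reaction ids
#'   newly constrained).
#' @export
reduce_by_equilibrium <- function(model, report, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  hit <- report$reaction[!is.na(report$score) & report$score >= threshold]
  for (rid in hit) {
    r <- model$reactions[[match(rid, model$reaction_ids)]]
    if (is.null(r$params$Veq))
      stop("reaction ", rid, " has no Veq; cannot constrain")
    model$constrained[rid] <- TRUE
  }
  list(model = model, constrained = hit)
}

#' Iterated identifiability reduction
#'
#' Runs the forward/reverse correlation analysis in rounds: after each
#' round the flagged reverse velocities are bound to `Vf/Veq` and the
#' analysis is repeated on the remaining pairs, until no new pair exceeds
#' the threshold (or `max_rounds` is reached).
#'
#' @inheritParams pairwise_velocity_correlation
#' @param threshold correlation threshold (default 0.95).
#' @param max_rounds safety cap on rounds.
#' @param verbose print per-round progress.
#' @return list with `model` (reduced), `report` (all rounds, with `round`
#'   column), `constrained` (ids per round), `free_velocities` (count after
#'   reduction).
#' @export
run_identifiability <- function(model, ic_sets, threshold = 0.95,
                                max_rounds = 10, verbose = FALSE, ...) {
  reports <- list(); rounds <- list()
  for (k in seq_len(max_rounds)) {
    rep_k <- pairwise_velocity_correlation(model, ic_sets, ...)
    rep_k$round <- k
    reports[[k]] <- rep_k
    red <- reduce_by_equilibrium(model, rep_k, threshold)
    model <- red$model
    rounds[[k]] <- red$constrained
    if (verbose)
      message("round ", k, ": ", length(red$constrained), " pair(s) constrained")
    if (!length(red$constrained)) break
  }
  list(model = model,
       report = do.call(rbind, reports),
       constrained = rounds,
       free_velocities = length(free_velocity_names(model)))
}
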