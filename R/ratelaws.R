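#' Kinetic rate laws
#'
#' Every reaction in the network carries one of a small set of enzyme-kinetic
#' rate-law forms. Concentrations are in mM, velocities in mM/min, and all
#' kinetic constants are strictly positive. Negative concentrations (transient
#' solver undershoot) are clipped to zero before evaluation.
#'
#' Supported forms:
#' \describe{
#'   \item{mm_irr}{Irreversible Michaelis-Menten, one factor
#'     \eqn{S/(Km+S)} per substrate.}
#'   \item{mm_rev}{Reversible Michaelis-Menten (convenience kinetics) with an
#'     explicit reverse velocity \eqn{Vr}.}
#'   \item{bibi_rev}{Random-order bi-bi (rapid equilibrium) with explicit
#'     \eqn{Vr}, including the two dead-end (abortive) complexes E.A.Q and
#'     E.B.P.}
#'   \item{haldane}{Reversible Michaelis-Menten parameterised by the
#'     concentration-space equilibrium constant \eqn{Keq} (single maximal
#'     velocity); used for transaminases, antiporters and near-equilibrium
#'     lumped steps.}
#'   \item{carrier}{Facilitated (uni-uni) transport with trans-interaction
#'     factor \eqn{\alpha}.}
#'   \item{ma_rev}{Reversible mass action with stoichiometric powers.}
#'   \item{ma_irr}{Irreversible mass action.}
#'   \item{mwc}{Allosteric Hill/MWC law: first substrate binds cooperatively
#'     (Hill coefficient \eqn{n}, allosteric constant \eqn{L0}, non-exclusive
#'     binding factor \eqn{c}); further substrates act as saturable
#'     cofactors. Allosteric effectors shift \eqn{L}.}
#' }
#'
#' Modifier types (any form): \code{inh} multiplies by \eqn{Ki/(Ki+I)},
#' \code{act} by \eqn{X/(Ka+X)}, \code{cof} by \eqn{X/(Km+X)};
#' \code{allo_inh}/\code{allo_act} act on the MWC allosteric constant only.
#'
#' @name ratelaws
NULL

.RATE_FORMS <- c("mm_irr", "mm_rev", "bibi_rev", "haldane", "carrier",
                 "ma_rev", "ma_irr", "mwc")

#' Evaluate one rate law at a concentration state
#'
#' Computes the signed net flux (mM/min) of a single reaction. This is the
#' reference (pure R) evaluator; the simulation engine uses a compiled kernel
#' with identical algebra.
#'
#' @param rx a reaction description (as found in `model$reactions[[i]]`):
#'   a list with `form`, `subs`, `pros`, `stoich`, `params`, `modifiers`.
#' @param conc named numeric vector of concentrations (mM); negative entries
#'   are clipped to 0.
#' @param vf effective forward maximal velocity (mM/min).
#' @param vr effective reverse maximal velocity (mM/min); ignored by
#'   irreversible and Keq-parameterised forms.
#' @return signed net flux in mM/min.
#' @export
rate_law_flux <- function(rx, conc, vf, vr = 0) {
  conc <- pmax(conc, 0)
  miss <- setdiff(unique(c(rx$subs, rx$pros,
                           vapply(rx$modifiers, `[[`, "", "species"))),
                  names(conc))
  if (length(miss))
    stop("state is missing metabolites for reaction ", rx$id, ": ",
         paste(miss, collapse = ", "))
  p <- rx$params
  S <- unname(conc[rx$subs])
  P <- if (length(rx$pros)) unname(conc[rx$pros]) else numeric(0)

  v <- switch(rx$form,
    mm_irr = {
      val <- vf
      for (i in seq_along(S)) val <- val * S[i] / (p[[paste0("Km_", rx$subs[i])]] + S[i])
      val
    },
    mm_rev = {
      a <- S / vapply(rx$subs, function(s) p[[paste0("Km_", s)]], 0)
      b <- P / vapply(rx$pros, function(s) p[[paste0("Km_", s)]], 0)
      (vf * prod(a) - vr * prod(b)) / (prod(1 + a) + prod(1 + b) - 1)
    },
    bibi_rev = {
      A <- S[1]; B <- S[2]; Pp <- P[1]; Q <- P[2]
      fnum <- vf * A * B / (p[["Kia"]] * p[["Kmb"]])
      rnum <- vr * Pp * Q / (p[["Kip"]] * p[["Kmq"]])
      D <- 1 + A / p[["Kia"]] + B / p[["Kib"]] + Pp / p[["Kip"]] + Q / p[["Kiq"]] +
        A * B / (p[["Kia"]] * p[["Kmb"]]) + Pp * Q / (p[["Kip"]] * p[["Kmq"]]) +
        A * Q / p[["Kd_AQ"]] + B * Pp / p[["Kd_BP"]]
      (fnum - rnum) / D
    },
    haldane = {
      Kms <- vapply(rx$subs, function(s) p[[paste0("Km_", s)]], 0)
      Kmp <- vapply(rx$pros, function(s) p[[paste0("Km_", s)]], 0)
      D <- prod(1 + S / Kms) + prod(1 + P / Kmp) - 1
      vf * (prod(S) - prod(P) / p[["Keq"]]) / (prod(Kms) * D)
    },
    carrier = {
      D <- 1 + S[1] / p[["Kms"]] + P[1] / p[["Kmp"]] +
        p[["alpha"]] * S[1] * P[1] / (p[["Kms"]] * p[["Kmp"]])
      vf * (S[1] - P[1] / p[["Keq"]]) / (p[["Kms"]] * D)
    },
    ma_rev = {
      sf <- abs(rx$stoich[rx$subs]); sp <- abs(rx$stoich[rx$pros])
      vf * prod(S^sf) - vr * prod(P^sp)
    },
    ma_irr = {
      sf <- abs(rx$stoich[rx$subs])
      vf * prod(S^sf)
    },
    mwc = {
      s1 <- S[1] / p[[paste0("Km_", rx$subs[1])]]
      n <- p[["n"]]; cc <- p[["c"]]
      L <- p[["L0"]]
      for (m in rx$modifiers) {
        x <- conc[[m$species]]
        if (m$type == "allo_inh") L <- L * (1 + x / p[[paste0("Ki_", m$species)]])^n
        if (m$type == "allo_act") L <- L / (1 + x / p[[paste0("Ka_", m$species)]])^n
      }
      val <- vf * s1 * (1 + s1)^(n - 1) / ((1 + s1)^n + L * (1 + cc * s1)^n)
      if (length(S) > 1)
        for (i in 2:length(S))
          val <- val * S[i] / (p[[paste0("Km_", rx$subs[i])]] + S[i])
      val
    },
    stop("unknown rate-law form: ", rx$form)
  )

  for (m in rx$modifiers) {
    if (m$type %in% c("allo_inh", "allo_act")) next
    x <- conc[[m$species]]
    v <- v * switch(m$type,
      inh = { k <- p[[paste0("Ki_", m$species)]]; k / (k + x) },
      act = { k <- p[[paste0("Ka_", m$species)]]; x / (k + x) },
      cof = { k <- p[[paste0("Km_", m$species)]]; x / (k + x) },
      stop("unknown modifier type: ", m$type))
  }
  v
}

#' Evaluate the net flux of one reaction in a network model
#'
#' Applies the model's current effective velocities (AKT modulation, active
#' knockdowns, equilibrium constraints) and evaluates the reaction's rate law
#' at the supplied state.
#'
#' @param model a `pdac_network` object.
#' @param reaction reaction id (character) or index.
#' @param state named concentration vector (mM). Must contain every species in
#'   the reaction's rate law; values must be finite and non-negative
#'   (solver-scale negative undershoot below 1e-9 is tolerated and clipped).
#' @return signed net flux (mM/min). Positive flux follows the reaction's
#'   declared substrate-to-product direction.
#' @export
evaluate_flux <- function(model, reaction, state) {
  i <- if (is.character(reaction)) match(reaction, model$reaction_ids) else reaction
  if (is.na(i) || i < 1 || i > length(model$reactions))
    stop("unknown reaction: ", reaction)
  if (any(!is.finite(state)))
    stop("non-finite concentration in state")
  if (any(state < -1e-9))
    stop("negative concentration input: ",
         paste(names(state)[state < -1e-9], collapse = ", "))
  ev <- effective_velocities(model)
  rate_law_flux(model$reactions[[i]], state, ev$vf[i], ev$vr[i])
}

#' All reaction fluxes at a state
#'
#' @inheritParams evaluate_flux
#' @return named numeric vector of net fluxes (mM/min), one per reaction.
#' @export
all_fluxes <- function(model, state) {
  ev <- effective_velocities(model)
  v <- vapply(seq_along(model$reactions), function(i)
    rate_law_flux(model$reactions[[i]], state, ev$vf[i], ev$vr[i]), 0)
  names(v) <- model$reaction_ids
  v
}
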