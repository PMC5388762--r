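## Packing of a pdac_network into the flat double vector consumed by the
## compiled kernel (src/pdacmet.c). Layout:
##   [1]  ns  (total species)
##   [2]  nr  (reactions)
##   [3]  cell-ODE flag
##   [4:11]  growth parameters (alpha_atp, alpha_glc, alpha_gln, alpha_d,
##           k_ap, k_gc, k_gn, K_CC)
##   [12:14] 0-based indices of ATP, GLC, GLN
##   [15:(14+ns)]       dynamic flags per species
##   [(15+ns):(14+ns+nr)] 0-based block offset per reaction
##   blocks: form, vf_eff, vr_eff, nsub, npro, sub idx, pro idx,
##           nstoich, (idx, coef)*, npar, params, nmod, (type, idx, k)*

.MOD_CODE <- c(inh = 1, act = 2, cof = 3, allo_inh = 4, allo_act = 5)
.FORM_CODE <- c(mm_irr = 1, mm_rev = 2, bibi_rev = 3, haldane = 4,
                carrier = 5, ma_rev = 6, ma_irr = 7, mwc = 8)

#' Pack a network model for the compiled kernel
#'
#' Resolves effective velocities (AKT, knockdowns, equilibrium constraints)
#' and flattens the model into the numeric vector format the C kernel reads.
#' Called internally by [simulate()]; exposed for low-level testing.
#'
#' @param model a `pdac_network`.
#' @param cell_ode integrate the cell-number equation as the final state?
#' @return numeric vector (packed model).
#' @export
pack_model <- function(model, cell_ode = TRUE) {
  ns <- nrow(model$species)
  nr <- length(model$reactions)
  idx0 <- stats::setNames(seq_len(ns) - 1L, model$species$id)
  ev <- effective_velocities(model)

  blocks <- vector("list", nr)
  for (j in seq_len(nr)) {
    r <- model$reactions[[j]]
    p <- r$params
    km <- function(ids) vapply(ids, function(s) p[[paste0("Km_", s)]], 0)
    pars <- switch(r$form,
      mm_irr  = km(r$subs),
      mm_rev  = c(km(r$subs), km(r$pros)),
      bibi_rev = c(p$Kia, p$Kib, p$Kmb, p$Kip, p$Kiq, p$Kmq, p$Kd_AQ, p$Kd_BP),
      haldane = c(km(r$subs), km(r$pros), p$Keq),
      carrier = c(p$Kms, p$Kmp, p$Keq, p$alpha),
      ma_rev  = c(abs(r$stoich[r$subs]), abs(r$stoich[r$pros])),
      ma_irr  = abs(r$stoich[r$subs]),
      mwc     = c(km(r$subs), p$n, p$L0, p$c))
    mods <- numeric(0)
    for (m in r$modifiers) {
      k <- switch(m$type,
                  inh = , allo_inh = p[[paste0("Ki_", m$species)]],
                  act = , allo_act = p[[paste0("Ka_", m$species)]],
                  cof = p[[paste0("Km_", m$species)]])
      mods <- c(mods, .MOD_CODE[[m$type]], idx0[[m$species]], k)
    }
    st <- r$stoich
    blocks[[j]] <- c(.FORM_CODE[[r$form]], ev$vf[j], ev$vr[j],
                     length(r$subs), length(r$pros),
                     idx0[r$subs], idx0[r$pros],
                     length(st), rbind(idx0[names(st)], st),
                     length(pars), pars,
                     length(r$modifiers), mods)
  }

  head_len <- 14L + ns + nr
  offs <- head_len + c(0, cumsum(vapply(blocks, length, 0L)))[seq_len(nr)]
  ## models without the growth-coupled species (toy networks) integrate a
  ## cell equation with zero growth terms
  g <- c(alpha_atp = 0, alpha_glc = 0, alpha_gln = 0, alpha_d = 0,
         k_ap = 1, k_gc = 1, k_gn = 1, K_CC = 1)
  if (!is.null(model$growth) && !anyNA(model$growth))
    g[names(model$growth)] <- model$growth
  gi <- function(nm) if (nm %in% names(idx0)) idx0[[nm]] else 0
  if (!all(c("ATP", "GLC", "GLN") %in% names(idx0)))
    g[c("alpha_atp", "alpha_glc", "alpha_gln")] <- 0
  c(ns, nr, as.numeric(cell_ode),
    g[["alpha_atp"]], g[["alpha_glc"]], g[["alpha_gln"]], g[["alpha_d"]],
    g[["k_ap"]], g[["k_gc"]], g[["k_gn"]], g[["K_CC"]],
    gi("ATP"), gi("GLC"), gi("GLN"),
    as.numeric(model$species$type == "dynamic"),
    offs, unlist(blocks, use.names = FALSE))
}

#' Assemble the ODE right-hand side at a state
#'
#' Evaluates the full derivative vector: the stoichiometry-weighted sum of
#' reaction fluxes for every dynamic metabolite, exact zeros for fixed
#' species (e.g. mitochondrial ATP/ADP) and boundary species (protocol
#' controlled), and the logistic-with-death cell-number derivative.
#'
#' @param model a `pdac_network`.
#' @param state named state vector as from [initial_state()] (all species
#'   plus `C_N`).
#' @param t time (min); present for interface completeness, the system is
#'   autonomous within a protocol segment.
#' @return list with `dstate` (derivatives, same names as `state`) and
#'   `flux` (named net reaction fluxes, mM/min).
#' @export
assemble_rhs <- function(model, state, t = 0) {
  ns <- nrow(model$species)
  if (length(state) != ns + 1L)
    stop("state dimension mismatch: expected ", ns + 1L, " (",
         ns, " species + C_N), got ", length(state))
  pk <- pack_model(model)
  out <- .Call(C_pdacmet_eval, pk, as.numeric(t), as.numeric(state))
  dstate <- stats::setNames(out[[1]], c(model$species$id, "C_N"))
  flux <- stats::setNames(out[[2]], model$reaction_ids)
  list(dstate = dstate, flux = flux)
}

## low-level kernel evaluation on a pre-packed model (used by tests and the
## fixed-step cross-integrator oracle); returns list(ydot, flux)
.kernel_eval <- function(packed, t, y) {
  .Call(C_pdacmet_eval, packed, as.numeric(t), as.numeric(y))
}
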