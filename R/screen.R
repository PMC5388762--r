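#' Knockdown dose-response
#'
#' Simulates the complete-media growth protocol once per knockdown level of
#' one reaction and reports the relative cell number at the horizon.
#'
#' @param model a `pdac_network`.
#' @param reaction reaction id to knock down.
#' @param levels knockdown fractions in \[0, 1\] (paper scan: 0.05 to 1).
#' @param days horizon (default 5).
#' @param ic optional initial condition.
#' @return data.frame with `level` and `cells` (day-`days` relative cell
#'   number; `NA` with a warning for failed simulations).
#' @export
knockdown_dose_response <- function(model, reaction,
                                    levels = seq(0.05, 1, by = 0.05),
                                    days = 5, ic = NULL) {
  if (any(levels < 0) || any(levels > 1)) stop("levels must lie in [0, 1]")
  cells <- vapply(levels, function(a) {
    pr <- protocol_complete(days, knockdowns =
      if (a > 0) data.frame(reaction = reaction, alpha = a) else NULL)
    r <- try(simulate(model, init = ic, proto = pr), silent = TRUE)
    if (inherits(r, "try-error")) {
      warning("simulation failed at level ", a)
      return(NA_real_)
    }
    utils::tail(r$cell_number, 1)
  }, 0)
  data.frame(level = levels, cells = cells)
}

#' Single and combination knockdown screen against a reference enzyme
#'
#' Runs four 5-day complete-media simulations: control, target knockdown
#' alone, reference knockdown alone (default GOT1), and the combination,
#' and classifies the combination behavior.
#'
#' @param model a `pdac_network`.
#' @param target target reaction id.
#' @param reference reference reaction id (default `"GOT1"`).
#' @param alpha knockdown fraction applied to both (default 0.85).
#' @param days horizon.
#' @param eps classification tolerance (relative cell number).
#' @param ic optional initial condition.
#' @return `pdac_screen` list: `curves` (data.frame day x condition),
#'   `day5` (named final cell numbers), `class`, `eps`, `target`,
#'   `reference`.
#' @export
combination_screen <- function(model, target, reference = "GOT1",
                               alpha = 0.85, days = 5, eps = 0.05,
                               ic = NULL) {
  if (!target %in% model$reaction_ids) stop("unknown reaction: ", target)
  kd <- function(ids) if (is.null(ids)) NULL else
    data.frame(reaction = ids, alpha = alpha)
  conds <- list(control = NULL, target = target, reference = reference,
                combination = unique(c(target, reference)))
  day_t <- (0:days) * 1440
  curves <- data.frame(day = 0:days)
  final <- c()
  for (nm in names(conds)) {
    tr <- simulate(model, init = ic,
                   proto = protocol_complete(days, knockdowns = kd(conds[[nm]])))
    curves[[nm]] <- vapply(day_t, function(t)
      trajectory_at(tr, t)$cell_number, 0)
    final[nm] <- curves[[nm]][days + 1]
  }
  res <- structure(list(curves = curves, day5 = final, eps = eps,
                        target = target, reference = reference,
                        alpha = alpha),
                   class = "pdac_screen")
  res$class <- classify_combination(res, eps)
  res
}

#' Classify a combination-screen result
#'
#' Three classes of combination behavior, judged on horizon cell numbers
#' (`N_t` target alone, `N_r` reference alone, `N_c` combination) with
#' relative tolerance `eps`:
#' \describe{
#'   \item{A}{target alone weaker than the reference, but the combination
#'     is synergistic: `N_t > N_r (1+eps)` and
#'     `N_c < min(N_t, N_r) (1-eps)`.}
#'   \item{B}{target comparable to the reference and the combination adds
#'     further benefit: `|N_t - N_r| <= eps N_r` and `N_c < N_r (1-eps)`.}
#'   \item{C}{target alone dominant, combination adds nothing:
#'     `N_t < N_r (1-eps)` and `|N_c - N_t| <= eps N_t`.}
#'   \item{none}{anything else.}
#' }
#'
#' @param result a `pdac_screen`, or a named vector with entries `target`,
#'   `reference`, `combination`.
#' @param eps relative tolerance (default 0.05).
#' @return one of `"A"`, `"B"`, `"C"`, `"none"`.
#' @export
classify_combination <- function(result, eps = 0.05) {
  n <- if (inherits(result, "pdac_screen")) result$day5 else result
  need <- c("target", "reference", "combination")
  if (!all(need %in% names(n)))
    stop("missing curve(s): ", paste(setdiff(need, names(n)), collapse = ", "))
  nt <- n[["target"]]; nr <- n[["reference"]]; nc <- n[["combination"]]
  if (nt > nr * (1 + eps) && nc < min(nt, nr) * (1 - eps)) return("A")
  if (abs(nt - nr) <= eps * nr && nc < nr * (1 - eps)) return("B")
  if (nt < nr * (1 - eps) && abs(nc - nt) <= eps * nt) return("C")
  "none"
}

#' @export
print.pdac_screen <- function(x, ...) {
  cat("<pdac_screen> ", x$target, " vs ", x$reference,
      " (alpha = ", x$alpha, ")\n  day-5 cells: ", sep = "")
  cat(paste(names(x$day5), signif(x$day5, 4), sep = "=", collapse = "  "),
      "\n  class: ", x$class, " (eps = ", x$eps, ")\n", sep = "")
  invisible(x)
}

#' Nutrient-availability grid
#'
#' Simulates the growth protocol for every combination of extracellular
#' glucose and glutamine level and reports relative cell numbers at the
#' horizon.
#'
#' @param model a `pdac_network`.
#' @param glc_levels,gln_levels media concentrations (mM).
#' @param days horizon (default 5).
#' @param ic optional initial condition.
#' @return matrix (glucose x glutamine) with axis values as dimnames.
#' @export
nutrient_grid <- function(model, glc_levels = c(0, 2, 5, 10, 20, 35),
                          gln_levels = c(0, 0.5, 1, 2, 4, 6), days = 5,
                          ic = NULL) {
  if (any(glc_levels < 0) || any(gln_levels < 0))
    stop("nutrient levels must be non-negative")
  out <- matrix(NA_real_, length(glc_levels), length(gln_levels),
                dimnames = list(glc = glc_levels, gln = gln_levels))
  for (i in seq_along(glc_levels))
    for (j in seq_along(gln_levels)) {
      r <- try(simulate(model, init = ic,
                        proto = protocol_complete(days, glc = glc_levels[i],
                                                  gln = gln_levels[j])),
               silent = TRUE)
      if (inherits(r, "try-error")) {
        warning("grid simulation failed at (", glc_levels[i], ", ",
                gln_levels[j], ")")
        next
      }
      out[i, j] <- utils::tail(r$cell_number, 1)
    }
  out
}
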