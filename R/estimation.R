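#' Weighted sum of squared residuals
#'
#' The calibration objective: `sum(w * (pred - obs)^2)`.
#'
#' @param predicted,observed equal-length numeric vectors.
#' @param weights positive weights (default 1); when per-observation
#'   uncertainties `sigma` are available use `weights = 1/sigma^2`.
#' @return non-negative scalar.
#' @export
wssr <- function(predicted, observed, weights = 1) {
  if (length(predicted) != length(observed))
    stop("length mismatch: ", length(predicted), " vs ", length(observed))
  weights <- rep_len(weights, length(observed))
  if (any(weights <= 0)) stop("weights must be strictly positive")
  sum(weights * (predicted - observed)^2)
}

#' Particle swarm optimization (global-best topology)
#'
#' Population-based stochastic minimizer used for the reaction-velocity
#' fit. Particles move in log-parameter space (velocities span orders of
#' magnitude) under inertia plus cognitive/social attraction; positions are
#' clamped to the box with velocity reset at the walls.
#'
#' @param fn objective: function of a named parameter vector, returning a
#'   finite scalar (non-finite values are treated as a large penalty).
#' @param lower,upper named positive bounds.
#' @param n_particles swarm size (default 50).
#' @param iterations PSO iterations per run (default 2500).
#' @param inertia,c1,c2 velocity-update coefficients.
#' @param seed integer seed.
#' @param init optional matrix of initial positions (rows = particles,
#'   original scale); remaining particles are drawn log-uniformly.
#' @param log_space search in log10 space (default TRUE).
#' @param penalty objective value substituted for failed evaluations.
#' @return list with `par` (best position, original scale), `value`,
#'   `trace` (best value per iteration), `evals`, `failures`, plus the
#'   provenance fields `seed`, `iterations`, `n_particles`, `lower`,
#'   `upper`.
#' @export
pso_optimize <- function(fn, lower, upper, n_particles = 50,
                         iterations = 2500, inertia = 0.7, c1 = 1.5,
                         c2 = 1.5, seed = 1, init = NULL, log_space = TRUE,
                         penalty = 1e12) {
  k <- length(lower)
  tf <- if (log_space) log10 else identity
  itf <- if (log_space) function(x) 10^x else identity
  lo <- tf(lower); hi <- tf(upper)
  set.seed(seed)
  X <- matrix(stats::runif(n_particles * k, rep(lo, each = n_particles),
                           rep(hi, each = n_particles)), n_particles, k)
  if (!is.null(init)) {
    ni <- min(nrow(init), n_particles)
    X[seq_len(ni), ] <- tf(init[seq_len(ni), , drop = FALSE])
  }
  V <- matrix(stats::runif(n_particles * k, -1, 1), n_particles, k) *
    rep((hi - lo) / 10, each = n_particles)
  evals <- 0L; failures <- 0L
  score <- function(x) {
    p <- itf(x); names(p) <- names(lower)
    evals <<- evals + 1L
    v <- try(fn(p), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) {
      failures <<- failures + 1L
      return(penalty)
    }
    v
  }
  pb_val <- apply(X, 1, score)
  pb_pos <- X
  g <- which.min(pb_val)
  gb_val <- pb_val[g]; gb_pos <- X[g, ]
  trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    r1 <- matrix(stats::runif(n_particles * k), n_particles, k)
    r2 <- matrix(stats::runif(n_particles * k), n_particles, k)
    V <- inertia * V + c1 * r1 * (pb_pos - X) +
      c2 * r2 * (rep(1, n_particles) %o% gb_pos - X)
    X <- X + V
    out_lo <- sweep(X, 2, lo, `<`); out_hi <- sweep(X, 2, hi, `>`)
    X[out_lo] <- rep(lo, each = n_particles)[out_lo]
    X[out_hi] <- rep(hi, each = n_particles)[out_hi]
    V[out_lo | out_hi] <- 0
    val <- apply(X, 1, score)
    imp <- val < pb_val
    pb_val[imp] <- val[imp]; pb_pos[imp, ] <- X[imp, ]
    g <- which.min(pb_val)
    if (pb_val[g] < gb_val) { gb_val <- pb_val[g]; gb_pos <- pb_pos[g, ] }
    trace[it] <- gb_val
  }
  par <- itf(gb_pos); names(par) <- names(lower)
  if (all(pb_val >= penalty))
    stop("all particles infeasible: ", failures, " failed evaluations")
  list(par = par, value = gb_val, trace = trace, evals = evals,
       failures = failures, seed = seed, iterations = iterations,
       n_particles = n_particles, lower = lower, upper = upper)
}

#' Stage 1: fit reaction velocities to fold-change data
#'
#' Particle swarm fit of the free reaction velocities (forward velocities
#' plus unconstrained reverse velocities) to an observed knockdown
#' fold-change panel, from one initial-condition set. Bounds are 100-fold
#' up and down from the current (literature) values; the best particle over
#' `n_runs` independent runs is returned. Evaluation failures are penalized,
#' not fatal.
#'
#' @param model a `pdac_network`, typically after identifiability reduction.
#' @param data fold-change dataset: data.frame with columns `metabolite`,
#'   `fold_change` and optionally `sigma` (used as `1/sigma^2` weights);
#'   attributes `kd_reaction`/`kd_alpha` override the defaults.
#' @param ic initial-condition vector (named).
#' @param n_runs independent PSO runs (default 2; best kept).
#' @param iterations,n_particles PSO controls (paper-scale defaults 2500
#'   and 50; scale down for quick runs).
#' @param seed integer seed (each run uses `seed + run - 1`).
#' @param t_obs fold-change observation time (min).
#' @param span bound factor (default 100-fold each way).
#' @param parameters velocities to fit; default all free velocities.
#' @return `pdac_fit` list: `par`, `wssr`, `runs` (per-run summaries),
#'   `model` (with fitted velocities applied), provenance fields.
#' @export
fit_reaction_velocities <- function(model, data, ic = NULL, n_runs = 2,
                                    iterations = 2500, n_particles = 50,
                                    seed = 1, t_obs = 1440, span = 100,
                                    parameters = free_velocity_names(model)) {
  obs <- stats::setNames(data$fold_change, data$metabolite)
  if (any(obs <= 0)) stop("observed fold-changes must be positive")
  w <- if (!is.null(data$sigma)) 1 / data$sigma^2 else rep(1, length(obs))
  kd <- attr(data, "kd_reaction") %||% "GOT1"
  al <- attr(data, "kd_alpha") %||% 0.85
  v0 <- get_velocities(model, parameters)
  lower <- v0 / span; upper <- v0 * span
  objective <- function(v) {
    pred <- fold_change_objective(set_velocities(model, v), ic = ic,
                                  kd_reaction = kd, alpha = al,
                                  t_obs = t_obs,
                                  panel = names(obs))
    wssr(pred, obs, w)
  }
  ## one particle starts at the current (literature) velocities; the rest
  ## of the swarm samples the log-uniform box
  runs <- lapply(seq_len(n_runs), function(r)
    pso_optimize(objective, lower, upper, n_particles = n_particles,
                 iterations = iterations, seed = seed + r - 1,
                 init = matrix(v0, 1, dimnames = list(NULL, names(v0)))))
  best <- runs[[which.min(vapply(runs, `[[`, 0, "value"))]]
  structure(list(par = best$par, wssr = best$value,
                 runs = lapply(runs, function(r)
                   list(value = r$value, seed = r$seed, evals = r$evals,
                        failures = r$failures)),
                 trace = best$trace,
                 model = set_velocities(model, best$par),
                 seed = seed, iterations = iterations,
                 n_particles = n_particles, n_runs = n_runs,
                 lower = lower, upper = upper, t_obs = t_obs),
            class = "pdac_fit")
}

#' @export
print.pdac_fit <- function(x, ...) {
  cat("<pdac_fit> ", length(x$par), " parameters, WSSR = ",
      signif(x$wssr, 5), "\n", sep = "")
  invisible(x)
}

## Nutrient time courses on a fixed half-step grid (for RK4 at step h)
.growth_grid <- function(traj, h = 10) {
  tmax <- max(traj$times)
  tg <- seq(0, tmax, by = h / 2)
  g <- function(sp) pmax(stats::approx(traj$times, traj$conc[, sp],
                                       xout = tg, rule = 2)$y, 0)
  list(t = tg, h = h, atp = g("ATP"), glc = g("GLC"), gln = g("GLN"))
}

.predict_growth_grid <- function(grid, p, days) {
  p <- as.list(p)
  lam <- p$alpha_atp * grid$atp / (p$k_ap + grid$atp) +
    p$alpha_glc * grid$glc / (p$k_gc + grid$glc) +
    p$alpha_gln * grid$gln / (p$k_gn + grid$gln)
  h <- grid$h; kcc <- p$K_CC; ad <- p$alpha_d
  n <- (length(grid$t) - 1) / 2          # full RK4 steps
  C <- numeric(n + 1); C[1] <- 1
  f <- function(lam_i, c) lam_i * (1 - c / kcc) * c - ad * c
  for (i in seq_len(n)) {
    c0 <- C[i]
    l0 <- lam[2 * i - 1]; lh <- lam[2 * i]; l1 <- lam[2 * i + 1]
    k1 <- f(l0, c0)
    k2 <- f(lh, c0 + h / 2 * k1)
    k3 <- f(lh, c0 + h / 2 * k2)
    k4 <- f(l1, c0 + h * k3)
    C[i + 1] <- max(c0 + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }
  stats::approx(grid$t[seq(1, length(grid$t), by = 2)], C,
                xout = days * 1440, rule = 2)$y
}

#' Predict a relative-cell-number curve for given growth parameters
#'
#' Integrates the logistic-with-death cell equation (classical RK4 on a
#' 10-minute grid) driven by the ATP, glucose and glutamine time courses of
#' a metabolite trajectory. The metabolite system does not depend on cell
#' number, so the trajectory is computed once and reused across candidate
#' growth parameters -- this is what makes the restarted growth fit cheap.
#'
#' @param traj a `pdac_trajectory` (its metabolite courses drive growth).
#' @param p growth parameters (see [growth_parameters()]).
#' @param days output days (default 0:5).
#' @return numeric vector of relative cell numbers at `days`.
#' @export
predict_growth <- function(traj, p, days = 0:5) {
  p <- growth_parameters(p)
  .predict_growth_grid(.growth_grid(traj), p, days)
}

#' Stage 2: fit the seven growth parameters to paired growth curves
#'
#' Restarted trust-region least squares (Levenberg-Marquardt in log
#' parameter space) of the growth/death parameters against the control and
#' knockdown relative-cell-number curves simultaneously; one parameter set
#' must fit both conditions. Restarts are drawn log-uniformly over a search
#' box spanning seven orders of magnitude per parameter; the carrying
#' capacity is held at its configured value.
#'
#' @param model a `pdac_network` with (fitted) velocities applied.
#' @param data growth dataset: data.frame with columns `day`, `condition`
#'   (`"control"`/`"knockdown"`), `cells` (> 0), optional `sigma`.
#' @param ic initial-condition vector.
#' @param n_restarts number of restarts (default 100).
#' @param seed integer seed.
#' @param kd_reaction,alpha knockdown descriptor for the knockdown curve.
#' @param box named list of `c(lower, upper)` per parameter; default spans
#'   seven decades around plausible rates (1/min) and saturation constants
#'   (mM).
#' @return list with `par` (growth parameters incl. fixed `K_CC`), `wssr`,
#'   `n_restarts`, `seed`, `converged` (restarts that converged), `box`.
#' @export
fit_growth_parameters <- function(model, data, ic = NULL, n_restarts = 100,
                                  seed = 1, kd_reaction = "GOT1",
                                  alpha = 0.85,
                                  box = NULL) {
  stopifnot(all(c("day", "condition", "cells") %in% names(data)))
  if (!all(c("control", "knockdown") %in% data$condition))
    stop("growth data must contain both control and knockdown conditions")
  if (any(data$cells <= 0)) stop("cell numbers must be positive")
  if (is.null(box))
    box <- list(alpha_atp = c(1e-7, 1), alpha_glc = c(1e-7, 1),
                alpha_gln = c(1e-7, 1), alpha_d = c(1e-7, 1),
                k_ap = c(1e-3, 1e4), k_gc = c(1e-3, 1e4),
                k_gn = c(1e-3, 1e4))
  days_max <- max(data$day)
  tr_c <- simulate(model, init = ic, proto = protocol_complete(days_max))
  tr_k <- simulate(model, init = ic, proto = protocol_complete(days_max,
    knockdowns = data.frame(reaction = kd_reaction, alpha = alpha)))
  dc <- data[data$condition == "control", ]
  dk <- data[data$condition == "knockdown", ]
  w <- function(d) if (!is.null(d$sigma)) 1 / d$sigma else rep(1, nrow(d))
  kcc <- model$growth[["K_CC"]]

  grid_c <- .growth_grid(tr_c); grid_k <- .growth_grid(tr_k)
  resid <- function(lp) {
    p <- c(as.list(stats::setNames(10^lp, growth_free_names())),
           K_CC = kcc)
    c(w(dc) * (.predict_growth_grid(grid_c, p, dc$day) - dc$cells),
      w(dk) * (.predict_growth_grid(grid_k, p, dk$day) - dk$cells))
  }
  lo <- log10(vapply(box, `[`, 0, 1))[growth_free_names()]
  hi <- log10(vapply(box, `[`, 0, 2))[growth_free_names()]
  set.seed(seed)
  best <- NULL; conv <- 0L
  for (r in seq_len(n_restarts)) {
    start <- stats::runif(7, lo, hi)
    fit <- try(minpack.lm::nls.lm(start, lower = lo, upper = hi,
                                  fn = resid,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    conv <- conv + 1L
    val <- sum(fit$fvec^2)
    if (is.null(best) || val < best$val)
      best <- list(par = fit$par, val = val)
  }
  if (is.null(best)) stop("all growth-fit restarts diverged")
  par <- c(stats::setNames(10^best$par, growth_free_names()), K_CC = kcc)
  list(par = par, wssr = best$val, n_restarts = n_restarts, seed = seed,
       converged = conv, box = box)
}
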