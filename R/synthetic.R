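#' Generate a ground-truth model for synthetic studies
#'
#' Perturbs the reference model into a known "true" parameterization: every
#' free reaction velocity is multiplied by an independent log-normal factor
#' with log-standard-deviation `scale`, and the growth parameters receive
#' log-normal factors clipped to a physiologic box (0.3x to 3x their
#' reference values). `scale = 0` returns the reference unchanged.
#'
#' @param model a `pdac_network`.
#' @param scale log-sd of the velocity perturbation factors (>= 0).
#' @param seed integer seed.
#' @return list with `model` (velocities applied), `velocities` (named
#'   true values), `growth` (named true growth parameters), `scale`,
#'   `seed`.
#' @export
make_ground_truth <- function(model, scale = 0.2, seed = 1) {
  if (scale < 0) stop("perturbation scale must be >= 0")
  set.seed(seed)
  vn <- free_velocity_names(model)
  v0 <- get_velocities(model, vn)
  vt <- v0 * exp(stats::rnorm(length(v0), 0, scale))
  g0 <- model$growth
  gf <- exp(stats::rnorm(7, 0, scale))
  gf <- pmin(pmax(gf, 0.3), 3)
  gt <- g0
  gt[growth_free_names()] <- g0[growth_free_names()] * gf
  m <- set_velocities(model, vt)
  m$growth <- gt
  list(model = m, velocities = vt, growth = gt, scale = scale, seed = seed)
}

#' Simulate a synthetic training and validation study
#'
#' Emulates the study's calibration data from a ground-truth model:
#' \itemize{
#'   \item a 14-metabolite fold-change panel under GOT1 knockdown
#'     (alpha = 0.85) observed 24 h after knockdown, with multiplicative
#'     log-normal noise of coefficient of variation `noise_cv`;
#'   \item relative-cell-number growth curves sampled daily over 5 days in
#'     complete media (35 mM glucose, 6 mM glutamine), control and
#'     knockdown;
#'   \item a validation growth curve under nutrient deprivation after 24 h.
#' }
#'
#' @param truth result of [make_ground_truth()] (or a list with `model`).
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal observation noise (0 = noise-free).
#' @param seed integer seed for the noise.
#' @param ic optional initial condition (default: configuration baseline).
#' @param days growth horizon in days.
#' @param t_obs fold-change observation time (min).
#' @return `pdac_synthetic_study` list: `fold_change` (data.frame
#'   `metabolite`, `fold_change`, attributes `kd_reaction`, `kd_alpha`),
#'   `growth` (data.frame `day`, `condition`, `cells`), `validation`
#'   (data.frame `day`, `condition` in complete/deprived, `cells`),
#'   `truth`, `noise_cv`, `seed`.
#' @export
simulate_training_dataset <- function(truth, noise_cv = 0.1, seed = 1,
                                      ic = NULL, days = 5, t_obs = 1440) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  m <- truth$model
  kd <- data.frame(reaction = "GOT1", alpha = 0.85)
  tr_c <- simulate(m, init = ic, proto = protocol_complete(days))
  tr_k <- simulate(m, init = ic, proto = protocol_complete(days,
                                                          knockdowns = kd))
  tr_d <- simulate(m, init = ic, proto = protocol_deprivation(days))
  fc <- compute_fold_change(tr_k, tr_c, m, t_obs = t_obs)

  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- function(n) if (noise_cv == 0) rep(1, n) else
    stats::rlnorm(n, -sdlog^2 / 2, sdlog)

  ## the trajectories integrate the cell ODE with the truth model's growth
  ## block, so read the simulated cell numbers directly
  day_t <- (0:days) * 1440
  cn <- function(tr) vapply(day_t, function(t)
    trajectory_at(tr, t)$cell_number, 0)

  fold_change <- data.frame(metabolite = fc$metabolite,
                            fold_change = fc$fold_change *
                              noise(nrow(fc)))
  attr(fold_change, "kd_reaction") <- "GOT1"
  attr(fold_change, "kd_alpha") <- 0.85

  growth <- rbind(
    data.frame(day = 0:days, condition = "control",
               cells = cn(tr_c) * noise(days + 1)),
    data.frame(day = 0:days, condition = "knockdown",
               cells = cn(tr_k) * noise(days + 1)))
  validation <- rbind(
    data.frame(day = 0:days, condition = "complete",
               cells = cn(tr_c) * noise(days + 1)),
    data.frame(day = 0:days, condition = "deprived",
               cells = cn(tr_d) * noise(days + 1)))

  structure(list(fold_change = fold_change, growth = growth,
                 validation = validation, truth = truth,
                 noise_cv = noise_cv, seed = seed),
            class = "pdac_synthetic_study")
}

#' @export
print.pdac_synthetic_study <- function(x, ...) {
  cat("<pdac_synthetic_study> seed ", x$seed, ", noise CV ", x$noise_cv,
      "\n  fold-change panel: ", nrow(x$fold_change),
      " metabolites; growth: ", nrow(x$growth), " observations\n", sep = "")
  invisible(x)
}

#' Read/write the delimited dataset schemas
#'
#' Fold-change tables have columns `metabolite, fold_change[, sigma]` plus
#' header comment lines `# kd_reaction:` and `# kd_alpha:`; growth tables
#' have `day, condition, cells[, sigma]`. [simulate_training_dataset()]
#' emits exactly these schemas, so real measurements are drop-in
#' replacements.
#'
#' @param x dataset (data.frame).
#' @param path CSV path.
#' @return the path (write) or the parsed data.frame (read).
#' @export
write_fold_change_dataset <- function(x, path) {
  con <- file(path, "w")
  writeLines(c(paste0("# kd_reaction: ", attr(x, "kd_reaction") %||% "GOT1"),
               paste0("# kd_alpha: ", attr(x, "kd_alpha") %||% 0.85)), con)
  utils::write.csv(x, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_fold_change_dataset
#' @export
read_fold_change_dataset <- function(path) {
  hdr <- readLines(path, n = 2)
  x <- utils::read.csv(path, comment.char = "#")
  attr(x, "kd_reaction") <- sub("# kd_reaction: *", "", hdr[1])
  attr(x, "kd_alpha") <- as.numeric(sub("# kd_alpha: *", "", hdr[2]))
  x
}

#' @rdname write_fold_change_dataset
#' @export
write_growth_dataset <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fold_change_dataset
#' @export
read_growth_dataset <- function(path) utils::read.csv(path)
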