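#' Extended Fourier Amplitude Sensitivity Test (eFAST)
#'
#' Variance-based global sensitivity analysis. Each parameter in turn is
#' assigned the high driving frequency while all others share low
#' (complementary) frequencies; the model output is evaluated along the
#' resulting space-filling search curve and Fourier-decomposed. The
#' first-order index `Si` is the output variance at the driving frequency
#' (and harmonics up to `M`) over the total variance; the total-order index
#' `Sti` is one minus the variance attributable to the complementary set.
#' `Nr` resample curves with random phase shifts are averaged.
#'
#' @param fn function mapping a named parameter vector to a numeric vector
#'   of outputs (names become the `output` column). Errors/non-finite
#'   results are counted and the corresponding curve points dropped.
#' @param lower,upper named numeric bounds per parameter.
#' @param Ns samples per search curve (odd; default 257).
#' @param M interference factor (harmonics; default 4).
#' @param Nr number of resample curves (default 5).
#' @param seed integer seed for the random phases.
#' @param log_scale sample log-uniformly over \[lower, upper\] (default:
#'   reaction velocities span orders of magnitude) instead of uniformly.
#' @return data.frame with columns `parameter`, `output`, `Si`, `Sti`;
#'   attributes `failures` (dropped evaluations), `Ns`, `M`, `Nr`, `seed`.
#' @export
efast <- function(fn, lower, upper, Ns = 257, M = 4, Nr = 5, seed = 1,
                  log_scale = TRUE) {
  k <- length(lower)
  if (k < 2) stop("eFAST needs at least 2 parameters")
  if (is.null(names(lower))) stop("bounds must be named")
  if (Ns %% 2 == 0) Ns <- Ns + 1
  pnames <- names(lower)
  set.seed(seed)
  omega_max <- floor((Ns - 1) / (2 * M))
  cmax <- max(1, floor(omega_max / (2 * M)))
  s <- pi * (2 * seq_len(Ns) - Ns - 1) / Ns

  nfail <- 0L
  res <- list()
  for (i in seq_len(k)) {
    om <- numeric(k)
    om[i] <- omega_max
    om[-i] <- round(seq(1, cmax, length.out = k - 1))
    acc_si <- NULL; acc_sti <- NULL
    for (r in seq_len(Nr)) {
      phi <- stats::runif(k, 0, 2 * pi)
      X <- sapply(seq_len(k), function(p)
        0.5 + asin(sin(om[p] * s + phi[p])) / pi)
      X <- pmin(pmax(X, 1e-12), 1 - 1e-12)
      Y <- NULL
      for (j in seq_len(Ns)) {
        x <- if (log_scale) lower * (upper / lower)^X[j, ]
             else lower + X[j, ] * (upper - lower)
        names(x) <- pnames
        y <- try(fn(x), silent = TRUE)
        if (inherits(y, "try-error") || any(!is.finite(y))) {
          nfail <- nfail + 1L
          y <- rep(NA_real_, if (is.null(Y)) 1 else ncol(Y))
        }
        Y <- rbind(Y, y)
      }
      if (is.null(colnames(Y)))
        colnames(Y) <- paste0("y", seq_len(ncol(Y)))
      ok <- stats::complete.cases(Y)
      for (oc in seq_len(ncol(Y))) {
        y <- Y[, oc]
        y[!ok] <- mean(y[ok])      # neutral fill for dropped points
        nh <- (Ns - 1) / 2
        jj <- seq_len(nh)
        A <- vapply(jj, function(j) sum(y * cos(j * s)) / Ns, 0)
        B <- vapply(jj, function(j) sum(y * sin(j * s)) / Ns, 0)
        spec <- A^2 + B^2
        V <- 2 * sum(spec)
        Vi <- 2 * sum(spec[seq_len(M) * omega_max])
        Vci <- 2 * sum(spec[seq_len(floor(omega_max / 2))])
        si <- if (V > 0) Vi / V else 0
        sti <- if (V > 0) 1 - Vci / V else 0
        key <- colnames(Y)[oc]
        acc_si[[key]] <- c(acc_si[[key]], si)
        acc_sti[[key]] <- c(acc_sti[[key]], sti)
      }
    }
    for (key in names(acc_si))
      res[[length(res) + 1]] <- data.frame(
        parameter = pnames[i], output = key,
        Si = mean(acc_si[[key]]), Sti = mean(acc_sti[[key]]))
  }
  out <- do.call(rbind, res)
  attr(out, "failures") <- nfail
  attr(out, "Ns") <- Ns; attr(out, "M") <- M; attr(out, "Nr") <- Nr
  attr(out, "seed") <- seed
  out
}

#' eFAST over reaction velocities of the metabolic model
#'
#' Applies [efast()] to the knockdown fold-change observables, varying the
#' selected free velocities log-uniformly two orders of magnitude up and
#' down from their current values. A dummy parameter (no effect on the
#' model) is appended as a significance reference.
#'
#' @param model a `pdac_network` (typically identifiability-reduced).
#' @param ic initial condition (named vector); default configuration
#'   baseline.
#' @param parameters velocity names to analyse (default: all free
#'   velocities).
#' @param span fold-range up and down (default 100, i.e. two orders of
#'   magnitude).
#' @param dummy append a dummy parameter.
#' @param ... passed to [efast()] (Ns, M, Nr, seed) and
#'   [fold_change_objective()] via `t_obs`.
#' @param t_obs fold-change observation time (min).
#' @return [efast()] result.
#' @export
efast_velocities <- function(model, ic = NULL,
                             parameters = free_velocity_names(model),
                             span = 100, dummy = TRUE, t_obs = 1440,
                             kd_reaction = "GOT1", alpha = 0.85,
                             panel = model$panel, ...) {
  v0 <- get_velocities(model, parameters)
  lower <- v0 / span; upper <- v0 * span
  if (dummy) {
    lower <- c(lower, dummy.par = 1e-3)
    upper <- c(upper, dummy.par = 1e3)
  }
  fn <- function(x) {
    x <- x[names(x) != "dummy.par"]
    fold_change_objective(set_velocities(model, x), ic = ic, t_obs = t_obs,
                          kd_reaction = kd_reaction, alpha = alpha,
                          panel = panel)
  }
  efast(fn, lower, upper, ...)
}
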