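test_that("a zero-duration protocol returns the initial state", {
  m <- ref_model()
  tr <- simulate(m, proto = protocol(duration = 0))
  expect_identical(tr$times, 0)
  expect_equal(unname(tr$conc[1, "ATP"]), 7.7)
  expect_identical(tr$cell_number, 1)
})

test_that("the stiff solution matches an independent fixed-step RK4 integrator", {
  ## cross-integrator oracle: classical RK4 at step 1e-3 min over 10 min
  m <- ref_model()
  st <- ref_state()
  pk <- pack_model(m)
  h <- 1e-3; nstep <- 10 / h
  y <- unname(st)
  f <- function(y) pdacmet:::.kernel_eval(pk, 0, y)[[1]]
  for (i in seq_len(nstep)) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  tr <- simulate(m, proto = protocol(duration = 10), times = c(0, 10))
  lsoda_end <- c(tr$conc[nrow(tr$conc), ], tr$cell_number[length(tr$times)])
  scale <- pmax(abs(y), 1e-6)
  expect_lt(max(abs(unname(lsoda_end) - y) / scale), 1e-4)
})

test_that("solution is invariant to output-grid refinement", {
  m <- toy_chain()
  t_common <- c(0, 20, 40)
  a <- simulate(m, proto = protocol(duration = 40), times = t_common)
  b <- simulate(m, proto = protocol(duration = 40), times = seq(0, 40, 2))
  ib <- match(t_common, b$times)
  expect_equal(a$conc, b$conc[ib, ], tolerance = 1e-7)
})

test_that("fold-change computation pools compartments and handles nulls", {
  m <- ref_model()
  tr <- simulate(m, proto = protocol_complete(1))
  ## identical trajectories give unit fold-changes
  fc <- compute_fold_change(tr, tr, m, t_obs = 1440)
  expect_equal(fc$fold_change, rep(1, 14))
  expect_identical(attr(fc, "pooling"), "compartment-summed")
  ## a zero-alpha knockdown run is the control within solver tolerance
  kd0 <- simulate(m, proto = protocol_complete(1,
    knockdowns = data.frame(reaction = "GOT1", alpha = 0)))
  fc0 <- compute_fold_change(kd0, tr, m, t_obs = 1440)
  expect_equal(fc0$fold_change, rep(1, 14), tolerance = 1e-8)
  expect_error(compute_fold_change(tr, tr, m, panel = "NOPE"),
               "not in model")
})

test_that("fold-change of a linear boundary-fed system matches the closed form", {
  u <- 1; k <- 0.5; s0 <- 1
  m <- toy_linear(u = u, k = k, s0 = s0)
  t_obs <- 4
  ctrl <- simulate(m, proto = protocol(duration = t_obs),
                   times = seq(0, t_obs, 1))
  kd <- simulate(apply_knockdown(m, "IN", 0.5),
                 proto = protocol(duration = t_obs),
                 times = seq(0, t_obs, 1))
  fc <- compute_fold_change(kd, ctrl, m, panel = "S", t_obs = t_obs)
  S <- function(uu, t) uu / k + (s0 - uu / k) * exp(-k * t)
  expect_equal(fc$fold_change, S(u / 2, t_obs) / S(u, t_obs),
               tolerance = 1e-6)
})

test_that("flux reversal detection finds analytic sign changes", {
  ## toy reaction with flux(t) = cos(t) against baseline +1
  tt <- seq(0, 4 * pi, by = 0.01)
  traj <- structure(list(times = tt,
                         conc = matrix(0, length(tt), 1,
                                       dimnames = list(NULL, "A")),
                         cell_number = rep(1, length(tt)),
                         flux = matrix(cos(tt), ncol = 1,
                                       dimnames = list(NULL, "R"))),
                    class = "pdac_trajectory")
  db <- 0.05
  rv <- detect_flux_reversals(traj, c(R = 1), deadband = db)
  expect_identical(nrow(rv), 2L)
  ## intervals bracket where cos(t) < -deadband
  expect_equal(rv$t_start, c(acos(-db), 2 * pi + acos(-db)),
               tolerance = 0.02)
  expect_equal(rv$t_end, c(2 * pi - acos(-db), 4 * pi - acos(-db)),
               tolerance = 0.02)
  ## self-comparison of a trajectory against its own signs is empty
  m <- toy_chain()
  tr <- simulate(m, proto = protocol(duration = 50), times = seq(0, 50, 5))
  bd <- baseline_directions(m)
  expect_identical(nrow(detect_flux_reversals(tr, bd)), 0L)
  expect_error(detect_flux_reversals(tr, c(RIN = 1)), "missing reactions")
})

test_that("media switches restart the solver without discontinuity artifacts", {
  m <- ref_model()
  tr <- simulate(m, proto = protocol_deprivation(2),
                 times = c(0, 1439, 1440, 1441, 2880))
  ## state is continuous across the switch ...
  i <- match(c(1439, 1440, 1441), tr$times)
  expect_lt(abs(tr$conc[i[2], "ATP"] - tr$conc[i[1], "ATP"]), 0.05)
  ## ... but the media species jump to the new schedule value
  expect_equal(unname(tr$conc[i[1], "GLC_e"]), 35)
  expect_equal(unname(tr$conc[i[3], "GLC_e"]), 0)
  ## times strictly increasing and concentrations above the guard
  expect_true(all(diff(tr$times) > 0))
  expect_true(min(tr$conc) >= -1e-9)
})

test_that("trajectory export is tidy", {
  m <- toy_linear()
  tr <- simulate(m, proto = protocol(duration = 5), times = 0:5)
  tab <- trajectory_table(tr)
  expect_setequal(unique(tab$kind), c("concentration", "flux", "cells"))
  expect_identical(nrow(tab), 6L * (2L + 2L + 1L))
})
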