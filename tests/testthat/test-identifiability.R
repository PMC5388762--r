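## knockdown/observation settings shared by the toy identifiability tests
chain_args <- list(kd_reaction = "RIN", alpha = 0.5, t_obs = 120,
                   panel = c("A", "B", "C"))

test_that("the near-equilibrium pair ranks first and matches a profile scan", {
  m <- toy_chain()
  ics <- rbind(c(A = 1, B = 1, C = 1), c(A = 2, B = 0.5, C = 1.5),
               c(A = 0.5, B = 1.5, C = 0.8))
  rep1 <- do.call(pairwise_velocity_correlation,
                  c(list(m, ics), chain_args))
  expect_true(all(rep1$score >= 0 & rep1$score <= 1, na.rm = TRUE))
  expect_identical(rep1$reaction[1], "RAB")
  expect_gt(rep1$score[rep1$reaction == "RAB"], 0.95)
  expect_gt(rep1$score[rep1$reaction == "RAB"],
            rep1$score[rep1$reaction == "RBC"])

  ## brute-force profile-likelihood oracle on a 20 x 20 (Vf, Vr) grid:
  ## discrepancy from the nominal observable, profiled over Vr. A
  ## confounded pair has a flat profile (any Vf rescues via Vr).
  base <- do.call(fold_change_objective, c(list(m, ic = ics[1, ]),
                                           chain_args))
  flatness <- function(rid) {
    v0 <- get_velocities(m, paste0(rid, c(".Vf", ".Vr")))
    grid <- 10^seq(-1, 1, length.out = 20)
    D <- matrix(NA_real_, 20, 20)
    for (i in 1:20) for (j in 1:20) {
      vv <- stats::setNames(v0 * c(grid[i], grid[j]), names(v0))
      fc <- do.call(fold_change_objective,
                    c(list(set_velocities(m, vv), ic = ics[1, ]),
                      chain_args))
      D[i, j] <- sum((fc - base)^2)
    }
    max(apply(D, 1, min)) / max(D)   # profiled ridge height vs landscape
  }
  expect_lt(flatness("RAB"), 0.05)           # confounded: flat ridge
  expect_gt(flatness("RBC"), 10 * flatness("RAB"))
})

test_that("equilibrium reduction bookkeeping is exact", {
  m <- toy_chain()
  rep1 <- data.frame(reaction = c("RAB", "RBC"), score = c(0.99, 0.3),
                     n_ic = 3, degenerate = FALSE)
  n0 <- length(free_velocity_names(m))
  ## no score reaches a threshold of 1: model unchanged
  red0 <- reduce_by_equilibrium(m, rep1, threshold = 1)
  expect_length(red0$constrained, 0)
  expect_identical(length(free_velocity_names(red0$model)), n0)
  ## one declared-correlated pair: free count drops by exactly one
  red1 <- reduce_by_equilibrium(m, rep1, threshold = 0.95)
  expect_identical(red1$constrained, "RAB")
  expect_identical(length(free_velocity_names(red1$model)), n0 - 1L)
  expect_false("RAB.Vr" %in% free_velocity_names(red1$model))
  ## the constrained Vr tracks Vf/Veq under subsequent knockdowns
  mk <- apply_knockdown(red1$model, "RAB", 0.7)
  ev <- effective_velocities(mk)
  i <- match("RAB", mk$reaction_ids)
  expect_equal(ev$vr[i], ev$vf[i] / mk$reactions[[i]]$params$Veq,
               tolerance = 1e-12)
  expect_error(reduce_by_equilibrium(m, rep1, threshold = 0), "threshold")
})

test_that("constrained models reproduce unconstrained simulations at Vr = Vf/Veq", {
  ## the packaged Veq values satisfy Vr = Vf/Veq exactly at the nominal
  ## velocities, so constraining every pair must not change the dynamics
  m <- ref_model()
  mc <- m
  for (r in m$reactions) if (r$explicit_vr) mc$constrained[r$id] <- TRUE
  expect_lt(length(free_velocity_names(mc)), length(free_velocity_names(m)))
  a <- simulate(m, proto = protocol_complete(1), times = c(0, 720, 1440))
  b <- simulate(mc, proto = protocol_complete(1), times = c(0, 720, 1440))
  expect_equal(a$conc, b$conc, tolerance = 1e-6)
  expect_equal(a$cell_number, b$cell_number, tolerance = 1e-8)
})

test_that("iterated reduction is monotone and terminates", {
  m <- toy_chain()
  ics <- rbind(c(A = 1, B = 1, C = 1), c(A = 2, B = 0.5, C = 1.5))
  out <- do.call(run_identifiability,
                 c(list(m, ics, threshold = 0.95), chain_args))
  expect_identical(out$constrained[[1]], "RAB")
  ## free-parameter count is monotone non-increasing across rounds
  expect_identical(out$free_velocities,
                   length(free_velocity_names(m)) -
                     sum(lengths(out$constrained)))
  expect_true(all(c("reaction", "score", "round") %in% names(out$report)))
})
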