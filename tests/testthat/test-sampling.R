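test_that("LHS places exactly one sample in every stratum", {
  b <- data.frame(metabolite = "X", lower = 0.0001, upper = 1.0001)
  s <- lhs_initial_conditions(b, 4, seed = 1, copy_map = c())
  counts <- table(cut(s[, "X"], breaks = seq(0.0001, 1.0001, length.out = 5)))
  expect_true(all(counts == 1))

  ## stratum-occupancy matrix over the full 46-dimensional bounds:
  ## every sampled column is a permutation of the strata
  bounds <- ic_bounds()
  n <- 20
  ens <- lhs_initial_conditions(bounds, n, seed = 3)
  copies <- c("mPYR", "mCIT", "mAKG", "mMAL", "mOAA", "mASP", "mGLU")
  for (j in setdiff(bounds$metabolite, copies)) {
    lo <- bounds$lower[bounds$metabolite == j]
    up <- bounds$upper[bounds$metabolite == j]
    stratum <- floor((ens[, j] - lo) / (up - lo) * n)
    expect_setequal(stratum, 0:(n - 1))
  }
})

test_that("LHS respects the printed bounds and compartment duplication", {
  ens <- lhs_initial_conditions(ic_bounds(), 100, seed = 5)
  expect_true(all(ens[, "GLC"] >= 2.5 & ens[, "GLC"] <= 14))
  for (dup in c("mPYR", "mMAL", "mASP", "mGLU"))
    expect_identical(ens[, dup], ens[, sub("^m", "", dup)])
  expect_error(lhs_initial_conditions(
    data.frame(metabolite = "X", lower = -1, upper = 1), 5), "bounds")
})

test_that("sampling is seed-reproducible and seed-sensitive", {
  b <- ic_bounds()
  expect_identical(lhs_initial_conditions(b, 10, seed = 9),
                   lhs_initial_conditions(b, 10, seed = 9))
  expect_false(identical(lhs_initial_conditions(b, 10, seed = 9),
                         lhs_initial_conditions(b, 10, seed = 10)))
  base <- c(A = 2, B = 0.5)
  expect_identical(gaussian_initial_conditions(base, 10, seed = 2),
                   gaussian_initial_conditions(base, 10, seed = 2))
  expect_false(identical(gaussian_initial_conditions(base, 10, seed = 2),
                         gaussian_initial_conditions(base, 10, seed = 3)))
})

test_that("Gaussian draws are truncated at +/-50% with sd = mean/6", {
  base <- c(GLC = 10, ATP = 3)
  g <- gaussian_initial_conditions(base, 1000, seed = 1)
  expect_true(all(g[, "GLC"] >= 5 & g[, "GLC"] <= 15))
  expect_true(all(g[, "ATP"] >= 1.5 & g[, "ATP"] <= 4.5))
  ## degenerate limit
  g0 <- gaussian_initial_conditions(base, 50, seed = 1, sd_scale = 0)
  expect_true(all(g0[, "GLC"] == 10))
  expect_error(gaussian_initial_conditions(c(A = 0), 5), "positive")
})

test_that("truncated-Gaussian moments match numerical quadrature", {
  mu <- 4; sd <- mu / 6; a <- 0.5 * mu; b <- 1.5 * mu
  Z <- stats::integrate(function(x) stats::dnorm(x, mu, sd), a, b)$value
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, mu, sd) / Z,
                         a, b)$value
  m2 <- stats::integrate(function(x) (x - m1)^2 * stats::dnorm(x, mu, sd) / Z,
                         a, b)$value
  g <- gaussian_initial_conditions(c(X = mu), 1e5, seed = 7)
  expect_equal(mean(g[, "X"]), m1, tolerance = 0.01)
  expect_equal(stats::sd(g[, "X"]), sqrt(m2), tolerance = 0.01)
})
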