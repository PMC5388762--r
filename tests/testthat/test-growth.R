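p_ref <- c(alpha_atp = 7e-4, alpha_glc = 1e-4, alpha_gln = 3e-4,
           alpha_d = 1.2e-4, k_ap = 10, k_gc = 0.5, k_gn = 2, K_CC = 100)

test_that("the Monod growth rate has the required fixed points", {
  expect_identical(specific_growth_rate(0, 0, 0, p_ref), 0)
  ## every nutrient at its half-saturation constant: half the maximal rate
  expect_equal(specific_growth_rate(10, 0.5, 2, p_ref),
               (7e-4 + 1e-4 + 3e-4) / 2)
  expect_equal(specific_growth_rate(1e9, 1e9, 1e9, p_ref),
               7e-4 + 1e-4 + 3e-4, tolerance = 1e-6)
  expect_error(specific_growth_rate(-1, 0, 0, p_ref), "negative")
})

test_that("lambda is monotone non-decreasing in each nutrient", {
  g <- seq(0, 50, length.out = 40)
  for (w in 1:3) {
    args <- list(atp = 3, glc_in = 5, gln_in = 1)
    lam <- vapply(g, function(v) {
      args[[w]] <- v
      do.call(specific_growth_rate, c(args, list(p = p_ref)))
    }, 0)
    expect_true(all(diff(lam) >= -1e-15))
  }
})

test_that("the cell-number derivative has its logistic fixed points", {
  p0 <- p_ref; p0["alpha_d"] <- 0
  expect_identical(cell_number_derivative(100, 1e-3, p0), 0)  # at K_CC
  expect_identical(cell_number_derivative(0, 1e-3, p_ref), 0) # extinction
  expect_equal(cell_number_derivative(2, 5e-4, p_ref),
               5e-4 * (1 - 2 / 100) * 2 - 1.2e-4 * 2)
})

test_that("with lambda = 0 the simulated cell number decays exponentially", {
  ad <- 1e-3
  m <- toy_cycle(growth = list(alpha_atp = 0, alpha_glc = 0, alpha_gln = 0,
                               alpha_d = ad, k_ap = 1, k_gc = 1, k_gn = 1,
                               K_CC = 10))
  tt <- seq(0, 2000, 200)
  tr <- simulate(m, proto = protocol(duration = 2000), times = tt,
                 rtol = 1e-10, atol = 1e-14)
  expect_equal(tr$cell_number, exp(-ad * tr$times), tolerance = 1e-8)
})

test_that("constant-nutrient growth follows the logistic-with-death closed form", {
  m <- toy_growth(growth = as.list(p_ref))
  lam <- specific_growth_rate(5, 10, 2, p_ref)   # fixed nutrient levels
  ad <- p_ref[["alpha_d"]]; K <- p_ref[["K_CC"]]
  r <- lam - ad
  Keff <- K * (1 - ad / lam)
  tt <- seq(0, 50 * 1440, length.out = 30)
  tr <- simulate(m, proto = protocol(duration = max(tt)), times = tt,
                 rtol = 1e-10, atol = 1e-12)
  closed <- Keff / (1 + (Keff - 1) * exp(-r * tt))
  expect_equal(tr$cell_number, closed, tolerance = 1e-6)
  ## long-time limit is K_CC (1 - alpha_d / lambda)
  expect_equal(tail(tr$cell_number, 1), Keff, tolerance = 1e-4)
})

test_that("growth parameter validation rejects bad sets", {
  expect_error(growth_parameters(p_ref[-1]), "missing")
  bad <- p_ref; bad["K_CC"] <- 0
  expect_error(growth_parameters(bad), "K_CC")
})
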