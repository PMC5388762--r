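test_that("limiting behaviors of the rate laws are correct", {
  mm <- list(id = "T", form = "mm_irr", stoich = c(S = -1, P = 1),
             subs = "S", pros = "P", modifiers = list(),
             params = list(Km_S = 0.2, Vf = 3))
  ## saturation: S = 1000 Km gives flux within 0.1% of Vf
  expect_equal(rate_law_flux(mm, c(S = 200, P = 1), vf = 3), 3,
               tolerance = 1e-3)
  ## knocked-out enzyme carries no flux anywhere
  expect_identical(rate_law_flux(mm, c(S = 1, P = 1), vf = 0), 0)

  ## reversible flux vanishes exactly at equilibrium
  hd <- list(id = "H", form = "haldane", stoich = c(S = -1, P = 1),
             subs = "S", pros = "P", modifiers = list(),
             params = list(Km_S = 1, Km_P = 2, Keq = 4, Vf = 1))
  expect_equal(rate_law_flux(hd, c(S = 1, P = 4), vf = 1), 0)
  rv <- list(id = "R", form = "mm_rev", stoich = c(S = -1, P = 1),
             subs = "S", pros = "P", modifiers = list(),
             params = list(Km_S = 1, Km_P = 1, Vf = 2, Vr = 1, Veq = 2))
  ## mm_rev zero when Vf*(S/Kms) == Vr*(P/Kmp)
  expect_equal(rate_law_flux(rv, c(S = 1, P = 2), vf = 2, vr = 1), 0)
  ca <- list(id = "C", form = "carrier", stoich = c(S = -1, P = 1),
             subs = "S", pros = "P", modifiers = list(),
             params = list(Kms = 1, Kmp = 1, Keq = 1, alpha = 1))
  expect_equal(rate_law_flux(ca, c(S = 2, P = 2), vf = 5), 0)

  ## missing metabolite is an error
  expect_error(rate_law_flux(mm, c(P = 1), vf = 1), "missing")
})

test_that("every rate-law form matches a direct-substitution oracle", {
  ## the oracle writes out each algebraic formula independently of the
  ## package's evaluator
  for (i in 1:10) {
    set.seed(100 + i)
    cc <- c(A = runif(1, 0.01, 5), B = runif(1, 0.01, 5),
            P = runif(1, 0.01, 5), Q = runif(1, 0.01, 5),
            M = runif(1, 0.01, 5))
    pk <- function() runif(1, 0.05, 3)
    vf <- runif(1, 0.1, 10); vr <- runif(1, 0.1, 10)

    ## mm_irr with one of each modifier type
    p <- list(Km_A = pk(), Km_B = pk(), Ki_M = pk(), Ka_P = pk(),
              Km_Q = pk(), Vf = vf)
    rx <- list(id = "t", form = "mm_irr", stoich = c(A = -1, B = -1),
               subs = c("A", "B"),
               pros = character(0),
               modifiers = list(list(type = "inh", species = "M"),
                                list(type = "act", species = "P"),
                                list(type = "cof", species = "Q")),
               params = p)
    oracle <- vf * cc["A"] / (p$Km_A + cc["A"]) *
      cc["B"] / (p$Km_B + cc["B"]) *
      p$Ki_M / (p$Ki_M + cc["M"]) *
      cc["P"] / (p$Ka_P + cc["P"]) *
      cc["Q"] / (p$Km_Q + cc["Q"])
    expect_equal(rate_law_flux(rx, cc, vf), unname(oracle),
                 tolerance = 1e-12)

    ## mm_rev (convenience kinetics)
    p <- list(Km_A = pk(), Km_B = pk(), Km_P = pk(), Km_Q = pk(),
              Vf = vf, Vr = vr, Veq = vf / vr)
    rx <- list(id = "t", form = "mm_rev",
               stoich = c(A = -1, B = -1, P = 1, Q = 1),
               subs = c("A", "B"), pros = c("P", "Q"),
               modifiers = list(), params = p)
    a1 <- cc["A"] / p$Km_A; a2 <- cc["B"] / p$Km_B
    b1 <- cc["P"] / p$Km_P; b2 <- cc["Q"] / p$Km_Q
    oracle <- (vf * a1 * a2 - vr * b1 * b2) /
      ((1 + a1) * (1 + a2) + (1 + b1) * (1 + b2) - 1)
    expect_equal(rate_law_flux(rx, cc, vf, vr), unname(oracle),
                 tolerance = 1e-12)

    ## random bi-bi with dead-end complexes
    p <- list(Kia = pk(), Kib = pk(), Kmb = pk(), Kip = pk(), Kiq = pk(),
              Kmq = pk(), Kd_AQ = pk(), Kd_BP = pk(),
              Vf = vf, Vr = vr, Veq = vf / vr)
    rx <- list(id = "t", form = "bibi_rev",
               stoich = c(A = -1, B = -1, P = 1, Q = 1),
               subs = c("A", "B"), pros = c("P", "Q"),
               modifiers = list(), params = p)
    A <- cc["A"]; B <- cc["B"]; P <- cc["P"]; Q <- cc["Q"]
    D <- 1 + A / p$Kia + B / p$Kib + P / p$Kip + Q / p$Kiq +
      A * B / (p$Kia * p$Kmb) + P * Q / (p$Kip * p$Kmq) +
      A * Q / p$Kd_AQ + B * P / p$Kd_BP
    oracle <- (vf * A * B / (p$Kia * p$Kmb) -
                 vr * P * Q / (p$Kip * p$Kmq)) / D
    expect_equal(rate_law_flux(rx, cc, vf, vr), unname(oracle),
                 tolerance = 1e-12)

    ## haldane (two substrates, two products)
    p <- list(Km_A = pk(), Km_B = pk(), Km_P = pk(), Km_Q = pk(),
              Keq = pk(), Vf = vf)
    rx <- list(id = "t", form = "haldane",
               stoich = c(A = -1, B = -1, P = 1, Q = 1),
               subs = c("A", "B"), pros = c("P", "Q"),
               modifiers = list(), params = p)
    D <- (1 + A / p$Km_A) * (1 + B / p$Km_B) +
      (1 + P / p$Km_P) * (1 + Q / p$Km_Q) - 1
    oracle <- vf * (A * B - P * Q / p$Keq) / (p$Km_A * p$Km_B * D)
    expect_equal(rate_law_flux(rx, cc, vf), unname(oracle),
                 tolerance = 1e-12)

    ## carrier with trans-interaction
    p <- list(Kms = pk(), Kmp = pk(), Keq = pk(), alpha = pk(), Vf = vf)
    rx <- list(id = "t", form = "carrier", stoich = c(A = -1, P = 1),
               subs = "A", pros = "P", modifiers = list(), params = p)
    D <- 1 + A / p$Kms + P / p$Kmp + p$alpha * A * P / (p$Kms * p$Kmp)
    oracle <- vf * (A - P / p$Keq) / (p$Kms * D)
    expect_equal(rate_law_flux(rx, cc, vf), unname(oracle),
                 tolerance = 1e-12)

    ## mass action with stoichiometric powers
    rx <- list(id = "t", form = "ma_rev",
               stoich = c(A = -1, B = -1, P = 2),
               subs = c("A", "B"), pros = "P",
               modifiers = list(), params = list(Vf = vf, Vr = vr,
                                                 Veq = vf / vr))
    oracle <- vf * A * B - vr * P^2
    expect_equal(rate_law_flux(rx, cc, vf, vr), unname(oracle),
                 tolerance = 1e-12)

    ## MWC with allosteric effectors and a cofactor substrate
    p <- list(Km_A = pk(), Km_B = pk(), n = 2, L0 = runif(1, 0.5, 5),
              c = 0.05, Ki_M = pk(), Ka_Q = pk(), Vf = vf)
    rx <- list(id = "t", form = "mwc", stoich = c(A = -1, B = -1, P = 1),
               subs = c("A", "B"), pros = "P",
               modifiers = list(list(type = "allo_inh", species = "M"),
                                list(type = "allo_act", species = "Q")),
               params = p)
    s <- A / p$Km_A
    L <- p$L0 * (1 + cc["M"] / p$Ki_M)^2 / (1 + cc["Q"] / p$Ka_Q)^2
    oracle <- vf * s * (1 + s) / ((1 + s)^2 + L * (1 + p$c * s)^2) *
      B / (p$Km_B + B)
    expect_equal(rate_law_flux(rx, cc, vf), unname(oracle),
                 tolerance = 1e-12)
  }
})

test_that("compiled kernel fluxes agree with the R rate-law path", {
  m <- ref_model()
  st <- ref_state()
  for (seed in 1:3) {
    x <- st
    set.seed(seed)
    x[] <- x * exp(rnorm(length(x), 0, 0.3))
    ck <- assemble_rhs(m, x)$flux
    rr <- all_fluxes(m, x[seq_len(nrow(m$species))])
    expect_equal(ck, rr, tolerance = 1e-12)
  }
})

test_that("evaluate_flux validates its inputs", {
  m <- ref_model()
  st <- ref_state()[seq_len(nrow(ref_model()$species))]
  expect_error(evaluate_flux(m, "NOPE", st), "unknown reaction")
  bad <- st; bad[["GLC"]] <- -1
  expect_error(evaluate_flux(m, "HK", bad), "negative")
  ## forward component scales linearly with effective Vf
  f1 <- evaluate_flux(m, "HK", st)
  m2 <- apply_knockdown(m, "HK", 0.5)
  expect_equal(evaluate_flux(m2, "HK", st), 0.5 * f1, tolerance = 1e-12)
})
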