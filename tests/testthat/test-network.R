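test_that("reference configuration satisfies the structural counts", {
  ct <- network_counts(ref_model())
  expect_identical(ct$metabolites, 46L)
  expect_identical(ct$reactions, 53L)
  expect_identical(ct$velocities, 71L)
  expect_identical(ct$parameters, 372L)
  expect_identical(ct$states, 47L)
  expect_length(ref_model()$panel, 14L)
  ## glycolysis/PPP link metabolites and shuttle species are present
  expect_true(all(c("G6P", "F6P", "G3P") %in% ref_model()$species$id))
  expect_true(all(c("MAL", "mMAL", "ASP", "mASP", "CIT", "mCIT",
                    "GLU", "mGLU", "AKG", "mAKG") %in%
                    ref_model()$species$id))
})

test_that("a minimal toy configuration round-trips its parameter inventory", {
  m <- toy_linear()
  expect_identical(network_counts(m)$metabolites, 1L)
  expect_identical(network_counts(m)$reactions, 2L)
  expect_identical(sort(names(parameter_inventory(m))),
                   sort(c("IN.Vf", "OUT.Vf")))
})

test_that("validation enumerates every violation, not just the first", {
  bad <- list(
    species = list(toy_species("A", 1)),
    reactions = list(
      list(id = "R1", form = "mm_irr", stoich = list(A = -1),
           substrates = list("A"), products = list(),
           params = list(Km_A = -1, Vf = 1)),
      list(id = "R1", form = "nosuchform", stoich = list(ZZZ = -1),
           substrates = list("ZZZ"), products = list(),
           params = list(Vf = 1))))
  err <- tryCatch(load_network(bad), error = conditionMessage)
  expect_match(err, "R1.*Km_A", all = FALSE)       # names reaction and constant
  expect_match(err, "duplicate reaction id")
  expect_match(err, "unknown rate-law form")
  expect_match(err, "undeclared metabolite")
  expect_match(err, "4 problem", all = FALSE)
})

test_that("AKT modulation scales only the flagged maximal velocities", {
  m <- ref_model()
  st <- ref_state()
  akt_targets <- m$reaction_ids[vapply(m$reactions, `[[`, TRUE,
                                       "akt_modulated")]
  expect_setequal(akt_targets, c("GLUT1", "HK", "PFK"))
  f1 <- assemble_rhs(m, st)$flux
  f0 <- assemble_rhs(apply_akt_modulation(m, 0), st)$flux
  fh <- assemble_rhs(apply_akt_modulation(m, 0.5), st)$flux
  for (id in akt_targets) {
    expect_equal(f0[[id]], 0.2 * f1[[id]], tolerance = 1e-12)
    expect_equal(fh[[id]], 0.6 * f1[[id]], tolerance = 1e-12)
  }
  others <- setdiff(names(f1), akt_targets)
  expect_equal(f0[others], f1[others], tolerance = 1e-12)
  expect_error(apply_akt_modulation(m, 1.5), "0, 1")
})

test_that("knockdowns scale forward velocities and constrained reverses", {
  m <- ref_model()
  st <- ref_state()
  f1 <- assemble_rhs(m, st)$flux
  ## alpha = 0.85: effective Vf is 15% of nominal
  ev0 <- effective_velocities(m)
  ev <- effective_velocities(apply_knockdown(m, "GOT1", 0.85))
  i <- match("GOT1", m$reaction_ids)
  expect_equal(ev$vf[i], 0.15 * ev0$vf[i], tolerance = 1e-12)
  ## alpha = 0: model unchanged
  expect_equal(assemble_rhs(apply_knockdown(m, "GOT1", 0), st)$flux, f1,
               tolerance = 1e-15)
  ## alpha = 1: zero forward flux at every state (GLS is irreversible)
  m1 <- apply_knockdown(m, "GLS", 1)
  for (seed in 1:3) {
    x <- st; set.seed(seed); x[] <- x * exp(rnorm(length(x), 0, 0.5))
    expect_identical(assemble_rhs(m1, x)$flux[["GLS"]], 0)
  }
  expect_error(apply_knockdown(m, "NOPE", 0.5), "unknown reaction")
  expect_error(apply_knockdown(m, "GOT1", 1.5), "alpha")
  ## equilibrium-constrained Vr is recomputed from the knocked-down Vf
  mc <- m; mc$constrained["GAPDH"] <- TRUE
  mck <- apply_knockdown(mc, "GAPDH", 0.6)
  j <- match("GAPDH", m$reaction_ids)
  veq <- m$reactions[[j]]$params$Veq
  evc <- effective_velocities(mck)
  expect_equal(evc$vr[j], evc$vf[j] / veq, tolerance = 1e-12)
})
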