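test_that("ground-truth generation is seeded and scale-controlled", {
  m <- ref_model()
  ## scale 0: the truth is the reference itself
  t0 <- make_ground_truth(m, scale = 0, seed = 1)
  expect_equal(t0$velocities, get_velocities(m), tolerance = 1e-15)
  expect_identical(t0$growth, m$growth)
  ## different seeds give distinct parameter vectors
  t1 <- make_ground_truth(m, scale = 0.5, seed = 1)
  t2 <- make_ground_truth(m, scale = 0.5, seed = 2)
  expect_false(identical(t1$velocities, t2$velocities))
  expect_error(make_ground_truth(m, scale = -1), ">= 0")
})

test_that("the empirical log-sd of the velocity factors matches the scale", {
  m <- ref_model()
  v0 <- get_velocities(m)
  fac <- unlist(lapply(1:150, function(s)
    make_ground_truth(m, scale = 0.4, seed = s)$velocities / v0))
  expect_gt(length(fac), 1e4)
  expect_equal(stats::sd(log(fac)), 0.4, tolerance = 0.02)
})

test_that("noise-free datasets equal the truth-model predictions exactly", {
  m <- ref_model()
  truth <- make_ground_truth(m, scale = 0.1, seed = 3)
  study <- simulate_training_dataset(truth, noise_cv = 0, seed = 1)
  direct <- fold_change_objective(truth$model)
  expect_equal(stats::setNames(study$fold_change$fold_change,
                               study$fold_change$metabolite),
               direct, tolerance = 1e-6)
  expect_identical(attr(study$fold_change, "kd_reaction"), "GOT1")
  expect_identical(attr(study$fold_change, "kd_alpha"), 0.85)
  ## deprivation validation curve ends below the complete-media curve
  va <- study$validation
  expect_lt(va$cells[va$condition == "deprived" & va$day == 5],
            va$cells[va$condition == "complete" & va$day == 5])
})

test_that("observation noise has the requested coefficient of variation", {
  m <- ref_model()
  truth <- make_ground_truth(m, scale = 0, seed = 1)
  clean <- simulate_training_dataset(truth, noise_cv = 0, seed = 1,
                                     days = 1)$fold_change$fold_change
  ratios <- unlist(lapply(1:80, function(s)
    simulate_training_dataset(truth, noise_cv = 0.1, seed = s,
                              days = 1)$fold_change$fold_change / clean))
  expect_equal(stats::sd(ratios) / mean(ratios), 0.1, tolerance = 0.1)
})

test_that("regeneration with the same seed is byte-identical", {
  m <- ref_model()
  truth <- make_ground_truth(m, scale = 0.2, seed = 5)
  a <- simulate_training_dataset(truth, noise_cv = 0.1, seed = 9, days = 1)
  b <- simulate_training_dataset(truth, noise_cv = 0.1, seed = 9, days = 1)
  expect_identical(a$fold_change, b$fold_change)
  expect_identical(a$growth, b$growth)
})

test_that("dataset files round-trip through the documented schemas", {
  m <- ref_model()
  truth <- make_ground_truth(m, scale = 0, seed = 1)
  study <- simulate_training_dataset(truth, noise_cv = 0.05, seed = 2,
                                     days = 1)
  fp <- tempfile(fileext = ".csv"); gp <- tempfile(fileext = ".csv")
  write_fold_change_dataset(study$fold_change, fp)
  write_growth_dataset(study$growth, gp)
  fc2 <- read_fold_change_dataset(fp)
  expect_equal(fc2$fold_change, study$fold_change$fold_change)
  expect_identical(attr(fc2, "kd_reaction"), "GOT1")
  expect_identical(attr(fc2, "kd_alpha"), 0.85)
  expect_equal(read_growth_dataset(gp)$cells, study$growth$cells)
})
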