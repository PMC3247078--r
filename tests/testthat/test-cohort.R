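## cohort generation runs the full population model per individual, so the
## tests use the reduced state space (boundary 25) and small cohorts

test_that("zero variability collapses the cohort onto the base model", {
  spec <- cohortSpec(nIndividuals = 3, cv = c(u = 0), seed = 4)
  fp <- feedbackParameters()
  co <- sampleCohort(spec, fp, B = 25L, gridPoints = 10)
  base <- depletionTimeFromTrajectory(
    simulateDde(fp, B = 25L, gridPoints = 10, tEndYears = 500,
                stopBelow = 500), 1e3)
  expect_equal(co$TdYears, rep(base, 3), tolerance = 1e-9)
  expect_equal(co$sdYears, 0, tolerance = 1e-9)
  expect_equal(co$excluded, 0L)
})

test_that("a fixed seed reproduces the cohort end to end", {
  spec <- cohortSpec(nIndividuals = 4, cv = c(u = 0.01), seed = 42)
  a <- sampleCohort(spec, B = 25L, gridPoints = 10)
  b <- sampleCohort(spec, B = 25L, gridPoints = 10)
  expect_identical(a$draws, b$draws)
  expect_identical(a$TdYears, b$TdYears)
})

test_that("depletion age is far more sensitive to u than to Kn variability", {
  ## 2% variation in degradation vs 20% variation in the suppression
  ## constant: the eigenvalue's steep dependence on u must dominate
  fp <- feedbackParameters()
  coU <- sampleCohort(cohortSpec(nIndividuals = 8, cv = c(u = 0.02),
                                 seed = 10),
                      fp, B = 25L, gridPoints = 10, capYears = 400)
  coKn <- sampleCohort(cohortSpec(nIndividuals = 8, cv = c(Kn = 0.2),
                                  seed = 10),
                       fp, B = 25L, gridPoints = 10, capYears = 400)
  expect_gt(coU$sdYears, coKn$sdYears)
  expect_gt(coU$sdYears, 1)   # years of spread from percent-level biology
})

test_that("count observations carry the configured multiplicative noise", {
  fp <- feedbackParameters()
  traj <- simulateDde(fp, B = 25L, gridPoints = 10, tEndYears = 55)
  ## zero noise returns the model curve exactly
  exact <- sampleCounts(traj, ages = seq(0, 50, 5), sigma = 0, seed = 1)
  expect_equal(exact$count,
               approx(traj@times, traj@n1, xout = seq(0, 50, 5))$y)
  ## log-residuals of a large sample have sd ~ sigma
  many <- sampleCounts(traj, ages = rep(25, 4000), sigma = 0.5, seed = 2)
  resid <- log(many$count) - log(approx(traj@times, traj@n1, 25)$y)
  expect_equal(sd(resid), 0.5, tolerance = 0.05)
  expect_equal(mean(resid), 0, tolerance = 0.05)
  ## counts are non-negative and decrease in expectation with age
  obs <- sampleCounts(traj, ages = seq(0, 50, 10), sigma = 0.3, seed = 3)
  expect_true(all(obs$count >= 0))
  mexp <- approx(traj@times, traj@n1, xout = seq(0, 50, 10))$y
  expect_true(all(diff(mexp) < 0))
  expect_error(sampleCounts(traj, ages = c(10, 200), sigma = 0.1, seed = 1),
               "support")
})

test_that("cohort specifications validate their fields", {
  expect_error(cohortSpec(cv = c(zz = 0.1)), "names among")
  expect_error(cohortSpec(cv = c(u = -0.1)), "non-negative")
  expect_error(cohortSpec(ages = c(-5, 10)), "0, 100")
  expect_error(cohortSpec(sigma = -1), "non-negative")
})
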