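## module tests run on a reduced state space (boundary 25, coarse rate
## grids); the production-scale numbers live in the acceptance suite

test_that("the suppression law halves the basal rate at Kn", {
  fp <- feedbackParameters()
  expect_equal(k1OfN2(0, fp), 0.06)
  expect_equal(k1OfN2(8.2e4, fp), 0.03)
  expect_true(all(diff(k1OfN2(seq(0, 1e6, length.out = 50), fp)) < 0))
  expect_error(k1OfN2(-1, fp), "non-negative")
  expect_error(feedbackParameters(Kn = -5), "positive")
})

test_that("the rate map is monotone and anchored at the unsuppressed rate", {
  fp <- feedbackParameters()
  B <- 25L
  map <- buildRateMap(fp, B = B, gridPoints = 12)
  expect_true(all(lambda1(map) < 0))
  expect_true(all(diff(abs(lambda1(map))) <= 1e-12))
  ## lambda1(0) equals the dominant mode at k1 = k1Max
  sw0 <- updateParameters(fp@switch, k1 = fp@k1Max)
  direct <- lambda1(dominantMode(buildGenerator(sw0, B))) * minutesPerYear()
  expect_equal(lambda1At(map, 0), direct, tolerance = 1e-9)
})

test_that("interpolated rates match held-out direct eigensolves within 1%", {
  fp <- feedbackParameters()
  B <- 25L
  map <- buildRateMap(fp, B = B, gridPoints = 25)
  for (n2 in c(3e3, 4e4, 2e5)) {
    sw <- updateParameters(fp@switch, k1 = k1OfN2(n2, fp))
    direct <- lambda1(dominantMode(buildGenerator(sw, B))) * minutesPerYear()
    expect_equal(lambda1At(map, n2), direct, tolerance = 0.01)
  }
})

test_that("without delay the population decays as a pure exponential", {
  fp0 <- feedbackParameters(tauYears = 0)
  map <- buildRateMap(fp0, B = 25L, gridPoints = 10)
  traj <- simulateDde(fp0, map = map, tEndYears = 5)
  r0 <- abs(lambda1At(map, 0))
  expect_equal(traj@n2, numeric(length(traj@times)))
  expect_equal(traj@n1, 1e6 * exp(-r0 * traj@times), tolerance = 1e-10)
})

test_that("an enormous Kn reduces the delay model to the no-feedback decay", {
  fp <- feedbackParameters(Kn = 1e12)
  map <- buildRateMap(fp, B = 25L, gridPoints = 10)
  ## fine steps: on the reduced space the unsuppressed rate is fast enough
  ## that the default step would leave visible truncation error
  traj <- simulateDde(fp, map = map, tEndYears = 2,
                      stepYears = fp@tauYears / 200)
  r0 <- abs(lambda1At(map, 0))
  expect_equal(traj@n1, 1e6 * exp(-r0 * traj@times), tolerance = 1e-4)
})

test_that("the conveyor conserves mass and is silent before one delay", {
  fp <- feedbackParameters()
  map <- buildRateMap(fp, B = 25L, gridPoints = 12)
  traj <- simulateDde(fp, map = map, tEndYears = 3)
  N0 <- fp@N0
  ## mass accounting: N0 = n1 + n2 + cumulative outflow at every node
  expect_lt(max(abs(traj@n1 + traj@n2 + traj@outflowCum - N0)) / N0, 1e-9)
  expect_true(all(diff(traj@outflowCum) >= 0))
  ## no outflow before t = tau
  early <- traj@times < fp@tauYears - 1e-12
  expect_true(all(traj@outflowCum[early] == 0))
  expect_lt(max(abs(traj@n1[early] + traj@n2[early] - N0)) / N0, 1e-9)
  expect_error(simulateDde(fp, map = map, stepYears = 1), "exceeds the delay")
})

test_that("suppression only slows depletion, and the stepper is converged", {
  fp <- feedbackParameters()
  B <- 25L
  map <- buildRateMap(fp, B = B, gridPoints = 12)
  traj <- simulateDde(fp, map = map, tEndYears = 60,
                      stepYears = fp@tauYears / 80, stopBelow = 500)
  td <- depletionTimeFromTrajectory(traj, 1e3)
  ## no-feedback depletion at the unsuppressed rate is necessarily faster
  tdNoFeedback <- log(1e6 / 1e3) / abs(lambda1At(map, 0))
  expect_gt(td, tdNoFeedback)
  ## halving the step moves the crossing by far less than 0.1 years
  traj2 <- simulateDde(fp, map = map, tEndYears = 60,
                       stepYears = fp@tauYears / 160, stopBelow = 500)
  expect_lt(abs(depletionTimeFromTrajectory(traj2, 1e3) - td), 0.1)
})

test_that("crossing detection interpolates linearly and reports failures", {
  tt <- seq(0, 10, by = 0.1)
  r <- 1.2
  traj <- new("PopulationTrajectory", times = tt, n1 = 1e6 * exp(-r * tt),
              n2 = numeric(length(tt)),
              lambda1PerYear = rep(-r, length(tt)),
              outflowCum = 1e6 * (1 - exp(-r * tt)), N0 = 1e6)
  expect_equal(depletionTimeFromTrajectory(traj, 1e3),
               log(1000) / r, tolerance = 1e-3)
  expect_error(depletionTimeFromTrajectory(traj, 1e-3), "extend")
})
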