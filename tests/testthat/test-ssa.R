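test_that("a fixed seed reproduces the event sequence bit for bit", {
  p <- table1Params()
  a <- simulateSsa(p, c(6, 1), tMaxYears = 0.02, seed = 42)
  b <- simulateSsa(p, c(6, 1), tMaxYears = 0.02, seed = 42)
  expect_identical(a@times, b@times)
  expect_identical(a@states, b@states)
  c2 <- simulateSsa(p, c(6, 1), tMaxYears = 0.02, seed = 43)
  expect_false(identical(a@times, c2@times))
})

test_that("consecutive states differ by one unit step in one coordinate", {
  tr <- simulateSsa(table1Params(), c(6, 1), tMaxYears = 0.02, seed = 7)
  d <- diff(tr@states)
  expect_true(all(rowSums(abs(d)) == 1))
  expect_true(all(tr@states >= 0))
  expect_true(all(diff(tr@times) > 0))
})

test_that("a pure birth-death limit reproduces the Poisson stationary mean", {
  ## feedback rates negligible: x is an immigration-death process with
  ## stationary law Poisson(k1/u1) = Poisson(5)
  p <- switchParameters(k1 = 0.5, V1 = 1e-9, V2 = 1e-9, u1 = 0.1, u2 = 0.1)
  tr <- simulateSsa(p, c(5, 0), tMaxYears = 0.5, seed = 3)
  hold <- diff(tr@times)
  burn <- tr@times[-length(tr@times)] > 5e3
  meanX <- sum(tr@states[-nrow(tr@states), "x"] * hold * burn) /
    sum(hold * burn)
  expect_equal(meanX, 5, tolerance = 0.05)
})

test_that("absorbing-mode runs stop at the boundary crossing", {
  p <- fastSwitchParams()
  tr <- simulateSsa(p, c(7, 1), tMaxYears = 5, seed = 9, mode = "absorbing",
                    B = 55)
  expect_true(tr@absorbed)
  final <- tr@states[nrow(tr@states), ]
  expect_gt(final[["x"]] + final[["y"]], 55)
  expect_true(all(rowSums(tr@states[-nrow(tr@states), , drop = FALSE]) <= 55))
})

test_that("reflecting occupancy matches the CME stationary law (chi-square)", {
  p <- table1Params()
  B <- 8L
  A <- reflectingGenerator(p, B)
  pi0 <- stationaryNullVector(A)
  tr <- simulateSsa(p, c(0, 0), tMaxYears = 4, seed = 1,
                    mode = "reflecting", B = B)
  ## sample decorrelated states: every ~2100 minutes >> relaxation time
  sampleT <- seq(0.2, 4, by = 0.004) * minutesPerYear()
  ix <- findInterval(sampleT, tr@times)
  sp <- enumerateStates(B)
  st <- tr@states[ix, , drop = FALSE]
  obs <- as.vector(table(factor(stateIndex(sp, st[, 1], st[, 2]),
                                levels = seq_len(nrow(sp@states)))))
  expected <- pi0 * length(sampleT)
  keep <- expected >= 5
  o2 <- c(obs[keep], sum(obs[!keep]))
  p2 <- c(pi0[keep], sum(pi0[!keep]))
  cs <- suppressWarnings(stats::chisq.test(o2, p = p2 / sum(p2)))
  expect_gt(cs$p.value, 0.01)
})

test_that("first-passage sampling is seeded, reproducible and exponential-like", {
  p <- fastSwitchParams()
  a <- estimateFirstPassage(p, nReps = 2, seed = 5)
  b <- estimateFirstPassage(p, nReps = 2, seed = 5)
  expect_identical(a$timesYears, b$timesYears)
  fp <- estimateFirstPassage(p, nReps = 60, seed = 12)
  expect_true(all(fp$timesYears > 0))
  ## MLE exponential rate is the reciprocal mean by construction
  expect_equal(fp$ratePerYear, 1 / fp$meanYears)
  ## and the empirical rate brackets the spectral decay rate within 3 SE
  s <- dominantMode(buildGenerator(p, 55))
  seRate <- fp$ratePerYear / sqrt(fp$nReps)
  expect_lt(abs(fp$ratePerYear - ratePerYear(s)), 3 * seRate)
  ## exponential shape: sd comparable to the mean
  expect_gt(fp$sdYears / fp$meanYears, 0.5)
  expect_lt(fp$sdYears / fp$meanYears, 2)
})

test_that("the time-weighted histogram is normalised and finds both modes", {
  p <- table1Params()
  trs <- list(
    simulateSsa(p, c(6, 1), tMaxYears = 0.3, seed = 21),
    simulateSsa(p, c(54, 50), tMaxYears = 0.3, seed = 22))
  h <- stationaryHistogram(trs, burnInYears = 0.02)
  expect_equal(sum(h$histogram$probability), 1, tolerance = 1e-12)
  expect_true(all(h$histogram$probability >= 0))
  ## one mode per macrostate, near the respective attractor
  expect_lt(abs(h$modes["off", "x"] - 5.5) + abs(h$modes["off", "y"] - 0.6),
            8)
  expect_gt(h$modes["on", "x"] + h$modes["on", "y"], 55)
  expect_error(stationaryHistogram(trs, burnInYears = 1), "burn-in")
})

test_that("accumulated occupancy is a reproducible proper distribution", {
  p <- table1Params()
  occ <- ssaOccupancy(p, seed = 77, nReps = 2, tMaxYears = 0.2,
                      burnInYears = 0.05, inits = rbind(c(6L, 1L)))
  occ2 <- ssaOccupancy(p, seed = 77, nReps = 2, tMaxYears = 0.2,
                       burnInYears = 0.05, inits = rbind(c(6L, 1L)))
  expect_identical(occ$occupancy, occ2$occupancy)
  expect_equal(sum(occ$occupancy), 1, tolerance = 1e-10)
  expect_equal(sum(occ$histogram$probability), 1, tolerance = 1e-10)
})
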