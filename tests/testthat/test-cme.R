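test_that("probability is conserved and absorption is monotone", {
  G <- buildGenerator(table1Params(), 12)
  sol <- solveCme(G, timesYears = c(0, 10^seq(-3, 1, length.out = 60)))
  expect_lt(max(abs(rowSums(sol@P) - 1)), 1e-8)
  expect_true(all(diff(pOn(sol)) >= 0))
  expect_true(all(sol@P >= 0))
  ## long-run absorption is certain
  longSol <- solveCme(G, timesYears = c(0, 50, 200))
  expect_gt(pOn(longSol)[3], 0.999)
})

test_that("initial conditions are honoured, including the absorbing mass", {
  G <- buildGenerator(table1Params(), 6)
  n <- nStates(G)
  ## point mass already on the absorbing state stays there
  p0 <- numeric(n)
  p0[n] <- 1
  sol <- solveCme(G, p0 = p0, timesYears = c(0, 0.5, 2))
  expect_equal(pOn(sol), rep(1, 3), tolerance = 1e-10)
  ## t = 0 returns the initial vector
  p1 <- numeric(n)
  p1[1] <- 1
  sol1 <- solveCme(G, p0 = p1, timesYears = c(0, 0.1))
  expect_equal(sol1@P[1, ], p1, tolerance = 1e-12)
  expect_error(solveCme(G, p0 = rep(1, n)), "probability")
})

test_that("the transient matches the matrix exponential on small spaces", {
  p <- table1Params()
  for (B in c(3, 12)) {
    G <- buildGenerator(p, B)
    n <- nStates(G)
    p0 <- numeric(n)
    p0[stateIndex(G@space, min(3, B), 0)] <- 1
    tys <- c(0.02, 0.4, 3)
    sol <- solveCme(G, p0 = p0, timesYears = c(0, tys))
    A <- as.matrix(fullGenerator(G))
    for (k in seq_along(tys)) {
      oracle <- as.vector(Matrix::expm(A * tys[k] * minutesPerYear()) %*% p0)
      expect_lt(max(abs(sol@P[k + 1, ] - oracle)), 1e-6)
    }
  }
})

test_that("the B = 1 absorption curve matches the hand-built 4-state model", {
  p <- table1Params()
  sol <- solveCme(buildGenerator(p, 1), p0 = c(1, 0, 0, 0),
                  timesYears = c(0, 0.001, 0.01, 0.1))
  Ah <- handGeneratorB1(p)
  for (k in 2:4) {
    tmin <- sol@times[k]
    oracle <- as.vector(Matrix::expm(Ah * tmin) %*% c(1, 0, 0, 0))
    expect_equal(pOn(sol)[k], oracle[4], tolerance = 1e-8)
  }
})

test_that("the exponential tail is consistent with the spectral rate", {
  p <- fastSwitchParams()    # half-life ~0.06 years: short grid suffices
  G <- buildGenerator(p, 55)
  s <- dominantMode(G)
  sol <- solveCme(G, timesYears = c(0, 10^seq(-4, log10(0.5),
                                              length.out = 200)))
  fit <- ponTailFit(sol, s)
  expect_gt(fit$c1, 0)
  expect_true(fit$ratio > 0.99 && fit$ratio < 1.01)
})

test_that("a single-state space decays as a pure exponential with c1 = 1", {
  G <- buildGenerator(table1Params(), 0)
  s <- dominantMode(G)
  sol <- solveCme(G, p0 = c(1, 0),
                  timesYears = 10^seq(-6, log10(3e-4), length.out = 80))
  fit <- ponTailFit(sol, s)
  expect_equal(fit$c1, 1, tolerance = 1e-6)
  expect_equal(fit$slopePerYear, lambda1(s) * minutesPerYear(),
               tolerance = 1e-6)
})

test_that("tail fitting demands coverage of at least three half-lives", {
  G <- buildGenerator(table1Params(), 12)
  s <- dominantMode(G)
  sol <- solveCme(G, timesYears = c(0, 0.001, 0.002))
  expect_error(ponTailFit(sol, s), "half-lives")
})
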