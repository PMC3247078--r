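test_that("the binomial pool law has the stated mean, variance and pmf", {
  cfg10 <- poolConfig(N0 = 10, Nd = 1)
  pd <- poolDistribution(0.5, cfg10, method = "exact")
  expect_equal(pd$pmf(5), 0.24609375)       # choose(10,5)/2^10
  expect_equal(pd$mean, 5)
  expect_equal(pd$var, 2.5)
  ## degenerate endpoints
  pd0 <- poolDistribution(0, poolConfig(), method = "exact")
  expect_equal(pd0$pmf(1e6), 1)
  expect_equal(pd0$mean, 1e6)
  ## the mean is N0 (1 - pOn) for arbitrary pOn
  for (pon in c(0.1, 0.37, 0.9)) {
    pd1 <- poolDistribution(pon, poolConfig())
    expect_equal(pd1$mean, 1e6 * (1 - pon))
    expect_equal(pd1$var, 1e6 * pon * (1 - pon))
  }
  expect_error(poolDistribution(1.2, poolConfig()), "probability")
  expect_error(poolConfig(N0 = 10, Nd = 20), "N0 >= Nd")
})

test_that("exact and corrected-normal binomial CDFs agree to 1e-4", {
  ## across the depletion crossing region of the nominal pool
  for (q in 10^seq(-4, -2.5, length.out = 30)) {
    pe <- poolDistribution(1 - q, poolConfig(), method = "exact")
    pn <- poolDistribution(1 - q, poolConfig(), method = "normal")
    expect_lt(abs(pe$cdf(1000) - pn$cdf(1000)), 1e-4)
  }
})

test_that("depletion statistics match a Monte-Carlo order-statistic oracle", {
  ## analytic exponential switching curve; the oracle draws each cell's
  ## switching time and takes the (N0 - Nd)-th order statistic
  r <- 0.5
  N0 <- 2000L
  Nd <- 50L
  curve <- analyticPonCurve(r, tMax = 16)
  st <- depletionTimeStats(curve, poolConfig(N0 = N0, Nd = Nd),
                           method = "exact")
  set.seed(101)
  tdMC <- replicate(400, sort(stats::rexp(N0, r))[N0 - Nd])
  seMean <- sd(tdMC) / sqrt(length(tdMC))
  expect_lt(abs(st$meanYears - mean(tdMC)), 4 * seMean)
  expect_lt(abs(st$sdYears - sd(tdMC)) / sd(tdMC), 0.2)
  expect_equal(st$mass, 1, tolerance = 1e-3)
  expect_true(all(diff(st$grid$cdf) >= 0))
})

test_that("an already-depleted pool has depletion time zero", {
  curve <- analyticPonCurve(1, tMax = 20)
  st <- depletionTimeStats(curve, poolConfig(N0 = 1000, Nd = 1000))
  expect_equal(st$meanYears, 0)
  expect_equal(st$grid$cdf[1], 1)
})

test_that("a too-short switching curve is rejected with advice", {
  curve <- analyticPonCurve(0.5, tMax = 1)
  expect_error(depletionTimeStats(curve, poolConfig(N0 = 1e4, Nd = 10)),
               "extend the time horizon")
})

test_that("the log-ratio approximation has its closed-form values", {
  ## a 5.9-year half-life and a thousandfold pool reduction give ~58.8 y
  lam <- -log(2) / 5.9
  expect_equal(expectedDepletionTimeApprox(lam, poolConfig()),
               log(1000) * 5.9 / log(2), tolerance = 1e-12)
  ## N0 = e * Nd collapses to 1/|lambda1|
  expect_equal(expectedDepletionTimeApprox(-0.25,
                 poolConfig(N0 = round(exp(1) * 1e5), Nd = 1e5)),
               4, tolerance = 1e-4)
  expect_error(expectedDepletionTimeApprox(0.3, poolConfig()), "negative")
})

test_that("pool statistics of the nominal switch are internally consistent", {
  ## exact and corrected-normal paths agree on the depletion CDF and the
  ## density integrates to one
  G <- buildGenerator(table1Params(), 55)
  sol <- solveCme(G)
  se <- depletionTimeStats(sol, method = "exact")
  sn <- depletionTimeStats(sol, method = "normal")
  expect_lt(max(abs(se$grid$cdf - sn$grid$cdf)), 1e-4)
  expect_equal(se$mass, 1, tolerance = 1e-3)
  ## the depletion peak is very sharp: sd well below 1% of the mean
  expect_lt(se$sdYears / se$meanYears, 0.01)
})
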