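test_that("rate laws evaluate to the expected values at reference states", {
  p <- table1Params()
  r0 <- evaluateRates(0, 0, p)
  expect_equal(unname(r0["v1"]), 0.055)
  expect_equal(unname(r0[c("v2", "v3", "v4", "v5")]), rep(0, 4))
  ## y at its half-saturation constant activates half the maximal rate
  expect_equal(unname(evaluateRates(0, 25, p)["v2"]), 0.55 / 2)
  expect_equal(unname(evaluateRates(10, 0, p)["v3"]), 0.10)
  expect_true(all(is.finite(evaluateRates(120, 300, p))) &&
                all(evaluateRates(120, 300, p) >= 0))
})

test_that("rate evaluation rejects invalid states and parameters", {
  expect_error(evaluateRates(-1, 0, table1Params()), "non-negative")
  expect_error(switchParameters(k1 = -0.1), "strictly positive")
  expect_error(switchParameters(u1 = 0), "strictly positive")
  expect_error(updateParameters(table1Params(), bogus = 1), "unknown")
})

test_that("nominal parameters give three equilibria with saddle in between", {
  eq <- findEquilibria(table1Params())
  expect_equal(nrow(eq), 3L)
  expect_equal(eq$stability, c("stable", "saddle", "stable"))
  ## sorted by x + y and saddle eigenvalues of mixed sign
  expect_true(all(diff(eq$x + eq$y) > 0))
  expect_true(eq$eig_re_1[2] > 0 && eq$eig_re_2[2] < 0)
  expect_false(any(eq$degenerate))
  ## low state: x near k1/u1 pushed up slightly by weak feedback, y small
  expect_equal(eq$x[1], 5.500686, tolerance = 1e-5)
  expect_equal(eq$y[1], 0.5796843, tolerance = 1e-5)
})

test_that("equilibria agree with a brute-force nullcline grid scan", {
  for (f in c(1, 1.05)) {
    p <- scaleParameters(table1Params(), "V", f)
    eq <- findEquilibria(p)
    oracle <- nullclineScanOracle(p, resolution = 0.05)
    expect_equal(nrow(eq), oracle$count)
    expect_true(all(abs(sort(eq$x) - sort(oracle$x)) < 0.1))
  }
})

test_that("raising the basal rate tenfold destroys bistability", {
  p <- updateParameters(table1Params(), k1 = 0.55)
  oracle <- nullclineScanOracle(p)
  expect_equal(oracle$count, 1L)
  eq <- findEquilibria(p)
  expect_equal(nrow(eq), 1L)
  expect_equal(eq$stability, "stable")
})

test_that("ODE trajectories stay non-negative and settle on I or III", {
  p <- table1Params()
  eq <- findEquilibria(p)
  lo <- as.numeric(eq[1, c("x", "y")])
  sad <- as.numeric(eq[2, c("x", "y")])
  hi <- as.numeric(eq[3, c("x", "y")])
  ## starting exactly at a fixed point stays there
  tr <- simulateSwitchOde(p, lo, c(0, 1e4, 1e5))
  expect_equal(unlist(tr[3, c("x", "y")], use.names = FALSE), lo,
               tolerance = 1e-6)
  ## from the origin: monotone approach to the low attractor
  tr0 <- simulateSwitchOde(p, c(0, 0), seq(0, 5e4, length.out = 200))
  expect_true(all(diff(tr0$x) > -1e-6) && all(diff(tr0$y) > -1e-6))
  expect_equal(unlist(tr0[200, c("x", "y")], use.names = FALSE), lo,
               tolerance = 1e-4)
  ## random initial conditions never settle on the saddle
  set.seed(11)
  ends <- t(replicate(100, {
    init <- runif(2, 0, 80)
    unlist(simulateSwitchOde(p, init, c(0, 1e5, 1e6))[3, c("x", "y")])
  }))
  expect_true(all(ends >= -1e-9))
  dLo <- sqrt((ends[, 1] - lo[1])^2 + (ends[, 2] - lo[2])^2)
  dHi <- sqrt((ends[, 1] - hi[1])^2 + (ends[, 2] - hi[2])^2)
  dSad <- sqrt((ends[, 1] - sad[1])^2 + (ends[, 2] - sad[2])^2)
  expect_true(all(pmin(dLo, dHi) < 0.01))
  expect_true(all(dSad > 1))
})

test_that("macrostate classification includes the boundary in the on set", {
  expect_equal(classifyMacrostate(0, 0), "off")
  expect_equal(classifyMacrostate(30, 30), "on")
  expect_equal(classifyMacrostate(27, 28), "on")   # x + y = L exactly
  expect_equal(classifyMacrostate(27, 27), "off")
  expect_equal(classifyMacrostate(c(0, 30), c(0, 30), L = 55),
               c("off", "on"))
  expect_error(classifyMacrostate(1, 1, L = 0), "positive integer")
  expect_error(classifyMacrostate(-1, 0), "non-negative")
})

test_that("switch parameter config files round-trip with exact keys", {
  f <- tempfile(fileext = ".yaml")
  writeSwitchConfig(scaleParameters(table1Params(), "u", 1.1), L = 60, f)
  got <- readSwitchConfig(f)
  expect_equal(got$L, 60L)
  expect_equal(parameterValues(got$params)[["u1"]], 0.011)
  expect_equal(parameterValues(got$params)[["k1"]], 0.055)
  ## unknown keys are rejected with the key named
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(k1 = 0.05, frobnicate = 1), bad)
  expect_error(readSwitchConfig(bad), "frobnicate")
})
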