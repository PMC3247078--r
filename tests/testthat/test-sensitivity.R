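test_that("single-cell scan entries recompute the eigenvalue formula", {
  ## on a reduced space, each entry must equal the direct computation
  sc <- runScan("single_cell", parameters = c("k1", "u"),
                factors = c(0.9, 1.1), B = 20)
  expect_equal(nrow(sc), 4L)
  for (i in seq_len(nrow(sc))) {
    sw <- scaleParameters(switchParameters(), sc$parameter[i], sc$factor[i])
    lam <- lambda1(dominantMode(buildGenerator(sw, 20))) * minutesPerYear()
    expect_equal(sc$Td_years[i], log(1000) / abs(lam), tolerance = 1e-9)
  }
  expect_true(all(sc$bistable))
  expect_true(all(is.finite(sc$Td_years) & sc$Td_years > 0))
})

test_that("an identity factor reproduces the unperturbed model", {
  sc <- runScan("single_cell", parameters = "k1", factors = 1, B = 20)
  lam <- lambda1(dominantMode(buildGenerator(switchParameters(), 20))) *
    minutesPerYear()
  expect_equal(sc$Td_years, log(1000) / abs(lam), tolerance = 1e-12)
})

test_that("losing bistability is flagged rather than silently reported", {
  sc <- runScan("single_cell", parameters = "k1", factors = c(1, 10),
                B = 20)
  expect_true(sc$bistable[sc$factor == 1])
  expect_false(sc$bistable[sc$factor == 10])
})

test_that("non-integer Hill exponents are scanned continuously", {
  sc <- runScan("single_cell", parameters = "h", factors = c(0.95, 1.05),
                B = 20)
  expect_true(all(is.finite(sc$Td_years)))
  ## steeper Hill curves slow the switching
  expect_lt(sc$Td_years[1], sc$Td_years[2])
})

test_that("population-model scans censor slow entries at the cap", {
  sc <- runScan("population", parameters = "u", factors = c(1, 2),
                B = 18, gridPoints = 8, capYears = 30)
  expect_false(sc$censored[1])
  expect_true(sc$censored[2])
  expect_true(is.na(sc$Td_years[2]))
  m <- scanMatrix(sc)
  expect_equal(m["u", "2"], ">30")
})

test_that("unknown scan parameters are rejected per model", {
  expect_error(runScan("single_cell", parameters = "Kn"), "unknown")
  expect_error(runScan("population", parameters = "bogus"), "unknown")
  expect_error(runScan("single_cell", factors = c(-1, 1)), "positive")
})
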