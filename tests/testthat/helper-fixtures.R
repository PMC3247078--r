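## shared fixtures and independent oracles

table1Params <- function() switchParameters()

## faster-switching set used where Monte-Carlo absorption must be cheap:
## degradation scaled down weakens the barrier by two orders of magnitude
fastSwitchParams <- function() scaleParameters(switchParameters(), "u", 0.8)

## brute-force nullcline-intersection scan: counts (and locates) sign
## changes of the y-nullcline-minus-x-nullcline mismatch on a dense x grid
nullclineScanOracle <- function(params, resolution = 0.05) {
  p <- parameterValues(params)
  xmax <- (p[["k1"]] + p[["V1"]]) / p[["u1"]] * 1.05
  xs <- seq(0, xmax, by = resolution)
  ynull <- p[["V2"]] * xs^p[["h"]] / (p[["M2"]]^p[["h"]] + xs^p[["h"]]) /
    p[["u2"]]
  mism <- p[["k1"]] +
    p[["V1"]] * ynull^p[["h"]] / (p[["M1"]]^p[["h"]] + ynull^p[["h"]]) -
    p[["u1"]] * xs
  sgn <- sign(mism)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  list(count = length(idx),
       x = (xs[idx] + xs[idx + 1]) / 2,
       y = ynull[idx])
}

## dense reflecting-wall generator over x + y <= B, built by independent
## hand enumeration of the four reaction channels; its null vector is the
## stationary law of the truncated (non-absorbing) network
reflectingGenerator <- function(params, B) {
  sp <- enumerateStates(B)
  st <- sp@states
  n <- nrow(st)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    v <- evaluateRates(st[j, 1], st[j, 2], params)
    moves <- list(c(1, 0, v[["v1"]] + v[["v2"]]),
                  c(-1, 0, v[["v3"]]),
                  c(0, 1, v[["v4"]]),
                  c(0, -1, v[["v5"]]))
    for (m in moves) {
      nx <- st[j, 1] + m[1]
      ny <- st[j, 2] + m[2]
      if (nx < 0 || ny < 0 || nx + ny > B) next
      i <- stateIndex(sp, nx, ny)
      A[i, j] <- A[i, j] + m[3]
      A[j, j] <- A[j, j] - m[3]
    }
  }
  A
}

stationaryNullVector <- function(A) {
  n <- nrow(A)
  pi0 <- solve(rbind(A[-n, ], 1), c(rep(0, n - 1), 1))
  pmax(pi0, 0) / sum(pmax(pi0, 0))
}

## hand-enumerated 4x4 generator of the B = 1 absorbing model:
## states (0,0), (1,0), (0,1), on
handGeneratorB1 <- function(params) {
  p <- parameterValues(params)
  v2at1 <- p[["V1"]] / (p[["M1"]]^p[["h"]] + 1)
  v4at1 <- p[["V2"]] / (p[["M2"]]^p[["h"]] + 1)
  k1 <- p[["k1"]]
  A <- matrix(0, 4, 4)
  A[2, 1] <- k1                       # (0,0) -> (1,0)
  A[1, 2] <- p[["u1"]]                # (1,0) -> (0,0)
  A[4, 2] <- k1 + v4at1               # (1,0) -> on (both productions leave)
  A[1, 3] <- p[["u2"]]                # (0,1) -> (0,0)
  A[4, 3] <- k1 + v2at1               # (0,1) -> on
  diag(A) <- -colSums(A)
  A
}

## analytic switching curve p_on(t) = 1 - exp(-r t) on a time grid,
## in the data-frame form accepted by depletionTimeStats
analyticPonCurve <- function(ratePerYear, tMax, n = 4001L) {
  tt <- seq(0, tMax, length.out = n)
  data.frame(time_years = tt, p_on = 1 - exp(-ratePerYear * tt))
}
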