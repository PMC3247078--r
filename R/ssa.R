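## per-realisation seed: mixes the replicate index into the base seed so
## replicate sets are reproducible and order-independent
.repSeed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647L)
}

#' Exact Gillespie simulation of the switch network
#'
#' Simulates the stochastic reaction network with the direct method:
#' exponential waiting times at the total propensity, reaction channel
#' drawn proportionally to its propensity.  Three modes are available:
#' `"free"` (the full network on the non-negative quadrant, as used for
#' stationary histograms), `"absorbing"` (the run stops when x + y first
#' exceeds `B`, matching the absorbing Markov model), and `"reflecting"`
#' (production events that would leave x + y <= `B` cannot fire; the
#' truncated network used for stationary cross-checks against the CME).
#'
#' @param params A [SwitchParameters-class] object.
#' @param init Integer initial state `c(x, y)`.  Default is the integer
#'   state nearest the low deterministic equilibrium.
#' @param tMaxYears Simulated time horizon in years.
#' @param seed Integer seed; a fixed seed reproduces the event sequence
#'   bit for bit.
#' @param mode `"free"`, `"absorbing"` or `"reflecting"`.
#' @param B Boundary for the absorbing/reflecting modes (default 55).
#' @param maxEvents Safety cap on the number of reaction events.
#' @return An [SsaTrajectory-class] object.
#' @export
#' @examples
#' tr <- simulateSsa(switchParameters(), c(6, 1), tMaxYears = 0.01, seed = 1)
#' tr
simulateSsa <- function(params, init = NULL, tMaxYears, seed,
                        mode = c("free", "absorbing", "reflecting"),
                        B = 55L, maxEvents = 1e8) {
  stopifnot(is(params, "SwitchParameters"))
  validObject(params)
  mode <- match.arg(mode)
  if (tMaxYears <= 0) stop("tMaxYears must be positive")
  if (is.null(init)) init <- .lowEquilibriumState(params)
  init <- as.integer(init)
  if (length(init) != 2L || any(init < 0L))
    stop("init must be two non-negative integers")
  modeCode <- match(mode, c("free", "absorbing", "reflecting")) - 1L
  set.seed(seed)
  res <- .ssaRun(parameterValues(params), init[1], init[2],
                 tMaxYears * .MINUTES_PER_YEAR, modeCode, as.integer(B),
                 maxEvents)
  new("SsaTrajectory",
      times = res$time,
      states = cbind(x = as.integer(res$x), y = as.integer(res$y)),
      seed = as.integer(seed), mode = mode,
      boundary = if (mode == "free") NA_integer_ else as.integer(B),
      absorbed = res$absorbed, tAbs = res$t_abs)
}

.lowEquilibriumState <- function(params) {
  eq <- findEquilibria(params)
  eq <- eq[eq$stability == "stable", , drop = FALSE]
  if (!nrow(eq)) stop("no stable equilibrium to start from")
  c(round(eq$x[1]), round(eq$y[1]))
}

setMethod("show", "SsaTrajectory", function(object) {
  cat(sprintf(
    "SsaTrajectory: %d events over %.4g years (mode %s, seed %d)\n",
    length(object@times) - 1L, max(object@times) / .MINUTES_PER_YEAR,
    object@mode, object@seed))
  if (isTRUE(object@absorbed))
    cat(sprintf("  absorbed at %.4g years\n",
                object@tAbs / .MINUTES_PER_YEAR))
  invisible(NULL)
})

#' @describeIn simulateSsa Data-frame view (time_min, x, y).
#' @param x An `SsaTrajectory` object.
#' @param row.names,optional,... Ignored (S3 compatibility).
#' @export
setMethod("as.data.frame", "SsaTrajectory",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time_min = x@times, x = x@states[, "x"], y = x@states[, "y"])
})

#' Time-weighted stationary histogram from stored trajectories
#'
#' Accumulates, over a list of free-running trajectories, the fraction of
#' simulated time spent in each microstate after discarding a burn-in, and
#' locates the two local modes: the maximum-occupancy state in the off
#' region (x + y < L) and in the on region (x + y >= L).
#'
#' @param trajs An [SsaTrajectory-class] or a list of them.
#' @param burnInYears Transient to discard from each trajectory (years).
#' @param L Macrostate threshold separating the two peaks (default 55).
#' @return A list with `histogram` (data frame `x`, `y`, `probability`,
#'   occupancy > 0 only) and `modes` (data frame with rows `off`, `on`).
#' @export
stationaryHistogram <- function(trajs, burnInYears = 0, L = 55L) {
  if (is(trajs, "SsaTrajectory")) trajs <- list(trajs)
  stopifnot(all(vapply(trajs, is, logical(1), "SsaTrajectory")))
  burn <- burnInYears * .MINUTES_PER_YEAR
  acc <- new.env(parent = emptyenv())
  total <- 0
  for (tr in trajs) {
    tt <- tr@times
    tEnd <- max(tt)
    if (burn >= tEnd)
      stop("burn-in (", burnInYears, " years) is not shorter than the ",
           "trajectory")
    hold <- diff(c(tt, tEnd))       # holding time of each visited state
    lo <- pmax(tt, burn)
    w <- pmax(pmin(tt + hold, tEnd) - lo, 0)
    keep <- w > 0
    key <- paste(tr@states[keep, 1], tr@states[keep, 2])
    wk <- tapply(w[keep], key, sum)
    for (k in names(wk)) {
      acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + wk[[k]]
    }
    total <- total + sum(w)
  }
  keys <- ls(acc)
  xy <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  hist <- data.frame(x = as.integer(xy[, 1]), y = as.integer(xy[, 2]),
                     probability = vapply(keys, function(k) acc[[k]],
                                          numeric(1)) / total)
  rownames(hist) <- NULL
  hist <- hist[order(hist$x, hist$y), ]
  list(histogram = hist, modes = .occupancyModes(hist, L))
}

.occupancyModes <- function(hist, L) {
  s <- hist$x + hist$y
  pick <- function(sel) {
    if (!any(sel)) return(data.frame(x = NA, y = NA, probability = NA))
    hist[sel, ][which.max(hist$probability[sel]), ]
  }
  out <- rbind(pick(s < L), pick(s >= L))
  rownames(out) <- c("off", "on")
  out
}

#' Stationary occupancy via accumulated long runs
#'
#' Runs `nReps` independent free realisations and accumulates the
#' time-weighted occupancy in compiled code, so the stationary bimodal
#' histogram can be estimated without storing events.  The reduced
#' protocol (default) runs 20 realisations of 3 simulated years with a
#' 0.1-year burn-in, starting half the realisations at each deterministic
#' stable equilibrium so both peaks are populated within the short
#' horizon; the `"full"` protocol reproduces the long-run setting (500
#' realisations of 300 years, 50-year burn-in, all started at the low
#' state) and takes correspondingly long.
#'
#' @param params A [SwitchParameters-class] object.
#' @param seed Integer base seed; each realisation mixes in its index.
#' @param protocol `"reduced"` (default) or `"full"`.
#' @param nReps,tMaxYears,burnInYears Override the protocol's settings.
#' @param inits Optional 2-column matrix of initial states recycled over
#'   realisations; defaults to alternating the two stable equilibria
#'   (reduced) or the low equilibrium only (full).
#' @param cap Largest coordinate tracked separately (default 150).
#' @param L Macrostate threshold for mode reporting (default 55).
#' @return A list with `occupancy` (matrix \[x+1, y+1\] of probabilities),
#'   `histogram` and `modes` as in [stationaryHistogram()], and the
#'   protocol settings used.
#' @export
ssaOccupancy <- function(params, seed, protocol = c("reduced", "full"),
                         nReps = NULL, tMaxYears = NULL,
                         burnInYears = NULL, inits = NULL,
                         cap = 150L, L = 55L) {
  stopifnot(is(params, "SwitchParameters"))
  protocol <- match.arg(protocol)
  if (protocol == "reduced") {
    if (is.null(nReps)) nReps <- 20L
    if (is.null(tMaxYears)) tMaxYears <- 3
    if (is.null(burnInYears)) burnInYears <- 0.1
  } else {
    if (is.null(nReps)) nReps <- 500L
    if (is.null(tMaxYears)) tMaxYears <- 300
    if (is.null(burnInYears)) burnInYears <- 50
  }
  if (burnInYears >= tMaxYears)
    stop("burn-in must be shorter than the simulated time")
  if (is.null(inits)) {
    eq <- findEquilibria(params)
    st <- eq[eq$stability == "stable", , drop = FALSE]
    inits <- if (protocol == "reduced" && nrow(st) >= 2) {
      rbind(round(c(st$x[1], st$y[1])),
            round(c(st$x[nrow(st)], st$y[nrow(st)])))
    } else {
      rbind(round(c(st$x[1], st$y[1])))
    }
  }
  inits <- matrix(as.integer(inits), ncol = 2)
  pv <- parameterValues(params)
  occ <- matrix(0, cap + 1, cap + 1)
  for (i in seq_len(nReps)) {
    set.seed(.repSeed(seed, i))
    ini <- inits[(i - 1L) %% nrow(inits) + 1L, ]
    occ <- occ + .ssaOccupancy(pv, ini[1], ini[2],
                               tMaxYears * .MINUTES_PER_YEAR,
                               burnInYears * .MINUTES_PER_YEAR,
                               as.integer(cap))
  }
  occ <- occ / sum(occ)
  nz <- which(occ > 0, arr.ind = TRUE)
  hist <- data.frame(x = nz[, 1] - 1L, y = nz[, 2] - 1L,
                     probability = occ[nz])
  hist <- hist[order(hist$x, hist$y), ]
  rownames(hist) <- NULL
  list(occupancy = occ, histogram = hist, modes = .occupancyModes(hist, L),
       protocol = protocol, nReps = nReps, tMaxYears = tMaxYears,
       burnInYears = burnInYears)
}

#' Monte-Carlo first-passage times to the on macrostate
#'
#' Simulates `nReps` independent absorbing-mode realisations and records
#' the time at which x + y first exceeds `B`.  Because switching is a rare
#' exit over a quasi-stationary barrier, the first-passage law is close to
#' exponential with rate |lambda1|; the maximum-likelihood exponential
#' rate is 1/mean.
#'
#' @param params A [SwitchParameters-class] object.
#' @param B Absorbing boundary (default 55).
#' @param nReps Number of realisations (at least 2).
#' @param seed Integer base seed; realisation i mixes i into the seed, so
#'   the sample is reproducible and independent of evaluation order.
#' @param init Initial state; default the integer state nearest the low
#'   equilibrium.
#' @param tMaxYears Per-realisation cap (default 1e4 years); realisations
#'   that do not absorb are dropped with a warning.
#' @return A list with `timesYears`, `meanYears`, `sdYears`, `ratePerYear`
#'   (= 1/mean), `seYears` (standard error of the mean) and `nReps`.
#' @export
estimateFirstPassage <- function(params, B = 55L, nReps, seed,
                                 init = NULL, tMaxYears = 1e4) {
  stopifnot(is(params, "SwitchParameters"))
  if (nReps < 2L) stop("nReps must be at least 2")
  if (is.null(init)) init <- .lowEquilibriumState(params)
  init <- as.integer(init)
  pv <- parameterValues(params)
  tm <- vapply(seq_len(nReps), function(i) {
    set.seed(.repSeed(seed, i))
    .ssaFirstPassage(pv, init[1], init[2], as.integer(B),
                     tMaxYears * .MINUTES_PER_YEAR)
  }, numeric(1))
  if (anyNA(tm)) {
    warning(sum(is.na(tm)), " realisation(s) did not absorb within ",
            tMaxYears, " years and were dropped")
    tm <- tm[!is.na(tm)]
  }
  yrs <- tm / .MINUTES_PER_YEAR
  list(timesYears = yrs, meanYears = mean(yrs), sdYears = sd(yrs),
       ratePerYear = 1 / mean(yrs),
       seYears = sd(yrs) / sqrt(length(yrs)), nReps = length(yrs),
       boundary = as.integer(B))
}
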