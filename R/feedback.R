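#' Construct feedback-population parameters
#'
#' Creates a [FeedbackParameters-class] with the nominal population-model
#' values: k1Max = 0.06/min, Kn = 8.2e4 follicles, tau = 0.4 years, the
#' switch constants shared with the single-cell model (V1 = V2 = 0.55,
#' M1 = M2 = 25, h = 3, u1 = u2 = 0.01) and N0 = 1e6 primordial follicles.
#'
#' @param k1Max Maximal basal production rate of the switch (per minute).
#' @param Kn Half-suppression follicle number: with n2 = Kn growing
#'   follicles the basal rate is halved.
#' @param tauYears Residence time in the growing compartment (years).
#' @param V1,V2,M1,M2,h,u1,u2 Switch constants, see [switchParameters()].
#' @param N0 Initial primordial follicle count.
#' @return A validated [FeedbackParameters-class] object.
#' @export
#' @examples
#' feedbackParameters()
feedbackParameters <- function(k1Max = 0.06, Kn = 8.2e4, tauYears = 0.4,
                               V1 = 0.55, V2 = 0.55, M1 = 25, M2 = 25,
                               h = 3, u1 = 0.01, u2 = 0.01, N0 = 1e6) {
  sw <- switchParameters(k1 = k1Max, V1 = V1, V2 = V2, M1 = M1, M2 = M2,
                         h = h, u1 = u1, u2 = u2)
  new("FeedbackParameters", k1Max = k1Max, Kn = Kn, tauYears = tauYears,
      switch = sw, N0 = N0)
}

#' @describeIn feedbackParameters Named vector of all parameters.
#' @param object A `FeedbackParameters` object.
#' @export
setMethod("parameterValues", "FeedbackParameters", function(object) {
  sw <- parameterValues(object@switch)
  c(k1_max = object@k1Max, Kn = object@Kn, tau_years = object@tauYears,
    sw[names(sw) != "k1"], N0 = object@N0)
})

setMethod("show", "FeedbackParameters", function(object) {
  cat("FeedbackParameters (delayed-suppression population model)\n")
  cat(sprintf("  k1_max = %g /min, Kn = %g follicles, tau = %g years, N0 = %g\n",
              object@k1Max, object@Kn, object@tauYears, object@N0))
  cat("  switch: ")
  show(object@switch)
  invisible(NULL)
})

#' Suppressed basal production rate
#'
#' Growing follicles lower the basal production rate of the switch:
#' k1(n2) = k1Max Kn / (Kn + n2), a strictly decreasing hyperbolic
#' suppression halved at n2 = Kn.
#'
#' @param n2 Number of growing follicles (vectorised, non-negative).
#' @param params A [FeedbackParameters-class] object.
#' @return Rate per minute.
#' @export
#' @examples
#' k1OfN2(8.2e4, feedbackParameters())   # half of k1Max
k1OfN2 <- function(n2, params) {
  stopifnot(is(params, "FeedbackParameters"))
  if (any(n2 < 0)) stop("n2 must be non-negative")
  params@k1Max * params@Kn / (params@Kn + n2)
}

#' Precompute the switching-rate map lambda1(n2)
#'
#' For each grid value of the growing-follicle number n2, rebuilds the
#' absorbing generator with k1 = k1(n2) and extracts the dominant
#' eigenvalue.  The grid spans \[0, N0\] (zero plus log-spaced points);
#' intermediate values are interpolated with a monotone (Hyman) spline of
#' log|lambda1| against log(1 + n2).  |lambda1| spans many orders of
#' magnitude along the grid; values below `rateFloorPerYear` are clamped
#' to the floor — there the switching dynamics are frozen on any
#' physiological time scale and the numerical eigenvalue is below the
#' resolution of the eigensolve.  A non-monotone raw grid beyond that
#' floor triggers a warning (it indicates a too-coarse grid).
#'
#' @param params A [FeedbackParameters-class] object.
#' @param B State-space boundary for the eigensolves (default 55).
#' @param gridPoints Number of log-spaced grid points in addition to
#'   n2 = 0 (default 40).
#' @param rateFloorPerYear Clamp for |lambda1| (default 1e-10 per year).
#' @return A [RateMap-class] object.
#' @export
buildRateMap <- function(params, B = 55L, gridPoints = 40L,
                         rateFloorPerYear = 1e-10) {
  stopifnot(is(params, "FeedbackParameters"))
  n2grid <- c(0, 10^seq(0, log10(params@N0), length.out = gridPoints))
  space <- enumerateStates(B)
  lamYear <- vapply(n2grid, function(n2) {
    sw <- updateParameters(params@switch, k1 = k1OfN2(n2, params))
    lambda1(dominantMode(buildGenerator(sw, space))) * .MINUTES_PER_YEAR
  }, numeric(1))
  rate <- pmax(abs(lamYear), rateFloorPerYear)
  mono <- cummin(rate)
  if (any(rate > mono * (1 + 1e-6) & rate > 2 * rateFloorPerYear))
    warning("computed |lambda1| is not monotone along the n2 grid; ",
            "the grid may be too coarse or the eigensolves inaccurate")
  rate <- mono * (1 - 1e-12 * seq_along(mono))  # strictify for the spline
  sp <- splinefun(log1p(n2grid), log(rate), method = "hyman")
  interp <- function(n2) -exp(sp(log1p(pmax(n2, 0))))
  new("RateMap", n2Grid = n2grid, lambda1PerYear = -rate,
      boundary = as.integer(B), params = params, interp = interp)
}

#' Interpolated switching rate at a follicle number
#'
#' @param map A [RateMap-class] object.
#' @param n2 Growing-follicle numbers (vectorised).
#' @return lambda1(n2) in per-year units (negative).
#' @export
lambda1At <- function(map, n2) {
  stopifnot(is(map, "RateMap"))
  map@interp(n2)
}

#' @describeIn buildRateMap Grid values of lambda1 (per year).
#' @param object A `RateMap` object.
#' @param ... Ignored.
#' @export
setMethod("lambda1", "RateMap", function(object, ...) object@lambda1PerYear)

setMethod("boundary", "RateMap", function(object) object@boundary)

setMethod("show", "RateMap", function(object) {
  cat(sprintf(
    "RateMap: lambda1(n2) on %d grid points over [0, %g] (boundary %d)\n",
    length(object@n2Grid), max(object@n2Grid), object@boundary))
  cat(sprintf("  |lambda1| from %.4g down to %.4g per year\n",
              abs(object@lambda1PerYear[1]),
              abs(object@lambda1PerYear[length(object@lambda1PerYear)])))
  invisible(NULL)
})

#' Simulate the delayed-feedback population model
#'
#' Integrates the two-compartment delay system: primordial follicles n1
#' initiate growth at the state-dependent rate |lambda1(n2)| and growing
#' follicles n2 leave the pool exactly tau years after entering (a pure
#' conveyor).  The method of steps uses a fixed step h dividing tau, with
#' a Heun predictor-corrector; the growing compartment is carried as the
#' sliding-window quadrature of the stored initiation-rate history
#' (n2(t) = cumulative inflow over (t - tau, t\]), which keeps the mass
#' balance N0 = n1 + n2 + cumulative outflow exact at every node and n2
#' non-negative by construction.  Before t = 0 nothing has initiated
#' (n1 = N0, n2 = 0 on \[-tau, 0\]), so there is no outflow before
#' t = tau.  With tau = 0 the in- and outflow cancel, n2 stays 0 and n1
#' decays as a pure exponential; that limit is returned analytically.
#'
#' @param params A [FeedbackParameters-class] object.
#' @param map Optional precomputed [RateMap-class]; built with defaults
#'   when missing.
#' @param tEndYears Integration horizon in years (default 100).
#' @param stepYears Fixed step h; must not exceed tau (default tau/20,
#'   rounded so that tau is an integer number of steps).
#' @param stopBelow Optional early-exit threshold on n1 (e.g. half the
#'   depletion number); the trajectory then ends shortly after crossing.
#' @param ... Passed to [buildRateMap()] when `map` is missing.
#' @return A [PopulationTrajectory-class] object.
#' @export
simulateDde <- function(params, map = NULL, tEndYears = 100,
                        stepYears = NULL, stopBelow = NULL, ...) {
  stopifnot(is(params, "FeedbackParameters"))
  if (tEndYears <= 0) stop("tEndYears must be positive")
  tau <- params@tauYears
  N0 <- params@N0
  if (tau == 0) {
    if (is.null(map)) map <- buildRateMap(params, ...)
    r0 <- abs(lambda1At(map, 0))
    tt <- seq(0, tEndYears, length.out = 2001L)
    n1 <- N0 * exp(-r0 * tt)
    return(new("PopulationTrajectory", times = tt, n1 = n1,
               n2 = numeric(length(tt)),
               lambda1PerYear = rep(-r0, length(tt)),
               outflowCum = N0 - n1, N0 = N0))
  }
  if (is.null(stepYears)) stepYears <- tau / 20
  if (stepYears > tau)
    stop("step size (", stepYears, " y) exceeds the delay tau (", tau,
         " y); the delayed term cannot be resolved")
  K <- max(1L, as.integer(round(tau / stepYears)))
  h <- tau / K                      # delay = exactly K steps
  if (is.null(map)) map <- buildRateMap(params, ...)
  rate <- function(n2) abs(lambda1At(map, n2))
  nSteps <- ceiling(tEndYears / h)
  n1 <- n2 <- a <- I <- numeric(nSteps + 1L)
  n1[1] <- N0
  a[1] <- rate(0) * N0              # initiation (inflow) rate at nodes
  last <- nSteps
  for (i in seq_len(nSteps)) {
    Ilag <- if (i + 1L - K >= 1L) I[i + 1L - K] else 0
    ## predictor (Euler)
    n1p <- n1[i] - h * a[i]
    ap <- rate(I[i] + h * a[i] - Ilag) * max(n1p, 0)
    ## corrector (trapezoid); I is the cumulative inflow integral
    n1[i + 1L] <- n1[i] - h / 2 * (a[i] + ap)
    I[i + 1L] <- I[i] + h / 2 * (a[i] + ap)
    n2[i + 1L] <- I[i + 1L] - Ilag
    a[i + 1L] <- rate(n2[i + 1L]) * n1[i + 1L]
    if (!is.null(stopBelow) && n1[i + 1L] <= stopBelow) { last <- i; break }
  }
  sel <- seq_len(last + 1L)
  tt <- (sel - 1L) * h
  outCum <- vapply(sel, function(i) if (i - K >= 1L) I[i - K] else 0,
                   numeric(1))
  new("PopulationTrajectory", times = tt, n1 = n1[sel], n2 = n2[sel],
      lambda1PerYear = -rate(n2[sel]), outflowCum = outCum, N0 = N0)
}

#' First crossing of the depletion threshold
#'
#' The depletion time is the smallest time at which n1 drops to Nd;
#' between trajectory nodes the crossing is located by linear
#' interpolation.
#'
#' @param traj A [PopulationTrajectory-class] object.
#' @param Nd Depletion number (default 1e3).
#' @return Depletion time in years.
#' @export
depletionTimeFromTrajectory <- function(traj, Nd = 1e3) {
  stopifnot(is(traj, "PopulationTrajectory"))
  n1 <- traj@n1
  tt <- traj@times
  if (n1[1] <= Nd) return(0)
  ic <- which(n1 <= Nd)[1]
  if (is.na(ic))
    stop("trajectory never reaches n1 <= ", Nd, " (final n1 = ",
         signif(n1[length(n1)], 6), " at ", signif(max(tt), 6),
         " years); extend the horizon")
  tt[ic - 1L] + (tt[ic] - tt[ic - 1L]) *
    (n1[ic - 1L] - Nd) / (n1[ic - 1L] - n1[ic])
}

setMethod("show", "PopulationTrajectory", function(object) {
  cat(sprintf(
    "PopulationTrajectory: %d nodes over %.4g years (N0 = %g)\n",
    length(object@times), max(object@times), object@N0))
  cat(sprintf("  final n1 = %.6g, n2 = %.6g\n",
              object@n1[length(object@n1)], object@n2[length(object@n2)]))
  invisible(NULL)
})

#' @describeIn simulateDde Data-frame view of the trajectory.
#' @param x A `PopulationTrajectory` object.
#' @param row.names,optional Ignored (S3 compatibility).
#' @export
setMethod("as.data.frame", "PopulationTrajectory",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time_years = x@times, n1 = x@n1, n2 = x@n2,
             lambda1_per_year = x@lambda1PerYear,
             outflow_cum = x@outflowCum)
})
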