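#' Solve the chemical master equation transient
#'
#' Integrates dP/dt = A P over the truncated state space with the
#' collapsed absorbing on-state, using the stiff sparse solver `lsodes`.
#' The absorbing-state probability `pOn(t)` is the last component of P;
#' it is non-decreasing and tends to 1.
#'
#' @param G A [GeneratorMatrix-class] object.
#' @param p0 Initial probability vector: either length n (including the
#'   absorbing state) or n - 1 (over off-microstates; the absorbing state
#'   then starts at 0).  The default is a point mass on the integer state
#'   nearest the low deterministic equilibrium, where resting cells start.
#' @param timesYears Increasing output times in years.  The default grid
#'   is log-spaced from 1e-3 to 40 years and then steps of 0.05 years to
#'   80 years, resolving both the fast transient and the exponential tail
#'   where the pool crossing happens.
#' @param rtol,atol Integrator tolerances (defaults 1e-8 and 1e-12).
#' @return A [CmeSolution-class] object.
#' @export
#' @examples
#' G <- buildGenerator(switchParameters(), 12)
#' sol <- solveCme(G, timesYears = c(0, 0.1, 1))
#' pOn(sol)
solveCme <- function(G, p0 = NULL, timesYears = NULL,
                     rtol = 1e-8, atol = 1e-12) {
  stopifnot(is(G, "GeneratorMatrix"))
  n <- nStates(G)
  if (is.null(p0)) {
    p0 <- numeric(n)
    p0[.lowEquilibriumIndex(G)] <- 1
  } else if (length(p0) == n - 1L) {
    p0 <- c(p0, 0)
  } else if (length(p0) != n) {
    stop("p0 must have length ", n, " (with absorbing state) or ", n - 1L)
  }
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-10)
    stop("p0 must be a probability vector (non-negative, sum 1)")
  if (is.null(timesYears))
    timesYears <- c(0, 10^seq(-3, log10(40), length.out = 250),
                    seq(40.05, 80, by = 0.05))
  if (is.unsorted(timesYears, strictly = TRUE))
    stop("timesYears must be strictly increasing")
  if (timesYears[1] < 0) stop("timesYears must be non-negative")
  times <- timesYears * .MINUTES_PER_YEAR
  ## p0 is the state at t = 0: anchor the integration there even when the
  ## output grid starts later
  prepended <- times[1] > 0
  intTimes <- if (prepended) c(0, times) else times
  Arev <- G@Arev
  aAbs <- G@aAbs
  nOff <- n - 1L
  rhs <- function(t, p, parms) {
    prev <- p[seq_len(nOff)]
    list(c(as.vector(Arev %*% prev), sum(aAbs * prev)))
  }
  sol <- deSolve::ode(y = p0, times = intTimes, func = rhs, parms = NULL,
                      method = "lsodes", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("CME integration failed (lsodes istate ",
         attr(sol, "istate")[1], "); try a coarser or shorter time grid ",
         "or looser tolerances")
  P <- unname(sol[, -1, drop = FALSE])
  if (prepended) P <- P[-1, , drop = FALSE]
  ## clip the harmless negative rounding residue before validity checks
  P[P < 0 & P > -1e-9] <- 0
  pOnv <- P[, n]
  pOnv <- cummax(pOnv)   # remove sub-tolerance integrator wiggle
  new("CmeSolution", times = times, P = P, pOn = pOnv)
}

## index of the integer microstate nearest the low stable equilibrium
.lowEquilibriumIndex <- function(G) {
  eq <- findEquilibria(G@params)
  eq <- eq[eq$stability == "stable", , drop = FALSE]
  if (!nrow(eq))
    stop("no stable equilibrium found; cannot pick a default p0")
  lo <- eq[1, ]   # sorted by x + y, first stable is the low state
  stateIndex(G@space, round(lo$x), round(lo$y))
}

#' @describeIn solveCme Absorption probability over time.
#' @param object A `CmeSolution` object.
#' @export
setMethod("pOn", "CmeSolution", function(object) object@pOn)

#' @describeIn solveCme Survival (off-state) probability over time.
#' @export
setMethod("pOff", "CmeSolution", function(object) 1 - object@pOn)

#' Output times of a CME solution in years
#' @param sol A [CmeSolution-class] object.
#' @return Numeric vector of times in years.
#' @export
cmeTimesYears <- function(sol) {
  stopifnot(is(sol, "CmeSolution"))
  sol@times / .MINUTES_PER_YEAR
}

setMethod("show", "CmeSolution", function(object) {
  ty <- range(object@times) / .MINUTES_PER_YEAR
  cat(sprintf(
    "CmeSolution: %d states, %d output times spanning %.3g-%.4g years\n",
    ncol(object@P), length(object@times), ty[1], ty[2]))
  cat(sprintf("  final pOn = %.6g\n", object@pOn[length(object@pOn)]))
  invisible(NULL)
})

#' As-data-frame view of the macrostate probabilities
#' @param x A [CmeSolution-class] object.
#' @param row.names,optional,... Ignored (S3 compatibility).
#' @return Data frame with columns `time_years`, `p_on`, `p_off`.
#' @export
setMethod("as.data.frame", "CmeSolution",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time_years = x@times / .MINUTES_PER_YEAR,
             p_on = x@pOn, p_off = 1 - x@pOn)
})

#' Fit the exponential tail of the off-state probability
#'
#' Over the last decade of the time grid the survival probability decays as
#' a single exponential, p_off(t) ~ c1 exp(lambda1 t) with c1 > 0.  This
#' regresses log p_off against t over that window and reports the
#' intercept-derived amplitude c1, the fitted slope, and its ratio to the
#' spectrally computed lambda1 (a self-consistency check between the
#' transient and spectral computations).
#'
#' @param sol A [CmeSolution-class] object.
#' @param summary Optional [SpectralSummary-class]; when supplied the
#'   solution must cover at least three switching half-lives and the
#'   `ratio` element is filled in.
#' @return A list with elements `c1`, `slopePerYear`, `ratio`
#'   (slope / lambda1, NA without `summary`), `residual` (RMS of the log
#'   fit) and `nPoints`.
#' @export
ponTailFit <- function(sol, summary = NULL) {
  stopifnot(is(sol, "CmeSolution"))
  tYears <- sol@times / .MINUTES_PER_YEAR
  pOffv <- 1 - sol@pOn
  if (!is.null(summary)) {
    stopifnot(is(summary, "SpectralSummary"))
    if (max(tYears) < 3 * summary@halfLifeYears)
      stop("solution spans ", signif(max(tYears), 4), " years but the ",
           "tail fit needs at least 3 half-lives (",
           signif(3 * summary@halfLifeYears, 4), " years)")
  }
  sel <- tYears >= max(tYears) / 10
  if (any(pOffv[sel] <= 0)) {
    warning("non-positive p_off values in the tail (numerical underflow); ",
            "truncating the fit window")
    sel <- sel & pOffv > 0
  }
  if (sum(sel) < 3L)
    stop("fewer than 3 usable tail points; extend the time grid")
  fit <- lm(log(pOffv[sel]) ~ tYears[sel])
  slope <- unname(coef(fit)[2])
  list(c1 = exp(unname(coef(fit)[1])),
       slopePerYear = slope,
       ratio = if (is.null(summary)) NA_real_ else
         slope / (summary@lambda1 * .MINUTES_PER_YEAR),
       residual = sqrt(mean(fit$residuals^2)),
       nPoints = sum(sel))
}
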