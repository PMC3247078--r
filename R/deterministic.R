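#' Reaction rates of the switch at a microstate
#'
#' Evaluates the five rate laws of the positive-feedback switch at state
#' (x, y): basal production of X (`v1 = k1`), Hill-activated production of
#' X by Y (`v2`), degradation of X (`v3`), Hill-activated production of Y
#' by X (`v4`) and degradation of Y (`v5`).  These same expressions serve
#' as the stochastic propensities of the master equation and the Gillespie
#' simulation.
#'
#' @param x,y Non-negative amounts of X and Y (real in the deterministic
#'   context, integer copy numbers in the stochastic one).
#' @param params A [SwitchParameters-class] object.
#' @return Named numeric vector `c(v1, v2, v3, v4, v5)`, all finite and
#'   non-negative.
#' @export
#' @examples
#' evaluateRates(0, 25, switchParameters())  # v2 at half-saturation
evaluateRates <- function(x, y, params) {
  stopifnot(is(params, "SwitchParameters"))
  validObject(params)
  if (length(x) != 1L || length(y) != 1L || !is.finite(x) || !is.finite(y))
    stop("state components must be finite scalars")
  if (x < 0 || y < 0)
    stop("state components must be non-negative")
  x <- unname(x)
  y <- unname(y)
  c(v1 = params@k1,
    v2 = params@V1 * y^params@h / (params@M1^params@h + y^params@h),
    v3 = params@u1 * x,
    v4 = params@V2 * x^params@h / (params@M2^params@h + x^params@h),
    v5 = params@u2 * y)
}

## vector field and Jacobian of the deterministic switch ODE
.switchField <- function(x, y, p) {
  c(p@k1 + p@V1 * y^p@h / (p@M1^p@h + y^p@h) - p@u1 * x,
    p@V2 * x^p@h / (p@M2^p@h + x^p@h) - p@u2 * y)
}

.switchJacobian <- function(x, y, p) {
  h <- p@h
  df1dy <- if (y > 0) {
    p@V1 * h * p@M1^h * y^(h - 1) / (p@M1^h + y^h)^2
  } else if (h == 1) p@V1 / p@M1 else 0
  df2dx <- if (x > 0) {
    p@V2 * h * p@M2^h * x^(h - 1) / (p@M2^h + x^h)^2
  } else if (h == 1) p@V2 / p@M2 else 0
  matrix(c(-p@u1, df2dx, df1dy, -p@u2), 2, 2)
}

#' Equilibria of the deterministic switch
#'
#' Finds all equilibrium points of the two-component switch ODE and
#' classifies their stability from the Jacobian spectrum.  The search
#' exploits the nullcline structure: at any equilibrium y = v4(x)/u2, so
#' equilibria are roots of a scalar function of x that is bracketed on a
#' dense grid over \[0, (k1+V1)/u1\] and polished with `uniroot`.  With
#' the nominal parameters the switch is bistable: a low stable point (I),
#' a saddle (II) and a high stable point (III).
#'
#' @param params A [SwitchParameters-class] object.
#' @param gridN Number of bracketing grid points (default 2000).
#' @param tol Residual tolerance on the right-hand-side norm (default 1e-9).
#' @param stabilityTol Tolerance for calling an eigenvalue real part zero;
#'   such points are flagged `degenerate` (default 1e-12).
#' @return A data frame sorted by x + y ascending, with columns `x`, `y`,
#'   `stability` (one of `"stable"`, `"unstable"`, `"saddle"`),
#'   `eig_re_1`, `eig_im_1`, `eig_re_2`, `eig_im_2` and `degenerate`.
#' @export
#' @examples
#' findEquilibria(switchParameters())
findEquilibria <- function(params, gridN = 2000L, tol = 1e-9,
                           stabilityTol = 1e-12) {
  stopifnot(is(params, "SwitchParameters"))
  p <- params
  ynull <- function(x) p@V2 * x^p@h / (p@M2^p@h + x^p@h) / p@u2
  ## residual of the x-equation with y forced onto the y-nullcline
  f <- function(x) {
    y <- ynull(x)
    p@k1 + p@V1 * y^p@h / (p@M1^p@h + y^p@h) - p@u1 * x
  }
  xmax <- (p@k1 + p@V1) / p@u1 * 1.05
  xs <- seq(0, xmax, length.out = gridN)
  fs <- vapply(xs, f, numeric(1))
  roots <- numeric(0)
  sgn <- sign(fs)
  cross <- which(sgn[-1] * sgn[-gridN] < 0)
  for (i in cross)
    roots <- c(roots, uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-12)$root)
  roots <- c(roots, xs[fs == 0])
  if (!length(roots))
    stop("no equilibrium bracketed on [0, ", signif(xmax, 4),
         "]; the vector field does not change sign on the search grid")
  ## de-duplicate at 1e-3 copies
  roots <- sort(roots)
  roots <- roots[c(TRUE, diff(roots) > 1e-3)]
  res <- lapply(roots, function(x) {
    y <- ynull(x)
    fv <- .switchField(x, y, p)
    if (sqrt(sum(fv^2)) > tol)
      stop("root polish failed: residual ", signif(sqrt(sum(fv^2)), 3),
           " exceeds tolerance at x = ", signif(x, 6))
    ev <- eigen(.switchJacobian(x, y, p), only.values = TRUE)$values
    ev <- ev[order(Re(ev), decreasing = TRUE)]
    re <- Re(ev)
    degenerate <- any(abs(re) <= stabilityTol)
    stability <- if (all(re < 0)) "stable"
                 else if (all(re > 0)) "unstable"
                 else "saddle"
    data.frame(x = x, y = y, stability = stability,
               eig_re_1 = Re(ev[1]), eig_im_1 = Im(ev[1]),
               eig_re_2 = Re(ev[2]), eig_im_2 = Im(ev[2]),
               degenerate = degenerate)
  })
  out <- do.call(rbind, res)
  out[order(out$x + out$y), , drop = FALSE]
}

#' Integrate the deterministic switch ODE
#'
#' Forward-integrates the two-component switch from a non-negative initial
#' state.  The flow preserves non-negativity (production terms are bounded,
#' degradation vanishes at zero) and converges to one of the stable
#' equilibria.
#'
#' @param params A [SwitchParameters-class] object.
#' @param init Numeric length-2 initial state `c(x, y)`, non-negative.
#' @param times Increasing output times in minutes.
#' @param ... Passed to [deSolve::ode()] (e.g. `rtol`, `atol`).
#' @return Data frame with columns `time` (minutes), `x`, `y`.
#' @export
#' @examples
#' simulateSwitchOde(switchParameters(), c(0, 0), seq(0, 2000, 10))
simulateSwitchOde <- function(params, init, times, ...) {
  stopifnot(is(params, "SwitchParameters"), length(init) == 2L)
  if (any(init < 0)) stop("initial state must be non-negative")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  rhs <- function(t, state, parms)
    list(.switchField(state[1], state[2], params))
  sol <- deSolve::ode(y = c(x = init[1], y = init[2]), times = times,
                      func = rhs, parms = NULL, ...)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed with istate ", attr(sol, "istate")[1],
         "; see deSolve::diagnostics for details")
  out <- as.data.frame(sol)
  names(out) <- c("time", "x", "y")
  out
}

#' Classify a microstate as off or on
#'
#' The off macrostate is the region x + y < L, the on macrostate is
#' x + y >= L.  The shared boundary x + y = L is reported as `"on"`: the
#' on-region is absorbing and irreversibility demands an unambiguous
#' assignment.
#'
#' @param x,y Non-negative state coordinates (vectorised).
#' @param L Macrostate threshold on x + y (positive integer, default 55).
#' @return Character vector of `"off"` / `"on"`.
#' @export
#' @examples
#' classifyMacrostate(c(0, 30, 27), c(0, 30, 28))
classifyMacrostate <- function(x, y, L = 55L) {
  if (length(L) != 1L || L != round(L) || L <= 0)
    stop("L must be a positive integer")
  if (any(x < 0) || any(y < 0)) stop("states must be non-negative")
  ifelse(x + y >= L, "on", "off")
}
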