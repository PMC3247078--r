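#' @import methods
NULL

setClassUnion("functionOrNULL", c("function", "NULL"))

#' Kinetic parameters of the bistable switch
#'
#' Rate constants of the two-component positive-feedback switch.  `k1` is
#' the basal production rate of X, `V1`/`V2` the maximal feedback-driven
#' production rates of X and Y, `M1`/`M2` the half-saturation copy numbers
#' of the Hill terms, `h` the Hill coefficient (real-valued so that
#' sensitivity scans may scale it continuously), and `u1`/`u2` the
#' first-order degradation rates.  All rates are per minute, copy-number
#' quantities are molecule counts.
#'
#' @slot k1,V1,V2,M1,M2,h,u1,u2 Strictly positive numeric scalars.
#' @seealso [switchParameters()] for the constructor with the nominal
#'   parameter set.
#' @export
setClass("SwitchParameters",
  representation(k1 = "numeric", V1 = "numeric", V2 = "numeric",
                 M1 = "numeric", M2 = "numeric", h = "numeric",
                 u1 = "numeric", u2 = "numeric"),
  validity = function(object) {
    v <- c(k1 = object@k1, V1 = object@V1, V2 = object@V2,
           M1 = object@M1, M2 = object@M2, h = object@h,
           u1 = object@u1, u2 = object@u2)
    if (length(v) != 8L || any(!is.finite(v)))
      return("all parameters must be finite numeric scalars")
    if (any(v <= 0))
      return(paste0("parameters must be strictly positive; offending: ",
                    paste(names(v)[v <= 0], collapse = ", ")))
    TRUE
  })

#' Enumerated microstates of the truncated Markov model
#'
#' Integer microstates (X, Y) with X + Y <= boundary, ordered
#' diagonal-by-diagonal: by s = X + Y ascending, then X descending, i.e.
#' (0,0), (1,0), (0,1), (2,0), (1,1), (0,2), ...  The collapsed absorbing
#' on-state occupies one extra index after the last off-microstate.
#'
#' @slot boundary Largest X + Y kept as an explicit off-microstate.
#' @slot states Integer matrix with columns `x`, `y`, one row per
#'   off-microstate.
#' @seealso [enumerateStates()], [stateIndex()]
#' @export
setClass("StateSpace",
  representation(boundary = "integer", states = "matrix"),
  validity = function(object) {
    B <- object@boundary
    if (length(B) != 1L || B < 0L)
      return("boundary must be a single non-negative integer")
    n <- (B + 1) * (B + 2) / 2
    if (nrow(object@states) != n)
      return(sprintf("expected %d off-microstates, found %d",
                     n, nrow(object@states)))
    if (any(object@states < 0L))
      return("microstates must be non-negative")
    TRUE
  })

#' Sparse generator of the absorbing Markov model
#'
#' Transition-rate (generator) matrix of the continuous-time Markov chain
#' over the off-microstates plus the collapsed absorbing on-state.  `Arev`
#' is the leading block over off-microstates; `aAbs` holds the absorption
#' propensities (the rates of production events that leave the off region).
#' Columns of the full generator sum to zero; the absorbing column is zero.
#'
#' @slot Arev Sparse `dgCMatrix`, (n-1) x (n-1), rates per minute.
#' @slot aAbs Numeric vector of absorption rates, one per off-microstate.
#' @slot space The [StateSpace-class] the generator was built on.
#' @slot params The [SwitchParameters-class] used.
#' @seealso [buildGenerator()], [fullGenerator()], [dominantMode()]
#' @export
setClass("GeneratorMatrix",
  representation(Arev = "dgCMatrix", aAbs = "numeric",
                 space = "StateSpace", params = "SwitchParameters"),
  validity = function(object) {
    n <- nrow(object@space@states)
    if (!all(dim(object@Arev) == c(n, n)))
      return("Arev dimension does not match the state space")
    if (length(object@aAbs) != n)
      return("aAbs length does not match the state space")
    if (any(object@aAbs < 0))
      return("absorption propensities must be non-negative")
    colsum <- Matrix::colSums(object@Arev) + object@aAbs
    if (max(abs(colsum)) > 1e-10)
      return("columns of the full generator must sum to zero")
    TRUE
  })

#' Dominant decay mode of the switching process
#'
#' The rightmost eigenvalue lambda1 of the non-absorbing generator block and
#' its strictly positive eigenvector (Perron structure of the irreducible
#' Metzler block).  |lambda1| is the asymptotic per-cell switching rate;
#' the off-state probability decays as c1 * exp(lambda1 * t).
#'
#' @slot lambda1 Dominant eigenvalue, per minute (real, negative).
#' @slot eigenvector Associated eigenvector, normalised to sum 1.
#' @slot ratePerYear Switching rate |lambda1| converted to per-year units.
#' @slot halfLifeYears ln(2) / |lambda1| in years.
#' @slot method `"sparse"` (inverse iteration) or `"dense"` (full spectrum).
#' @slot boundary The state-space boundary used.
#' @seealso [dominantMode()]
#' @export
setClass("SpectralSummary",
  representation(lambda1 = "numeric", eigenvector = "numeric",
                 ratePerYear = "numeric", halfLifeYears = "numeric",
                 method = "character", boundary = "integer"),
  validity = function(object) {
    if (length(object@lambda1) != 1L || !is.finite(object@lambda1) ||
        object@lambda1 >= 0)
      return("lambda1 must be a single finite negative number")
    if (any(object@eigenvector < 0))
      return("dominant eigenvector must be non-negative")
    if (abs(sum(object@eigenvector) - 1) > 1e-8)
      return("dominant eigenvector must be normalised to sum 1")
    TRUE
  })

#' Transient solution of the chemical master equation
#'
#' Probability over all microstates (off-states plus the absorbing
#' on-state) on a grid of output times.  Each row of `P` is a probability
#' vector; `pOn` is its last component, the probability that the switch has
#' irreversibly turned on.
#'
#' @slot times Output times in minutes.
#' @slot P Matrix, one row per time, one column per state.
#' @slot pOn Numeric vector, the absorbing-state probability over time.
#' @seealso [solveCme()], [pOn()], [pOff()]
#' @export
setClass("CmeSolution",
  representation(times = "numeric", P = "matrix", pOn = "numeric"),
  validity = function(object) {
    if (nrow(object@P) != length(object@times))
      return("P must have one row per output time")
    if (length(object@pOn) != length(object@times))
      return("pOn must have one entry per output time")
    if (min(object@P) < -1e-8)
      return("probabilities must be non-negative")
    if (max(abs(rowSums(object@P) - 1)) > 1e-8)
      return("probability must be conserved (rows of P sum to 1)")
    if (min(diff(object@pOn)) < -1e-8)
      return("pOn must be non-decreasing")
    TRUE
  })

#' Gillespie trajectory of the switch network
#'
#' Exact stochastic simulation sample path: jump times and the integer
#' microstate after each reaction event.  Consecutive states differ by one
#' unit step in one coordinate.
#'
#' @slot times Event times in minutes (first entry 0, the initial state).
#' @slot states Integer matrix with columns `x`, `y`.
#' @slot seed Seed used for the realisation.
#' @slot mode `"free"`, `"absorbing"` or `"reflecting"`.
#' @slot boundary Boundary used in absorbing/reflecting mode (NA if free).
#' @slot absorbed Logical, whether the run ended by absorption.
#' @slot tAbs Absorption time in minutes (NA if not absorbed).
#' @seealso [simulateSsa()]
#' @export
setClass("SsaTrajectory",
  representation(times = "numeric", states = "matrix", seed = "integer",
                 mode = "character", boundary = "integer",
                 absorbed = "logical", tAbs = "numeric"),
  validity = function(object) {
    if (nrow(object@states) != length(object@times))
      return("states must have one row per event time")
    if (any(object@states < 0L))
      return("copy numbers must be non-negative")
    if (is.unsorted(object@times))
      return("event times must be non-decreasing")
    TRUE
  })

#' Pool size and depletion threshold
#'
#' @slot N0 Initial number of cells in the pool.
#' @slot Nd Depletion number: the pool counts as depleted when at most
#'   `Nd` cells remain (Nd = 1000 is taken to mark the onset of menopause;
#'   Nd = N0 is the degenerate already-depleted pool).
#' @seealso [poolConfig()]
#' @export
setClass("PoolConfig",
  representation(N0 = "numeric", Nd = "numeric"),
  validity = function(object) {
    if (object@N0 != round(object@N0) || object@Nd != round(object@Nd))
      return("N0 and Nd must be integer-valued")
    if (!(object@N0 >= object@Nd && object@Nd >= 1))
      return("need N0 >= Nd >= 1")
    TRUE
  })

#' Feedback parameters of the delayed population model
#'
#' Parameters of the two-compartment follicle population model in which
#' growing follicles suppress growth initiation: the basal production rate
#' of the switch drops from `k1Max` with the number of growing follicles
#' n2 as k1(n2) = k1Max * Kn / (Kn + n2).  Growing follicles reside for a
#' fixed time `tauYears` before leaving the pool.
#'
#' @slot k1Max Maximal basal production rate (per minute).
#' @slot Kn Half-suppression follicle number.
#' @slot tauYears Residence time in the growing compartment (years).
#' @slot switch Switch parameters shared with the single-cell model (the
#'   `k1` slot holds `k1Max`, i.e. the unsuppressed value).
#' @slot N0 Initial number of primordial follicles.
#' @seealso [feedbackParameters()], [k1OfN2()], [simulateDde()]
#' @export
setClass("FeedbackParameters",
  representation(k1Max = "numeric", Kn = "numeric", tauYears = "numeric",
                 switch = "SwitchParameters", N0 = "numeric"),
  validity = function(object) {
    v <- c(k1Max = object@k1Max, Kn = object@Kn, N0 = object@N0)
    if (any(!is.finite(v)) || any(v <= 0))
      return(paste0("feedback parameters must be strictly positive; ",
                    "offending: ", paste(names(v)[v <= 0], collapse = ", ")))
    if (!is.finite(object@tauYears) || object@tauYears < 0)
      return("tauYears must be non-negative (0 selects the no-delay limit)")
    TRUE
  })

#' Precomputed switching-rate map lambda1(n2)
#'
#' Dominant eigenvalue of the transition matrix rebuilt with
#' k1 = k1(n2), tabulated on a grid of growing-follicle numbers and
#' interpolated monotonically (log|lambda1| against log(1 + n2), Hyman
#' spline).  |lambda1| is non-increasing in n2: more suppression means
#' slower switching.  Rates below a numerical floor are clamped; see
#' [buildRateMap()].
#'
#' @slot n2Grid Grid of growing-follicle numbers.
#' @slot lambda1PerYear Dominant eigenvalue at each grid point, per year
#'   (negative).
#' @slot boundary State-space boundary used for the eigensolves.
#' @slot params The [FeedbackParameters-class] used.
#' @slot interp Interpolating function n2 -> lambda1 (per year, negative).
#' @seealso [buildRateMap()], [lambda1At()]
#' @export
setClass("RateMap",
  representation(n2Grid = "numeric", lambda1PerYear = "numeric",
                 boundary = "integer", params = "FeedbackParameters",
                 interp = "functionOrNULL"),
  validity = function(object) {
    if (length(object@n2Grid) != length(object@lambda1PerYear))
      return("grid and rate vectors must have equal length")
    if (any(object@lambda1PerYear >= 0))
      return("lambda1 must be negative everywhere")
    if (any(diff(abs(object@lambda1PerYear)) > 1e-12))
      return("|lambda1| must be non-increasing in n2")
    TRUE
  })

#' Trajectory of the delayed-feedback population model
#'
#' Numbers of primordial (`n1`) and growing (`n2`) follicles over time,
#' together with the instantaneous switching rate used at each step and the
#' cumulative number of follicles that have left the growing compartment.
#'
#' @slot times Output times in years.
#' @slot n1 Primordial follicle count.
#' @slot n2 Growing follicle count.
#' @slot lambda1PerYear Instantaneous rate lambda1(n2(t)), per year.
#' @slot outflowCum Cumulative outflow from the growing compartment.
#' @slot N0 Initial primordial count.
#' @seealso [simulateDde()], [depletionTimeFromTrajectory()]
#' @export
setClass("PopulationTrajectory",
  representation(times = "numeric", n1 = "numeric", n2 = "numeric",
                 lambda1PerYear = "numeric", outflowCum = "numeric",
                 N0 = "numeric"),
  validity = function(object) {
    L <- lengths(list(object@times, object@n1, object@n2,
                      object@lambda1PerYear, object@outflowCum))
    if (length(unique(L)) != 1L)
      return("all trajectory vectors must have equal length")
    if (any(diff(object@n1) > 1e-9 * object@N0))
      return("n1 must be non-increasing")
    if (min(object@n1) < -1e-9 * object@N0 ||
        min(object@n2) < -1e-9 * object@N0)
      return("follicle counts must be non-negative")
    if (abs(object@n1[1] - object@N0) > 1e-9 * object@N0)
      return("n1 must start at N0")
    TRUE
  })
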