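#' Extract the dominant eigenvalue (per minute)
#' @param object A [SpectralSummary-class] or [RateMap-class].
#' @param ... Further arguments passed to methods.
#' @return Numeric; the dominant eigenvalue(s), negative.
#' @export
setGeneric("lambda1", function(object, ...) standardGeneric("lambda1"))

#' Switching rate in per-year units
#' @param object A [SpectralSummary-class].
#' @return Numeric scalar, |lambda1| per year.
#' @export
setGeneric("ratePerYear", function(object) standardGeneric("ratePerYear"))

#' Switching half-life in years
#' @param object A [SpectralSummary-class].
#' @return Numeric scalar, ln(2)/|lambda1| in years.
#' @export
setGeneric("halfLifeYears", function(object) standardGeneric("halfLifeYears"))

#' On-state (absorption) probability over time
#' @param object A [CmeSolution-class].
#' @return Numeric vector.
#' @export
setGeneric("pOn", function(object) standardGeneric("pOn"))

#' Off-state (survival) probability over time
#' @param object A [CmeSolution-class].
#' @return Numeric vector, `1 - pOn(object)`.
#' @export
setGeneric("pOff", function(object) standardGeneric("pOff"))

#' State-space boundary
#' @param object A [StateSpace-class], [GeneratorMatrix-class],
#'   [SpectralSummary-class] or [RateMap-class].
#' @return Integer scalar.
#' @export
setGeneric("boundary", function(object) standardGeneric("boundary"))

#' Number of states, including the absorbing on-state
#' @param object A [StateSpace-class] or [GeneratorMatrix-class].
#' @return Integer scalar.
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' Parameter values as a named vector
#' @param object A [SwitchParameters-class] or [FeedbackParameters-class].
#' @return Named numeric vector.
#' @export
setGeneric("parameterValues",
           function(object) standardGeneric("parameterValues"))
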