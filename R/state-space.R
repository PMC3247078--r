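#' Enumerate the truncated state space
#'
#' Lists all integer microstates (X, Y) with X + Y <= B, ordered by the
#' diagonal sum s = X + Y ascending and, within a diagonal, by X
#' descending: (0,0), (1,0), (0,1), (2,0), (1,1), (0,2), ...  The collapsed
#' absorbing on-state takes the final index, so the model has
#' (B+1)(B+2)/2 + 1 states in total.  B = 0 is permitted as a degenerate
#' space with the single off-microstate (0,0).
#'
#' @param B Boundary: largest X + Y kept as an explicit off-microstate.
#' @return A [StateSpace-class] object.
#' @export
#' @examples
#' enumerateStates(1)   # off states (0,0), (1,0), (0,1); 4 states in all
enumerateStates <- function(B) {
  if (length(B) != 1L || !is.finite(B) || B != round(B) || B < 0)
    stop("B must be a single non-negative integer")
  B <- as.integer(B)
  s <- rep.int(0:B, 0:B + 1L)
  x <- unlist(lapply(0:B, function(d) d:0), use.names = FALSE)
  states <- cbind(x = as.integer(x), y = as.integer(s - x))
  new("StateSpace", boundary = B, states = states)
}

#' Index of a microstate in the enumeration
#'
#' Maps (x, y) to its 1-based position in the state ordering of
#' [enumerateStates()].  The absorbing on-state has index
#' [nStates()], i.e. one past the last off-microstate.
#'
#' @param space A [StateSpace-class] object.
#' @param x,y Integer coordinates (vectorised); must satisfy
#'   x + y <= boundary.
#' @return Integer vector of positions.
#' @export
#' @examples
#' sp <- enumerateStates(3)
#' stateIndex(sp, 0, 0)
stateIndex <- function(space, x, y) {
  stopifnot(is(space, "StateSpace"))
  if (any(x < 0) || any(y < 0) || any(x + y > space@boundary))
    stop("state outside the off region of the state space")
  d <- x + y
  as.integer(d * (d + 1) / 2 + (d - x) + 1)
}

#' @describeIn enumerateStates Total number of states including the
#'   absorbing on-state.
#' @param object A `StateSpace` object.
#' @export
setMethod("nStates", "StateSpace", function(object) {
  nrow(object@states) + 1L
})

#' @describeIn enumerateStates Index of the absorbing on-state (the last).
#' @param space A `StateSpace` object.
#' @export
absorbingIndex <- function(space) {
  stopifnot(is(space, "StateSpace"))
  nStates(space)
}

setMethod("boundary", "StateSpace", function(object) object@boundary)

setMethod("show", "StateSpace", function(object) {
  cat(sprintf(
    "StateSpace: x + y <= %d; %d off-microstates + 1 absorbing (n = %d)\n",
    object@boundary, nrow(object@states), nStates(object)))
  invisible(NULL)
})
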