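#' Assemble the sparse generator of the absorbing Markov model
#'
#' Builds the transition-rate matrix of the continuous-time Markov chain
#' whose states are the off-microstates of `space` plus one collapsed
#' absorbing on-state.  Propensities are the deterministic rate laws
#' evaluated at integer states (the network is not elementary, so rate
#' laws stand in for mass-action propensities).  Production events
#' (X -> X+1 at rate v1 + v2(Y); Y -> Y+1 at rate v4(X)) that would leave
#' the off region are routed to the absorbing state; degradation events
#' always stay internal.  Every column of the full generator sums to zero
#' and the absorbing column is identically zero.
#'
#' @param params A [SwitchParameters-class] object.
#' @param space A [StateSpace-class], or a boundary integer which is passed
#'   to [enumerateStates()].
#' @return A [GeneratorMatrix-class] holding the off-block `Arev`, the
#'   absorption row `aAbs`, and the inputs.
#' @export
#' @examples
#' G <- buildGenerator(switchParameters(), 10)
#' Matrix::colSums(fullGenerator(G))   # all zero
buildGenerator <- function(params, space) {
  stopifnot(is(params, "SwitchParameters"))
  validObject(params)
  if (!is(space, "StateSpace")) space <- enumerateStates(space)
  B <- space@boundary
  x <- space@states[, "x"]
  y <- space@states[, "y"]
  n <- nrow(space@states)
  p <- params
  rXp <- p@k1 + p@V1 * y^p@h / (p@M1^p@h + y^p@h)  # v1 + v2(Y)
  rYp <- p@V2 * x^p@h / (p@M2^p@h + x^p@h)         # v4(X)
  rXm <- p@u1 * x                                  # v3(X)
  rYm <- p@u2 * y                                  # v5(Y)
  internal <- (x + y + 1L) <= B          # production stays in the off region
  dx <- x > 0L
  dy <- y > 0L
  idx <- function(X, Y) { d <- X + Y; as.integer(d * (d + 1) / 2 + (d - X) + 1) }
  Arev <- Matrix::sparseMatrix(
    i = c(seq_len(n),
          idx(x[internal] + 1L, y[internal]),
          idx(x[internal], y[internal] + 1L),
          idx(x[dx] - 1L, y[dx]),
          idx(x[dy], y[dy] - 1L)),
    j = c(seq_len(n), which(internal), which(internal),
          which(dx), which(dy)),
    x = c(-(rXp + rYp + rXm + rYm),
          rXp[internal], rYp[internal], rXm[dx], rYm[dy]),
    dims = c(n, n))
  aAbs <- numeric(n)
  aAbs[!internal] <- rXp[!internal] + rYp[!internal]
  new("GeneratorMatrix", Arev = Arev, aAbs = aAbs,
      space = space, params = params)
}

#' Full generator including the absorbing state
#'
#' Assembles the complete n x n rate matrix
#' \deqn{A = \begin{pmatrix} A_{rev} & 0 \\ a_{abs} & 0 \end{pmatrix}}
#' from the stored blocks.
#'
#' @param G A [GeneratorMatrix-class] object.
#' @return A sparse `dgCMatrix` of dimension [nStates()].
#' @export
fullGenerator <- function(G) {
  stopifnot(is(G, "GeneratorMatrix"))
  n <- nrow(G@Arev)
  tr <- Matrix::summary(G@Arev)
  abs_j <- which(G@aAbs > 0)
  Matrix::sparseMatrix(
    i = c(tr$i, rep.int(n + 1L, length(abs_j))),
    j = c(tr$j, abs_j),
    x = c(tr$x, G@aAbs[abs_j]),
    dims = c(n + 1L, n + 1L))
}

#' Export a generator in MatrixMarket format
#'
#' Writes the full generator (off block plus absorption row) as a sparse
#' MatrixMarket `.mtx` file for external inspection.
#'
#' @param G A [GeneratorMatrix-class] object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
exportGeneratorMtx <- function(G, file) {
  Matrix::writeMM(fullGenerator(G), file)
  invisible(file)
}

#' @describeIn buildGenerator Number of states including the absorbing one.
#' @param object A `GeneratorMatrix` object.
#' @export
setMethod("nStates", "GeneratorMatrix", function(object) {
  nrow(object@Arev) + 1L
})

setMethod("boundary", "GeneratorMatrix", function(object) {
  object@space@boundary
})

setMethod("show", "GeneratorMatrix", function(object) {
  n <- nStates(object)
  cat(sprintf(
    "GeneratorMatrix: n = %d states (boundary %d), %d non-zero rates\n",
    n, object@space@boundary,
    length(object@Arev@x) + sum(object@aAbs > 0)))
  cat(sprintf("  absorbing states reachable from %d boundary microstates\n",
              sum(object@aAbs > 0)))
  invisible(NULL)
})
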