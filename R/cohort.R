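#' Specification of a synthetic cohort
#'
#' Defines how a cohort of individuals is generated around a base
#' parameter set: per-parameter lognormal coefficients of variation
#' (independent across parameters, median-preserving), the ages at which
#' noisy follicle counts are observed, and the log-scale standard
#' deviation of the multiplicative count noise.  The default varies only
#' the degradation rate u (CV 0.5%): the depletion time is so sensitive
#' to u that even sub-percent genetic variability in transcript stability
#' spreads menopause age by years, which is the mechanism the cohort
#' generator exercises.
#'
#' @param nIndividuals Number of individuals (default 50).
#' @param cv Named numeric vector of lognormal CVs among
#'   `k1`, `V`, `u`, `M`, `h`, `Kn`, `tau` (paired parameters vary
#'   jointly); parameters not named get CV 0.
#' @param seed Integer seed for reproducible draws.
#' @param ages Observation ages in years, within \[0, 100\].
#' @param sigma Log-scale sd of the multiplicative count noise
#'   (default 0.5, i.e. scatter of roughly a factor 1.6).
#' @return A list of class `"cohortSpec"`.
#' @export
#' @examples
#' cohortSpec(nIndividuals = 10, cv = c(u = 0.02), seed = 7)
cohortSpec <- function(nIndividuals = 50L, cv = c(u = 0.005), seed = 1L,
                       ages = seq(0, 50, by = 5), sigma = 0.5) {
  known <- c("k1", "V", "u", "M", "h", "Kn", "tau")
  if (is.null(names(cv)) || any(!names(cv) %in% known))
    stop("cv must be a named vector with names among: ",
         paste(known, collapse = ", "))
  if (any(cv < 0)) stop("CVs must be non-negative")
  if (any(ages < 0 | ages > 100)) stop("ages must lie in [0, 100]")
  if (sigma < 0) stop("sigma must be non-negative")
  full <- setNames(numeric(length(known)), known)
  full[names(cv)] <- cv
  structure(list(nIndividuals = as.integer(nIndividuals), cv = full,
                 seed = as.integer(seed), ages = ages, sigma = sigma),
            class = "cohortSpec")
}

#' Generate a synthetic cohort of depletion times
#'
#' Draws per-individual parameter multipliers from independent lognormal
#' distributions (median 1, sdlog = sqrt(log(1 + CV^2))), runs the
#' delayed-feedback population model for each individual, and records the
#' individual depletion times — the model's menopause ages.  Individuals
#' whose perturbed switch loses bistability are excluded and counted.
#' The whole procedure is deterministic under the spec's seed.
#'
#' @param spec A [cohortSpec()] object.
#' @param params Base [FeedbackParameters-class].
#' @param cfg A [PoolConfig-class] (depletion threshold).
#' @param B,gridPoints,stepYears Passed to the rate map / DDE machinery;
#'   when only `k1` and `Kn`/`tau` vary, the base switch's eigensolves are
#'   reused across individuals through the shared rate-map grid in k1.
#' @param capYears Horizon cap per individual (default 500 years).
#' @return A list of class `"syntheticCohort"`: `draws` (data frame of
#'   multipliers), `TdYears`, `excluded` (count), `meanYears`, `sdYears`.
#' @export
sampleCohort <- function(spec, params = feedbackParameters(),
                         cfg = poolConfig(), B = 55L, gridPoints = 40L,
                         stepYears = NULL, capYears = 500) {
  stopifnot(inherits(spec, "cohortSpec"), is(params, "FeedbackParameters"))
  set.seed(spec$seed)
  n <- spec$nIndividuals
  sdlog <- sqrt(log(1 + spec$cv^2))
  draws <- vapply(sdlog, function(s) {
    if (s == 0) rep(1, n) else rlnorm(n, meanlog = 0, sdlog = s)
  }, numeric(n))
  draws <- matrix(draws, nrow = n,
                  dimnames = list(NULL, names(spec$cv)))
  ## reuse one rate map when the switch itself does not vary
  switchVaries <- any(spec$cv[c("V", "u", "M", "h")] > 0)
  baseMap <- if (!switchVaries)
    buildRateMap(params, B = B, gridPoints = gridPoints) else NULL
  Td <- rep(NA_real_, n)
  excluded <- 0L
  for (i in seq_len(n)) {
    fp <- params
    for (par in colnames(draws))
      fp <- .scaleFeedback(fp, par, draws[i, par])
    if (nrow(findEquilibria(fp@switch)) != 3L) {
      excluded <- excluded + 1L
      next
    }
    map <- if (!switchVaries && draws[i, "k1"] == 1) {
      ## k1max, Kn, tau variation enters the DDE through k1OfN2 and tau
      ## only when the switch is unchanged; Kn rescales the map's n2 axis
      if (fp@Kn == params@Kn) baseMap else
        buildRateMap(fp, B = B, gridPoints = gridPoints)
    } else {
      buildRateMap(fp, B = B, gridPoints = gridPoints)
    }
    traj <- simulateDde(fp, map = map, tEndYears = capYears,
                        stepYears = stepYears, stopBelow = cfg@Nd / 2)
    Td[i] <- tryCatch(depletionTimeFromTrajectory(traj, cfg@Nd),
                      error = function(e) NA_real_)
  }
  ok <- !is.na(Td)
  structure(list(draws = as.data.frame(draws), TdYears = Td,
                 excluded = excluded,
                 meanYears = mean(Td[ok]), sdYears = sd(Td[ok])),
            class = "syntheticCohort")
}

#' @export
print.syntheticCohort <- function(x, ...) {
  ok <- sum(!is.na(x$TdYears))
  cat(sprintf(
    "Synthetic cohort: %d individuals (%d excluded, %d censored)\n",
    length(x$TdYears), x$excluded, length(x$TdYears) - ok - x$excluded))
  cat(sprintf("  depletion age: mean %.4g years, sd %.3g years\n",
              x$meanYears, x$sdYears))
  invisible(x)
}

#' Noisy follicle-count observations along a trajectory
#'
#' Emulates clinical age-versus-count scatter: at each observation age the
#' model's primordial count n1 is multiplied by lognormal noise
#' exp(eps), eps ~ Normal(0, sigma^2).  Counts are non-negative by
#' construction and equal the model curve exactly when sigma = 0.
#'
#' @param traj A [PopulationTrajectory-class] object.
#' @param spec A [cohortSpec()] (supplies `ages`, `sigma` and `seed`), or
#'   NULL to pass `ages`/`sigma`/`seed` directly.
#' @param ages,sigma,seed Overrides of the spec fields.
#' @return Data frame with columns `age_years`, `count`.
#' @export
sampleCounts <- function(traj, spec = NULL, ages = NULL, sigma = NULL,
                         seed = NULL) {
  stopifnot(is(traj, "PopulationTrajectory"))
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "cohortSpec"))
    if (is.null(ages)) ages <- spec$ages
    if (is.null(sigma)) sigma <- spec$sigma
    if (is.null(seed)) seed <- spec$seed
  }
  if (is.null(ages) || is.null(sigma) || is.null(seed))
    stop("ages, sigma and seed must be supplied (directly or via spec)")
  if (any(ages < min(traj@times) | ages > max(traj@times)))
    stop("observation ages outside the trajectory support [",
         signif(min(traj@times), 4), ", ", signif(max(traj@times), 4), "]")
  n1 <- approx(traj@times, traj@n1, xout = ages)$y
  set.seed(seed)
  eps <- rnorm(length(ages), mean = 0, sd = sigma)
  data.frame(age_years = ages, count = pmax(n1 * exp(eps), 0))
}
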