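#' Default run configuration
#'
#' The packaged defaults reproduce the nominal parameter tables of the
#' model exactly: the switch constants (k1 = 0.055/min, V = 0.55/min,
#' M = 25, h = 3, u = 0.01/min), the macrostate threshold L = 55, the
#' pool (N0 = 1e6, Nd = 1e3), and the population-model constants
#' (k1_max = 0.06/min, Kn = 8.2e4, tau = 0.4 years).
#'
#' @return A nested list of class `"switchpoolConfig"` with sections
#'   `switch`, `L`, `pool`, `feedback`, `scan`, and scalar fields `seed`,
#'   `out_dir`, `verbose`.
#' @export
#' @examples
#' defaultRunConfig()$switch$k1
defaultRunConfig <- function() {
  structure(list(
    switch = as.list(parameterValues(switchParameters())),
    L = 55L,
    pool = list(N0 = 1e6, Nd = 1e3),
    feedback = list(k1_max = 0.06, Kn = 8.2e4, tau_years = 0.4),
    scan = list(model = "single_cell",
                parameters = c("k1", "V", "u", "M", "h"),
                factors = c(0.8, 0.9, 0.95, 1.05, 1.1, 1.3)),
    seed = 1L,
    out_dir = ".",
    verbose = TRUE
  ), class = "switchpoolConfig")
}

.configSections <- function() {
  d <- unclass(defaultRunConfig())
  lapply(d, function(x) if (is.list(x)) names(x) else NULL)
}

#' Load a run configuration from JSON or YAML
#'
#' Reads a configuration file, rejects unknown keys with a message naming
#' them, fills missing keys from the packaged defaults
#' ([defaultRunConfig()]), and validates the values (rates positive,
#' counts integral, threshold a positive integer), naming the offending
#' field on failure.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `"switchpoolConfig"` list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(.readConfigFile(path), error = function(e)
    stop("failed to parse ", path, ": ", conditionMessage(e)))
  if (is.null(raw)) raw <- list()
  cfg <- unclass(defaultRunConfig())
  sections <- .configSections()
  bad <- setdiff(names(raw), names(cfg))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (nm in names(raw)) {
    if (is.null(sections[[nm]])) {
      cfg[[nm]] <- raw[[nm]]
    } else {
      sub <- raw[[nm]]
      if (!is.list(sub))
        stop("configuration section '", nm, "' must be a mapping")
      badSub <- setdiff(names(sub), sections[[nm]])
      if (length(badSub))
        stop("unknown key(s) in section '", nm, "': ",
             paste(badSub, collapse = ", "))
      for (k in names(sub)) cfg[[nm]][[k]] <- sub[[k]]
    }
  }
  .validateConfig(structure(cfg, class = "switchpoolConfig"))
}

.validateConfig <- function(cfg) {
  chkPos <- function(value, field) {
    if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
        value <= 0)
      stop("invalid value for field '", field,
           "': must be a positive number")
  }
  for (nm in names(cfg$switch)) chkPos(cfg$switch[[nm]],
                                       paste0("switch.", nm))
  if (!is.numeric(cfg$L) || cfg$L != round(cfg$L) || cfg$L <= 0)
    stop("invalid value for field 'L': must be a positive integer")
  cfg$L <- as.integer(cfg$L)
  chkPos(cfg$pool$N0, "pool.N0")
  chkPos(cfg$pool$Nd, "pool.Nd")
  if (cfg$pool$N0 <= cfg$pool$Nd)
    stop("invalid pool configuration: need N0 > Nd")
  for (nm in names(cfg$feedback)) chkPos(cfg$feedback[[nm]],
                                         paste0("feedback.", nm))
  if (!cfg$scan$model %in% c("single_cell", "population"))
    stop("invalid value for field 'scan.model'")
  if (any(cfg$scan$factors <= 0))
    stop("invalid value for field 'scan.factors': must be positive")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Write a run configuration
#'
#' @param cfg A `"switchpoolConfig"` list.
#' @param path Output path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
saveConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "switchpoolConfig"))
  .writeConfigFile(unclass(cfg), path)
  invisible(path)
}

## build model objects from a config
.cfgSwitch <- function(cfg) do.call(switchParameters, cfg$switch)
.cfgFeedback <- function(cfg) {
  sw <- cfg$switch
  feedbackParameters(k1Max = cfg$feedback$k1_max, Kn = cfg$feedback$Kn,
                     tauYears = cfg$feedback$tau_years,
                     V1 = sw$V1, V2 = sw$V2, M1 = sw$M1, M2 = sw$M2,
                     h = sw$h, u1 = sw$u1, u2 = sw$u2,
                     N0 = cfg$pool$N0)
}
.cfgPool <- function(cfg) poolConfig(N0 = cfg$pool$N0, Nd = cfg$pool$Nd)

#' Run the analysis pipeline
#'
#' Executes the requested stages with the given configuration and writes
#' each stage's artifacts (CSV/JSON) into `outDir`.  Stages:
#' \describe{
#'   \item{equilibria}{`equilibria.csv` — deterministic equilibria and
#'     stability.}
#'   \item{lambda1}{`spectral_summary.json` — dominant eigenvalue, rate
#'     per year, half-life, and the state-space dimension used.}
#'   \item{cme}{`pon_curve.csv` — time_years, p_on, p_off.}
#'   \item{pool}{`depletion.csv` and `pool_summary.json` — depletion-time
#'     CDF/density, mean, sd, and the log-ratio approximation.}
#'   \item{dde}{`population_trajectory.csv` — feedback-model n1, n2,
#'     rate; depletion time in the summary.}
#'   \item{scan}{`scan_<model>.csv` — sensitivity table.}
#'   \item{simulate}{`ssa_histogram.csv` — stationary occupancy (reduced
#'     protocol) and mode locations.}
#'   \item{cohort}{`cohort_observations.csv`, `cohort_summary.json`.}
#' }
#' A `summary.json` aggregating the key numbers (half-life, E\[Td\], sd,
#' feedback depletion time) is written at the end.  Later stages reuse
#' earlier results where they can (the CME stage feeds the pool stage).
#'
#' @param cfg A `"switchpoolConfig"` list (default [defaultRunConfig()]).
#' @param stages Subset of the stage names above.
#' @param outDir Output directory (default from the config).
#' @return Invisibly, a named list of artifact paths and key numbers.
#' @export
runPipeline <- function(cfg = defaultRunConfig(),
                        stages = c("equilibria", "lambda1", "cme", "pool",
                                   "dde"),
                        outDir = cfg$out_dir) {
  stopifnot(inherits(cfg, "switchpoolConfig"))
  known <- c("equilibria", "lambda1", "cme", "pool", "dde", "scan",
             "simulate", "cohort")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(known, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (isTRUE(cfg$verbose)) message(...)
  sw <- .cfgSwitch(cfg)
  pool <- .cfgPool(cfg)
  B <- as.integer(cfg$L)
  art <- list()
  summary <- list()
  G <- NULL
  spec <- NULL
  cmeSol <- NULL

  needG <- function() {
    if (is.null(G)) G <<- buildGenerator(sw, B)
    G
  }
  needSpec <- function() {
    if (is.null(spec)) spec <<- dominantMode(needG())
    spec
  }

  if ("equilibria" %in% stages) {
    eq <- findEquilibria(sw)
    f <- file.path(outDir, "equilibria.csv")
    write.csv(data.frame(state_x = eq$x, state_y = eq$y,
                         stability = eq$stability,
                         eig_re_1 = eq$eig_re_1, eig_re_2 = eq$eig_re_2),
              f, row.names = FALSE)
    art$equilibria <- f
    say("equilibria: ", nrow(eq), " found (",
        paste(eq$stability, collapse = ", "), ")")
  }
  if ("lambda1" %in% stages) {
    s <- needSpec()
    f <- file.path(outDir, "spectral_summary.json")
    jsonlite::write_json(list(lambda1_per_min = lambda1(s),
                              rate_per_year = ratePerYear(s),
                              half_life_years = halfLifeYears(s),
                              n_states = nStates(needG())),
                         f, auto_unbox = TRUE, digits = NA)
    art$lambda1 <- f
    summary$half_life_years <- halfLifeYears(s)
    say(sprintf("lambda1: %.4e /min on n = %d states; half-life %.4g years",
                lambda1(s), nStates(needG()), halfLifeYears(s)))
  }
  if (any(c("cme", "pool") %in% stages)) {
    cmeSol <- solveCme(needG())
    f <- file.path(outDir, "pon_curve.csv")
    write.csv(as.data.frame(cmeSol), f, row.names = FALSE)
    art$cme <- f
    say(sprintf("cme: solved on n = %d states to %.4g years",
                nStates(needG()),
                max(cmeSol@times) / .MINUTES_PER_YEAR))
  }
  if ("pool" %in% stages) {
    st <- depletionTimeStats(cmeSol, pool)
    approxTd <- expectedDepletionTimeApprox(needSpec(), pool)
    f1 <- file.path(outDir, "depletion.csv")
    write.csv(st$grid, f1, row.names = FALSE)
    f2 <- file.path(outDir, "pool_summary.json")
    jsonlite::write_json(list(mean_years = st$meanYears,
                              sd_years = st$sdYears,
                              approx_years = approxTd),
                         f2, auto_unbox = TRUE, digits = NA)
    art$pool <- c(f1, f2)
    summary$Etd_years <- st$meanYears
    summary$sd_years <- st$sdYears
    say(sprintf("pool: E[Td] = %.4g years, sd = %.3g years (approx %.4g)",
                st$meanYears, st$sdYears, approxTd))
  }
  if ("dde" %in% stages) {
    fp <- .cfgFeedback(cfg)
    traj <- simulateDde(fp, B = B, tEndYears = 510,
                        stopBelow = pool@Nd / 2)
    td <- depletionTimeFromTrajectory(traj, pool@Nd)
    f <- file.path(outDir, "population_trajectory.csv")
    df <- as.data.frame(traj)
    write.csv(df[, c("time_years", "n1", "n2", "lambda1_per_year")], f,
              row.names = FALSE)
    art$dde <- f
    summary$Td_feedback_years <- td
    say(sprintf("dde: feedback depletion time %.4g years", td))
  }
  if ("scan" %in% stages) {
    sc <- runScan(cfg$scan$model, parameters = cfg$scan$parameters,
                  factors = cfg$scan$factors, switchParams = sw,
                  feedbackParams = .cfgFeedback(cfg), cfg = pool, B = B)
    f <- file.path(outDir, paste0("scan_", cfg$scan$model, ".csv"))
    write.csv(as.data.frame(sc), f, row.names = FALSE)
    art$scan <- f
    say("scan: ", nrow(sc), " entries (", cfg$scan$model, " model)")
  }
  if ("simulate" %in% stages) {
    occ <- ssaOccupancy(sw, seed = cfg$seed, L = B)
    f <- file.path(outDir, "ssa_histogram.csv")
    write.csv(occ$histogram, f, row.names = FALSE)
    art$simulate <- f
    say(sprintf("simulate: modes off (%d, %d), on (%d, %d)",
                occ$modes["off", "x"], occ$modes["off", "y"],
                occ$modes["on", "x"], occ$modes["on", "y"]))
  }
  if ("cohort" %in% stages) {
    spec2 <- cohortSpec(seed = cfg$seed)
    co <- sampleCohort(spec2, .cfgFeedback(cfg), cfg = pool, B = B)
    f1 <- file.path(outDir, "cohort_summary.json")
    jsonlite::write_json(list(n = spec2$nIndividuals,
                              excluded = co$excluded,
                              mean_years = co$meanYears,
                              sd_years = co$sdYears),
                         f1, auto_unbox = TRUE, digits = NA)
    traj <- simulateDde(.cfgFeedback(cfg), B = B, tEndYears = 60)
    obs <- sampleCounts(traj, spec2)
    f2 <- file.path(outDir, "cohort_observations.csv")
    write.csv(obs, f2, row.names = FALSE)
    art$cohort <- c(f1, f2)
    say(sprintf("cohort: menopause age mean %.4g, sd %.3g years",
                co$meanYears, co$sdYears))
  }
  fs <- file.path(outDir, "summary.json")
  jsonlite::write_json(summary, fs, auto_unbox = TRUE, digits = NA)
  art$summary <- fs
  invisible(c(art, summary))
}
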