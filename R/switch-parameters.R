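#' Construct a switch parameter set
#'
#' Creates a [SwitchParameters-class] object.  The defaults are the nominal
#' kinetic constants of the bistable switch: basal production
#' k1 = 0.055/min (about 3.3 transcripts per hour), maximal feedback
#' production V1 = V2 = 0.55/min, half-saturation M1 = M2 = 25 copies,
#' Hill coefficient h = 3, and degradation u1 = u2 = 0.01/min (a transcript
#' half-life of about 70 minutes).  With these values the deterministic
#' switch is bistable and the fully activated steady state carries
#' V1/u1 = 55 copies.
#'
#' @param k1 Basal production rate of X (per minute).
#' @param V1,V2 Maximal feedback production rates (per minute).
#' @param M1,M2 Half-saturation constants (copy number).
#' @param h Hill coefficient (dimensionless; non-integer values are allowed
#'   so sensitivity scans can scale it continuously).
#' @param u1,u2 First-order degradation rates (per minute).
#' @return A validated [SwitchParameters-class] object.
#' @export
#' @examples
#' p <- switchParameters()
#' parameterValues(p)
switchParameters <- function(k1 = 0.055, V1 = 0.55, V2 = 0.55,
                             M1 = 25, M2 = 25, h = 3,
                             u1 = 0.01, u2 = 0.01) {
  new("SwitchParameters", k1 = k1, V1 = V1, V2 = V2, M1 = M1, M2 = M2,
      h = h, u1 = u1, u2 = u2)
}

#' @describeIn switchParameters Named vector of the eight rate constants.
#' @param object A `SwitchParameters` object.
#' @export
setMethod("parameterValues", "SwitchParameters", function(object) {
  c(k1 = object@k1, V1 = object@V1, V2 = object@V2,
    M1 = object@M1, M2 = object@M2, h = object@h,
    u1 = object@u1, u2 = object@u2)
})

setMethod("show", "SwitchParameters", function(object) {
  v <- parameterValues(object)
  cat("SwitchParameters (rates per minute, copy numbers in molecules)\n")
  cat(sprintf("  k1=%g  V1=%g V2=%g  M1=%g M2=%g  h=%g  u1=%g u2=%g\n",
              v["k1"], v["V1"], v["V2"], v["M1"], v["M2"], v["h"],
              v["u1"], v["u2"]))
  invisible(NULL)
})

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named rate constants replaced.
#'
#' @param params A [SwitchParameters-class] object.
#' @param ... Named scalar replacements among k1, V1, V2, M1, M2, h, u1, u2.
#' @return A new, validated [SwitchParameters-class] object.
#' @export
#' @examples
#' updateParameters(switchParameters(), k1 = 0.06)
updateParameters <- function(params, ...) {
  stopifnot(is(params, "SwitchParameters"))
  repl <- list(...)
  known <- c("k1", "V1", "V2", "M1", "M2", "h", "u1", "u2")
  bad <- setdiff(names(repl), known)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(repl)) slot(params, nm) <- as.numeric(repl[[nm]])
  validObject(params)
  params
}

#' Scale a (possibly paired) parameter by a factor
#'
#' Multiplies one of the scan parameters by `factor`.  The paired entries
#' are scaled jointly, following the pairing used throughout the model:
#' `"V"` scales V1 and V2, `"u"` scales u1 and u2, `"M"` scales M1 and M2.
#' `"k1"` and `"h"` scale a single slot.
#'
#' @param params A [SwitchParameters-class] object.
#' @param which One of `"k1"`, `"V"`, `"u"`, `"M"`, `"h"`.
#' @param factor Positive multiplier.
#' @return A new, validated [SwitchParameters-class] object.
#' @export
#' @examples
#' scaleParameters(switchParameters(), "u", 1.1)
scaleParameters <- function(params, which = c("k1", "V", "u", "M", "h"),
                            factor) {
  which <- match.arg(which)
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  slots <- switch(which,
                  k1 = "k1", h = "h",
                  V = c("V1", "V2"), u = c("u1", "u2"), M = c("M1", "M2"))
  for (nm in slots) slot(params, nm) <- slot(params, nm) * factor
  validObject(params)
  params
}

#' Read / write a switch parameter configuration file
#'
#' Parameter sets travel as flat JSON or YAML files with keys exactly
#' `{k1, V1, V2, M1, M2, h, u1, u2, L}`; rates are per minute and `L` is
#' the macrostate threshold on x + y.
#'
#' @param path File path; the format is chosen by extension (`.json` or
#'   `.yaml`/`.yml`).
#' @return `readSwitchConfig` returns a list with elements `params`
#'   (a [SwitchParameters-class]) and `L`.  `writeSwitchConfig` returns
#'   `path` invisibly.
#' @export
readSwitchConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- .readConfigFile(path)
  keys <- c("k1", "V1", "V2", "M1", "M2", "h", "u1", "u2", "L")
  bad <- setdiff(names(raw), keys)
  if (length(bad))
    stop("unknown key(s) in switch config: ", paste(bad, collapse = ", "))
  missing <- setdiff(keys, names(raw))
  defaults <- c(as.list(parameterValues(switchParameters())), list(L = 55))
  for (nm in missing) raw[[nm]] <- defaults[[nm]]
  L <- raw$L
  if (!is.numeric(L) || L != round(L) || L <= 0)
    stop("invalid value for field 'L': must be a positive integer")
  params <- do.call(switchParameters, raw[setdiff(keys, "L")])
  list(params = params, L = as.integer(L))
}

#' @rdname readSwitchConfig
#' @param params A [SwitchParameters-class] object to serialise.
#' @param L Macrostate threshold on x + y.
#' @export
writeSwitchConfig <- function(params, L = 55L, path) {
  stopifnot(is(params, "SwitchParameters"))
  obj <- c(as.list(parameterValues(params)), list(L = as.integer(L)))
  .writeConfigFile(obj, path)
  invisible(path)
}

## format dispatch shared by all config readers/writers
.readConfigFile <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

.writeConfigFile <- function(obj, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
}
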