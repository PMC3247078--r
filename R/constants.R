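## One year of simulated time, in minutes: 365 days x 1440 min.
## All kinetic parameters are stored per minute; conversion to years happens
## only at reporting boundaries, always through this constant.
.MINUTES_PER_YEAR <- 365 * 1440

#' Minutes per year used for all unit conversions
#'
#' The package stores every kinetic rate in per-minute units and reports
#' times in years.  A year is fixed at 365 x 1440 = 525600 minutes, so the
#' conversion per-minute to per-year and back is exact to machine precision.
#'
#' @return The number of minutes in one model year (525600).
#' @export
#' @examples
#' minutesPerYear()
minutesPerYear <- function() .MINUTES_PER_YEAR
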