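#' Relative humidity from temperature and dew point
#'
#' August–Roche–Magnus conversion: RH = 100 * e(td) / e(t) with saturation
#' vapour pressure e(x) proportional to exp(a*x / (b + x)), a = 17.625,
#' b = 243.04 degC. A dew point above the air temperature (possible in noisy
#' station data) is clamped to 100% with a warning. Missing inputs propagate.
#'
#' @param t air temperature, degC (vectorised).
#' @param td dew point temperature, degC.
#' @param a,b Magnus constants.
#' @return relative humidity in percent, in \[0, 100\].
#' @export
dewpoint_to_rh <- function(t, td, a = 17.625, b = 243.04) {
  # single exp of the log-ratio keeps saturation (td = t) at exactly 100
  rh <- 100 * exp(a * td / (b + td) - a * t / (b + t))
  over <- !is.na(rh) & rh > 100
  if (any(over)) {
    warning(sum(over), " dew point value(s) above air temperature; ",
            "relative humidity clamped to 100%")
    rh[over] <- 100
  }
  rh
}

#' NWS heat index (apparent temperature)
#'
#' Implements the National Weather Service algorithm: temperature is
#' converted to degF; the Steadman simple formula
#' 0.5 * (T + 61 + (T - 68) * 1.2 + RH * 0.094), averaged with T, is used
#' when that average is below 80 degF; otherwise the Rothfusz regression
#' applies, with the standard low-humidity subtraction (RH < 13%,
#' 80 <= T <= 112 degF) and high-humidity addition (RH > 85%,
#' 80 <= T <= 87 degF). The result is returned in degC, unrounded (set
#' `round_f = TRUE` to round to whole degF first, as some published
#' implementations do).
#'
#' @param t air temperature, degC (vectorised).
#' @param rh relative humidity, percent in \[0, 100\].
#' @param round_f round the internal degF result to the nearest whole degree
#'   before converting back, matching chart-style output. Default `FALSE`.
#' @return apparent temperature, degC. Missing inputs propagate.
#' @export
heat_index <- function(t, rh, round_f = FALSE) {
  ok <- !is.na(rh)
  if (any(ok & (rh < 0 | rh > 100))) {
    stop("relative humidity must be in [0, 100]")
  }
  tf <- c_to_f(t)
  hi <- heat_index_f(tf, rh)
  if (round_f) hi <- round(hi)
  f_to_c(hi)
}

# degF in, degF out; vectorised core of the NWS algorithm
heat_index_f <- function(tf, rh) {
  simple <- 0.5 * (tf + 61 + (tf - 68) * 1.2 + rh * 0.094)
  hi <- (simple + tf) / 2
  hot <- !is.na(hi) & hi >= 80
  if (any(hot)) {
    T <- tf[hot]
    R <- rh[hot]
    roth <- -42.379 + 2.04901523 * T + 10.14333127 * R -
      0.22475541 * T * R - 6.83783e-3 * T^2 - 5.481717e-2 * R^2 +
      1.22874e-3 * T^2 * R + 8.5282e-4 * T * R^2 - 1.99e-6 * T^2 * R^2
    lo <- R < 13 & T >= 80 & T <= 112
    roth[lo] <- roth[lo] -
      ((13 - R[lo]) / 4) * sqrt((17 - abs(T[lo] - 95)) / 17)
    hi_adj <- R > 85 & T >= 80 & T <= 87
    roth[hi_adj] <- roth[hi_adj] +
      ((R[hi_adj] - 85) / 10) * ((87 - T[hi_adj]) / 5)
    hi[hot] <- roth
  }
  hi
}

c_to_f <- function(t) t * 9 / 5 + 32
f_to_c <- function(t) (t - 32) * 5 / 9

#' Derive humidity and apparent temperature for a regional weather series
#'
#' Adds `rh = dewpoint_to_rh(tmax, dewpoint)` and
#' `at_max = heat_index(tmax, rh)` columns. Rows missing `tmax` or
#' `dewpoint` get missing derived values.
#'
#' @param weather a regional daily weather `data.frame` with `tmax` and
#'   `dewpoint` columns (degC).
#' @param round_f passed to [heat_index()].
#' @return `weather` with numeric `rh` and `at_max` columns appended.
#' @export
derive_metrics <- function(weather, round_f = FALSE) {
  rh <- rep(NA_real_, nrow(weather))
  at <- rep(NA_real_, nrow(weather))
  ok <- !is.na(weather$tmax) & !is.na(weather$dewpoint)
  if (any(ok)) {
    rh[ok] <- dewpoint_to_rh(weather$tmax[ok], weather$dewpoint[ok])
    at[ok] <- heat_index(weather$tmax[ok], rh[ok], round_f = round_f)
  }
  weather$rh <- rh
  weather$at_max <- at
  weather
}
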