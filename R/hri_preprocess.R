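#' Mark low daily counts as censored
#'
#' Surveillance products suppress daily counts below a privacy cutoff.
#' Days with `count < cutoff` (strictly) are marked censored; a day exactly
#' at the cutoff is not. Used both to process raw series and by the
#' synthetic generator to emulate the surveillance product.
#'
#' @param series a `data.frame` with a non-negative `count` column.
#' @param cutoff censoring cutoff; default 5 ("fewer than five").
#' @return `series` with a logical `censored` column; the censoring
#'   fraction is attached as attribute `censoring_fraction`.
#' @export
apply_censoring <- function(series, cutoff = 5) {
  if (any(series$count < 0, na.rm = TRUE)) stop("counts must be >= 0")
  series$censored <- !is.na(series$count) & series$count < cutoff
  attr(series, "censoring_fraction") <- mean(series$censored)
  series
}

#' Impute censored daily counts with a constant
#'
#' Every censored day's count is replaced by `impute_value` (default 3, the
#' reported median of suppressed days); uncensored days are untouched.
#'
#' @param series a `data.frame` with `count` and logical `censored` columns.
#' @param impute_value non-negative integer imputation constant.
#' @return `series` with censored counts imputed; attribute
#'   `censoring_fraction` gives the fraction of imputed days.
#' @export
impute_censored <- function(series, impute_value = 3) {
  if (is.null(series$censored)) stop("series lacks a censored column")
  if (impute_value < 0) stop("impute_value must be >= 0")
  series$count[series$censored] <- impute_value
  attr(series, "censoring_fraction") <- mean(series$censored)
  series
}
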