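#' The standard 28-definition heat wave grammar
#'
#' Each definition combines a heat metric (daily mean, maximum, minimum or
#' maximum apparent temperature), a duration rule (single day, or 2+/3+
#' consecutive days), a threshold type (relative percentile of a long summer
#' climatology, or an absolute cutoff in degC) and an intensity (the
#' percentile, or the cutoff). HW_01-HW_08 use mean temperature,
#' HW_09-HW_16 maximum, HW_18-HW_25 minimum, each crossing 2+/3+ days with
#' the 99/98/95/90th percentiles; HW_17 is the single absolute definition
#' (maximum temperature > 35 degC on a single day); HW_26-HW_28 are
#' single-day maximum-apparent-temperature definitions at the 95/90/85th
#' percentiles.
#'
#' @return a 28-row `data.frame` with columns `id`, `metric`
#'   (`mean|max|min|apparent_max`), `duration` (`1-day|2+|3+`),
#'   `threshold_type` (`relative|absolute`), `intensity` (percentile, or
#'   degC for absolute).
#' @export
standard_definitions <- function() {
  grid_ids <- function(ids, metric) {
    data.frame(
      id = ids, metric = metric,
      duration = rep(c("2+", "3+"), 4),
      threshold_type = "relative",
      intensity = rep(c(99, 98, 95, 90), each = 2),
      stringsAsFactors = FALSE
    )
  }
  defs <- rbind(
    grid_ids(sprintf("HW_%02d", 1:8), "mean"),
    grid_ids(sprintf("HW_%02d", 9:16), "max"),
    data.frame(id = "HW_17", metric = "max", duration = "1-day",
               threshold_type = "absolute", intensity = 35,
               stringsAsFactors = FALSE),
    grid_ids(sprintf("HW_%02d", 18:25), "min"),
    data.frame(id = sprintf("HW_%02d", 26:28), metric = "apparent_max",
               duration = "1-day", threshold_type = "relative",
               intensity = c(95, 90, 85), stringsAsFactors = FALSE)
  )
  rownames(defs) <- NULL
  defs
}

#' Percentile threshold from a climatological baseline
#'
#' The p-th percentile of the non-missing baseline values, using linear
#' interpolation between order statistics (position h = (n-1)*p/100 + 1,
#' i.e. `stats::quantile` type 7).
#'
#' @param baseline numeric vector of metric values over the baseline summer
#'   days (missing values dropped).
#' @param percentile percentile in (0, 100).
#' @param type `stats::quantile` interpolation type; 7 is the documented
#'   default.
#' @return threshold in the units of `baseline` (degC).
#' @export
compute_threshold <- function(baseline, percentile, type = 7) {
  baseline <- baseline[!is.na(baseline)]
  if (length(baseline) == 0) stop("baseline is empty after dropping NAs")
  unname(stats::quantile(baseline, percentile / 100, type = type))
}

metric_column <- function(metric) {
  switch(metric,
         mean = "tmean", max = "tmax", min = "tmin",
         apparent_max = "at_max",
         stop("unknown metric: ", metric))
}

#' Resolve thresholds for a definition set from baseline climatology
#'
#' Relative definitions get the percentile of their metric over the
#' baseline summer days of each region; absolute definitions carry their
#' intensity directly (identical across regions).
#'
#' @param baseline a regional daily weather `data.frame` covering the
#'   baseline era, with derived metrics (see [derive_metrics()]).
#' @param definitions a definition table as from [standard_definitions()].
#' @param type percentile interpolation type, passed to [compute_threshold()].
#' @return a `data.frame` with columns `region`, `definition_id`,
#'   `threshold_c`.
#' @export
compute_thresholds <- function(baseline, definitions = standard_definitions(),
                               type = 7) {
  regions <- sort(unique(baseline$region))
  out <- expand.grid(region = regions, definition_id = definitions$id,
                     stringsAsFactors = FALSE)
  out$threshold_c <- NA_real_
  for (i in seq_len(nrow(out))) {
    def <- definitions[definitions$id == out$definition_id[i], ]
    if (def$threshold_type == "absolute") {
      out$threshold_c[i] <- def$intensity
    } else {
      vals <- baseline[baseline$region == out$region[i],
                       metric_column(def$metric)]
      out$threshold_c[i] <- compute_threshold(vals, def$intensity,
                                              type = type)
    }
  }
  out[order(out$region, out$definition_id), ]
}

#' Flag heat-wave days for one definition on one regional series
#'
#' A day exceeds when its metric value is strictly greater than the
#' threshold. Single-day definitions flag every exceedance day. k+ duration
#' definitions flag exactly the days belonging to a maximal run of
#' consecutive exceedance days of length >= k. Runs break at missing values
#' and wherever consecutive rows are not consecutive calendar dates (so
#' exposure never accumulates across the off-season gap between summers,
#' while month boundaries inside a summer are seamless).
#'
#' @param dates ordered `Date` vector of the study window.
#' @param values metric values (degC) aligned with `dates`.
#' @param definition a single-row definition (see [standard_definitions()]).
#' @param threshold resolved threshold in degC.
#' @return integer 0/1 vector of flags, same length as `dates`.
#' @export
flag_days <- function(dates, values, definition, threshold) {
  if (length(dates) != length(values)) {
    stop("dates and values differ in length")
  }
  if (is.unsorted(dates)) stop("dates must be ascending")
  exceed <- !is.na(values) & values > threshold
  k <- switch(definition$duration, "1-day" = 1L, "2+" = 2L, "3+" = 3L,
              stop("unknown duration: ", definition$duration))
  if (k == 1L) return(as.integer(exceed))
  # a calendar-date gap breaks a run even if both sides exceed
  block <- cumsum(c(1L, as.integer(diff(dates) != 1)))
  flags <- integer(length(dates))
  for (b in split(seq_along(dates), block)) {
    r <- rle(exceed[b])
    keep <- r$values & r$lengths >= k
    flags[b] <- as.integer(rep(keep, r$lengths))
  }
  flags
}

#' Flag heat-wave days for every definition and region
#'
#' @param weather study-window regional weather with derived metrics,
#'   sorted by region then date.
#' @param definitions definition table.
#' @param thresholds threshold table from [compute_thresholds()].
#' @return a list with `flags` (long `data.frame`: `region`, `date`,
#'   `definition_id`, `flag`) and `counts` (`region`, `definition_id`,
#'   `hw_days`, the flagged-day totals).
#' @export
flag_all <- function(weather, definitions = standard_definitions(),
                     thresholds) {
  weather <- weather[order(weather$region, weather$date), ]
  pieces <- list()
  for (reg in sort(unique(weather$region))) {
    w <- weather[weather$region == reg, ]
    for (i in seq_len(nrow(definitions))) {
      def <- definitions[i, ]
      th <- thresholds$threshold_c[thresholds$region == reg &
                                     thresholds$definition_id == def$id]
      if (length(th) != 1 || is.na(th)) {
        stop("no resolved threshold for definition ", def$id,
             " in region ", reg)
      }
      fl <- flag_days(w$date, w[[metric_column(def$metric)]], def, th)
      pieces[[paste(reg, def$id)]] <- data.frame(
        region = reg, date = w$date, definition_id = def$id, flag = fl,
        stringsAsFactors = FALSE
      )
    }
  }
  flags <- do.call(rbind, pieces)
  rownames(flags) <- NULL
  counts <- stats::aggregate(flag ~ region + definition_id, flags, sum)
  names(counts)[names(counts) == "flag"] <- "hw_days"
  counts <- counts[order(counts$region, counts$definition_id), ]
  rownames(counts) <- NULL
  list(flags = flags, counts = counts)
}
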