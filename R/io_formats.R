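#' Read a daily station weather CSV
#'
#' Reads a GHCN-D-like CSV of daily station observations. Expected columns
#' (renameable through `schema`): `date`, `station_id`, `region`, `tmin`,
#' `tmax`, `tmean`, `dewpoint`. Temperatures are degrees Celsius; dates are
#' ISO-8601. Unparseable numeric cells become `NA`; rows are returned sorted
#' by date then station.
#'
#' @param path path to a CSV file with a header row.
#' @param schema named character vector mapping canonical column names to the
#'   names used in the file, e.g. `c(tmax = "TMAX")`. Unmapped columns keep
#'   their canonical names.
#' @return a `data.frame` with columns `date` (`Date`), `station_id`,
#'   `region` (character), `tmin`, `tmax`, `tmean`, `dewpoint` (numeric).
#' @export
read_daily_weather <- function(path, schema = NULL) {
  canonical <- c("date", "station_id", "region", "tmin", "tmax", "tmean",
                 "dewpoint")
  df <- read_csv_checked(path, canonical, schema)
  df$date <- as.Date(df$date)
  for (col in c("tmin", "tmax", "tmean", "dewpoint")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$station_id <- as.character(df$station_id)
  df$region <- as.character(df$region)
  key <- paste(df$station_id, df$date)
  if (anyDuplicated(key)) {
    stop("duplicate (station, date) records: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  df <- df[order(df$date, df$station_id), canonical]
  rownames(df) <- NULL
  df
}

#' Read an HRI daily count CSV
#'
#' Columns `date`, `region`, `count` and optionally `censored`
#' (logical/0-1); a missing `censored` column means no day is censored.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` with `date`, `region`, `count`, `censored`.
#' @export
read_hri <- function(path) {
  df <- read_csv_checked(path, c("date", "region", "count"))
  df$date <- as.Date(df$date)
  df$region <- as.character(df$region)
  df$count <- suppressWarnings(as.numeric(df$count))
  df$censored <- if ("censored" %in% names(df)) {
    as.logical(df$censored) %in% TRUE
  } else {
    FALSE
  }
  df <- df[order(df$region, df$date),
           c("date", "region", "count", "censored")]
  rownames(df) <- NULL
  df
}

#' Read an NWS heat-product interval CSV
#'
#' Columns: `start_date`, `end_date` (inclusive), `county`, `product`
#' (`advisory` or `excessive_heat_warning`).
#'
#' @param path path to a CSV file.
#' @return a `data.frame` of alert intervals.
#' @export
read_alerts <- function(path) {
  df <- read_csv_checked(path, c("start_date", "end_date", "county",
                                 "product"))
  df$start_date <- as.Date(df$start_date)
  df$end_date <- as.Date(df$end_date)
  if (any(df$start_date > df$end_date)) {
    stop("alert interval with start_date after end_date")
  }
  bad <- setdiff(unique(df$product), c("advisory", "excessive_heat_warning"))
  if (length(bad)) {
    stop("unknown alert product(s): ", paste(bad, collapse = ", "))
  }
  df
}

#' Read a county-to-region mapping CSV
#'
#' @param path path to a CSV with columns `county`, `region`.
#' @return a named character vector: `map["county"]` is its region.
#' @export
read_region_map <- function(path) {
  df <- read_csv_checked(path, c("county", "region"))
  stats::setNames(as.character(df$region), as.character(df$county))
}

read_csv_checked <- function(path, required, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(df)) {
        names(df)[names(df) == schema[[canon]]] <- canon
      }
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Aggregate station-day records to regional daily weather
#'
#' For each (region, date), every weather field is the unweighted arithmetic
#' mean over the stations reporting that field that day; a field no station
#' reports is `NA`. Station order is irrelevant.
#'
#' @param records a `data.frame` as from [read_daily_weather()].
#' @return a `data.frame` with one row per (region, date) and columns
#'   `region`, `date`, `tmin`, `tmax`, `tmean`, `dewpoint`, sorted by region
#'   then date.
#' @export
aggregate_to_region <- function(records) {
  fields <- c("tmin", "tmax", "tmean", "dewpoint")
  out_cols <- c("region", "date", fields)
  if (nrow(records) == 0) {
    out <- records[, intersect(out_cols, names(records)), drop = FALSE]
    for (f in setdiff(out_cols, names(out))) out[[f]] <- numeric(0)
    return(out[, out_cols])
  }
  if (any(is.na(records$region) | records$region == "")) {
    stop("every station record must carry a region label")
  }
  mean_or_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  }
  agg <- stats::aggregate(records[fields],
                          by = list(region = records$region,
                                    date = records$date),
                          FUN = mean_or_na)
  agg <- agg[order(agg$region, agg$date), out_cols]
  rownames(agg) <- NULL
  agg
}

#' Expand alert intervals into daily regional flags
#'
#' A region-day is flagged 1 iff at least one interval, mapped through a
#' county in that region, covers the day (both endpoints inclusive). Both
#' advisories and excessive heat warnings count; overlapping intervals still
#' give a binary flag.
#'
#' @param intervals alert intervals as from [read_alerts()] (may have 0 rows).
#' @param region_map named character vector, county -> region.
#' @param window a vector of `Date`s defining the study window, in order.
#' @return a `data.frame` with columns `region`, `date`, `flag` (0/1),
#'   covering every region in `region_map`'s range for every window day.
#' @export
expand_alerts <- function(intervals, region_map, window) {
  if (length(window) == 0) stop("study window is empty")
  regions <- sort(unique(unname(region_map)))
  out <- expand.grid(date = window, region = regions,
                     stringsAsFactors = FALSE)
  out <- out[, c("region", "date")]
  out$flag <- 0L
  if (nrow(intervals) > 0) {
    unmapped <- setdiff(unique(intervals$county), names(region_map))
    if (length(unmapped)) {
      stop("county not in region map: ", paste(unmapped, collapse = ", "))
    }
    for (i in seq_len(nrow(intervals))) {
      days <- seq(intervals$start_date[i], intervals$end_date[i], by = "day")
      reg <- region_map[[intervals$county[i]]]
      hit <- out$region == reg & out$date %in% days
      out$flag[hit] <- 1L
    }
  }
  out <- out[order(out$region, out$date), ]
  rownames(out) <- NULL
  out
}

#' Write model-fit results to a tidy CSV
#'
#' One row per (region, definition): the definition descriptor, resolved
#' threshold, flagged-day count, rate ratio with 95% CI, AIC and dispersion.
#'
#' @param fits a `data.frame` of results, as produced by [fit_all_definitions()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_results <- function(fits, path) {
  if (is.null(fits) || nrow(fits) == 0) stop("no fits to write")
  cols <- c("region", "definition_id", "metric", "duration", "threshold_type",
            "intensity", "threshold_c", "hw_days", "rr", "ci_lo", "ci_hi",
            "aic", "theta")
  missing <- setdiff(cols, names(fits))
  if (length(missing)) {
    stop("fits table lacks column(s): ", paste(missing, collapse = ", "))
  }
  utils::write.csv(fits[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param path path to the CSV.
#' @return a `data.frame` with the stable results column set.
#' @export
read_results <- function(path) {
  read_csv_checked(path, c("region", "definition_id", "rr", "aic"))
}
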