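# Brute-force flagging oracle: a day is flagged iff it lies inside some
# window of k consecutive exceedance days (consecutive calendar dates, no
# missing values). Independent of the rle-based implementation.
flag_days_bruteforce <- function(dates, values, k, threshold) {
  n <- length(dates)
  exceed <- !is.na(values) & values > threshold
  flags <- integer(n)
  for (j in seq_len(n - k + 1)) {
    idx <- j:(j + k - 1)
    consecutive <- all(diff(as.integer(dates[idx])) == 1)
    if (consecutive && all(exceed[idx])) flags[idx] <- 1L
  }
  flags
}

# Random daily series with occasional date gaps and missing values
random_series <- function(n_max = 60) {
  n <- sample(5:n_max, 1)
  gaps <- cumsum(sample(c(1, 1, 1, 1, 5), n - 1, replace = TRUE))
  dates <- as.Date("2015-06-01") + c(0, gaps)
  values <- round(stats::rnorm(n, 30, 3), 1)
  values[stats::runif(n) < 0.08] <- NA
  list(dates = dates, values = values)
}

# A small deterministic station-day weather table written to a temp CSV
write_weather_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  path
}

fast_config <- function(seed = 1L, baseline_years = 30L, ...) {
  synthetic_config(seed = seed, baseline_years = baseline_years, ...)
}
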