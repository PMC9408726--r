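#' Configuration for the synthetic study generator
#'
#' Defaults emulate the study conditions the pipeline is designed for: two
#' physiographic regions, five summer seasons (1 May–30 Sep) of daily
#' weather with a mid-July seasonal peak and AR(1) day-to-day persistence, a
#' 120-year baseline climatology for percentile thresholds (the study era
#' sits a warm offset above it, so moderate-percentile definitions flag a
#' realistic 25–35% of study days), sparse NWS-style alerts on ~2.5% of
#' days, and negative-binomial daily counts generated from the count-model
#' linear predictor with a known heat-wave rate ratio of 2.75 and
#' left-censoring below 5 visits.
#'
#' @param seed master seed; each generation stage derives its own stream
#'   from it by a fixed label, so stages never perturb each other.
#' @param regions region names.
#' @param study_years calendar years of the study summers.
#' @param baseline_years number of climatology years preceding the study.
#' @param peak_tmax seasonal peak of mean daily maximum temperature, degC
#'   (mid-July).
#' @param amplitude seasonal half-range, degC: the seasonal mean falls this
#'   far below `peak_tmax` in midwinter.
#' @param phi AR(1) coefficient of the regional daily anomaly, in (-1, 1).
#' @param noise_sd AR(1) innovation standard deviation, degC.
#' @param warm_offset degC added to study-era temperatures relative to the
#'   baseline climatology era (secular warming; makes percentile
#'   exceedances common in the study years, as observed).
#' @param station_sd per-station measurement noise sd, degC.
#' @param stations_per_region number of stations per region.
#' @param diurnal_mean,diurnal_sd daily tmax - tmin range, degC.
#' @param dew_deficit_mean mean of the (gamma-distributed) tmax - dewpoint
#'   deficit, degC.
#' @param true_definition id of the definition whose flags drive counts.
#' @param beta0 intercept of the count model (log rate per person-day).
#' @param beta_hw log rate ratio of a heat-wave day (default log 2.75).
#' @param beta_rh,beta_nws,beta_weekend remaining coefficients.
#' @param beta_month named log effects for Jun–Sep (May = reference).
#' @param beta_year numeric vector of log year effects (first year =
#'   reference; recycled/truncated to the number of study years).
#' @param theta NB2 dispersion of the daily counts.
#' @param population named per-region populations for the offset.
#' @param censor_cutoff counts strictly below this are suppressed.
#' @param impute_value imputation constant for suppressed counts.
#' @param alert_target target fraction of study days with an NWS alert.
#' @return a list of class `hwd_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             regions = c("Coastal", "Piedmont"),
                             study_years = c(2011, 2012, 2014, 2015, 2016),
                             baseline_years = 120L,
                             peak_tmax = 33,
                             amplitude = 14,
                             phi = 0.7,
                             noise_sd = 2.2,
                             warm_offset = 2.5,
                             station_sd = 0.8,
                             stations_per_region = 2L,
                             diurnal_mean = 9,
                             diurnal_sd = 1.2,
                             dew_deficit_mean = 7,
                             true_definition = "HW_15",
                             beta0 = log(5.0e-6),
                             beta_hw = log(2.75),
                             beta_rh = 0,
                             beta_nws = 0.05,
                             beta_weekend = 0.05,
                             beta_month = c(Jun = 0.10, Jul = 0.20,
                                            Aug = 0.15, Sep = 0.00),
                             beta_year = c(0, 0.05, -0.05, 0.10, 0.05),
                             theta = 5,
                             population = c(Coastal = 1e6,
                                            Piedmont = 1.3e6),
                             censor_cutoff = 5,
                             impute_value = 3,
                             alert_target = 0.025) {
  if (abs(phi) >= 1) stop("AR(1) coefficient must be in (-1, 1)")
  if (theta <= 0) stop("theta must be positive")
  if (any(population[regions] <= 0) || any(is.na(population[regions]))) {
    stop("every region needs a positive population")
  }
  structure(as.list(environment()), class = "hwd_config")
}

# one reproducible stream per stage, derived from the master seed
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + sum(utf8ToInt(stage)) %% 1009L
}

#' Summer-season dates for a set of years
#'
#' @param years calendar years.
#' @return `Date` vector of all days from 1 May to 30 Sep in each year.
#' @export
summer_dates <- function(years) {
  do.call(c, lapply(sort(years), function(y) {
    seq(as.Date(sprintf("%d-05-01", y)), as.Date(sprintf("%d-09-30", y)),
        by = "day")
  }))
}

#' Simulate station-day weather for the baseline era and study years
#'
#' Regional daily maximum temperature is a seasonal sinusoid (peak mid-July)
#' plus a seasonally-restarted AR(1) anomaly; study-era days additionally
#' get the configured warm offset. Stations observe the regional value plus
#' independent noise; tmin is tmax minus a positive diurnal range, tmean the
#' midpoint, and dewpoint tmax minus a gamma-distributed deficit. Identical
#' seeds give identical output.
#'
#' @param config an [synthetic_config()] object.
#' @return a station-day `data.frame` (columns as [read_daily_weather()])
#'   covering all baseline and study summers.
#' @export
simulate_weather <- function(config) {
  set.seed(stage_seed(config$seed, "weather"))
  first <- min(config$study_years)
  baseline_yrs <- seq(first - config$baseline_years, first - 1)
  years <- c(baseline_yrs, sort(config$study_years))
  out <- list()
  for (reg in config$regions) {
    for (y in years) {
      dates <- summer_dates(y)
      nd <- length(dates)
      doy <- as.integer(format(dates, "%j"))
      seasonal <- config$peak_tmax -
        config$amplitude * (1 - cos(2 * pi * (doy - 196) / 365.25)) / 2
      if (y %in% config$study_years) seasonal <- seasonal + config$warm_offset
      # AR(1) anomaly restarted each season, stationary start
      anom <- numeric(nd)
      marg_sd <- config$noise_sd / sqrt(1 - config$phi^2)
      anom[1] <- stats::rnorm(1, 0, marg_sd)
      if (nd > 1) {
        innov <- stats::rnorm(nd - 1, 0, config$noise_sd)
        for (i in 2:nd) anom[i] <- config$phi * anom[i - 1] + innov[i - 1]
      }
      tmax_reg <- seasonal + anom
      deficit <- stats::rgamma(nd, shape = 4,
                               rate = 4 / config$dew_deficit_mean)
      dew_reg <- tmax_reg - deficit
      for (s in seq_len(config$stations_per_region)) {
        tmax <- tmax_reg + stats::rnorm(nd, 0, config$station_sd)
        rng <- pmax(stats::rnorm(nd, config$diurnal_mean,
                                 config$diurnal_sd), 2)
        tmin <- tmax - rng
        out[[paste(reg, y, s)]] <- data.frame(
          date = dates,
          station_id = sprintf("%s_ST%02d", toupper(substr(reg, 1, 3)), s),
          region = reg,
          tmin = tmin, tmax = tmax, tmean = (tmax + tmin) / 2,
          dewpoint = pmin(dew_reg, tmax),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$date, df$station_id), ]
  rownames(df) <- NULL
  df
}

#' Simulate sparse NWS-style heat alerts from generated weather
#'
#' Alerts are issued, per region, on study days whose maximum apparent
#' temperature exceeds the (1 - target) empirical quantile; consecutive
#' alert days are grouped into advisory intervals attributed to a synthetic
#' county of the region.
#'
#' @param weather regional study-window weather with derived `at_max`.
#' @param config an [synthetic_config()] object.
#' @return a list: `intervals` (alert interval `data.frame`) and
#'   `region_map` (named vector, synthetic county -> region).
#' @export
simulate_alerts <- function(weather, config) {
  intervals <- list()
  counties <- character(0)
  for (reg in config$regions) {
    w <- weather[weather$region == reg, ]
    w <- w[order(w$date), ]
    county <- paste0(reg, "_County_1")
    counties[county] <- reg
    at <- w$at_max
    thr <- stats::quantile(at, 1 - config$alert_target, na.rm = TRUE,
                           type = 7)
    hot <- !is.na(at) & at > thr
    if (!any(hot)) next
    d <- w$date[hot]
    brk <- cumsum(c(1L, as.integer(diff(d) != 1)))
    for (g in split(d, brk)) {
      intervals[[length(intervals) + 1L]] <- data.frame(
        start_date = min(g), end_date = max(g), county = county,
        product = "advisory", stringsAsFactors = FALSE
      )
    }
  }
  intervals <- if (length(intervals)) {
    do.call(rbind, intervals)
  } else {
    data.frame(start_date = as.Date(character(0)),
               end_date = as.Date(character(0)),
               county = character(0), product = character(0),
               stringsAsFactors = FALSE)
  }
  list(intervals = intervals, region_map = counties)
}

#' Simulate daily HRI counts from the count-model linear predictor
#'
#' Counts are NB2 draws with
#' log mu = beta0 + beta_hw HW + beta_rh RH + beta_nws NWS +
#' beta_weekend weekend + month + year effects + log(population).
#'
#' @param data per-region `data.frame` with `date`, `hw`, `rh`, `nws`.
#' @param region region name (selects the population).
#' @param config an [synthetic_config()] object.
#' @return `data.frame` `date`, `region`, `count` of raw (uncensored)
#'   counts.
#' @export
simulate_counts <- function(data, region, config) {
  set.seed(stage_seed(config$seed, paste0("counts_", region)))
  mo <- month.abb[as.integer(format(data$date, "%m"))]
  yr <- as.integer(format(data$date, "%Y"))
  yrs <- sort(unique(c(config$study_years, yr)))
  byear <- rep_len(config$beta_year, length(yrs))
  byear[1] <- 0
  names(byear) <- as.character(yrs)
  bmonth <- c(May = 0, config$beta_month)
  weekend <- as.integer(format(data$date, "%u") %in% c("6", "7"))
  eta <- config$beta0 + config$beta_hw * data$hw +
    config$beta_rh * data$rh + config$beta_nws * data$nws +
    config$beta_weekend * weekend +
    unname(bmonth[mo]) + unname(byear[as.character(yr)]) +
    log(config$population[[region]])
  mu <- exp(eta)
  data.frame(date = data$date, region = region,
             count = stats::rnbinom(length(mu), size = config$theta,
                                    mu = mu),
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study dataset
#'
#' Runs all three generators and the intermediate derivations: station
#' weather (baseline + study), regional aggregation and metric derivation,
#' alerts, heat-wave flags under the configured true definition, NB2
#' counts, and surveillance censoring.
#'
#' @param config an [synthetic_config()] object.
#' @return a list: `stations` (station-days), `weather_baseline` and
#'   `weather_study` (regional daily weather with derived metrics),
#'   `alerts`, `region_map`, `nws` (expanded daily alert flags),
#'   `true_flags` (daily flags of the true definition), `hri_raw`
#'   (uncensored counts), `hri` (censored counts, censored flags set, not
#'   yet imputed), and `config`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stations <- simulate_weather(config)
  regional <- aggregate_to_region(stations)
  regional <- derive_metrics(regional)
  study_dates <- summer_dates(config$study_years)
  in_study <- regional$date %in% study_dates
  weather_study <- regional[in_study, ]
  weather_baseline <- regional[!in_study, ]
  alerts <- simulate_alerts(weather_study, config)
  nws <- expand_alerts(alerts$intervals, alerts$region_map, study_dates)
  defs <- standard_definitions()
  true_def <- defs[defs$id == config$true_definition, ]
  if (nrow(true_def) != 1) {
    stop("unknown true_definition: ", config$true_definition)
  }
  thresholds <- compute_thresholds(weather_baseline, true_def)
  fl <- flag_all(weather_study, true_def, thresholds)
  counts <- list()
  for (reg in config$regions) {
    d <- merge(
      fl$flags[fl$flags$region == reg, c("date", "flag")],
      weather_study[weather_study$region == reg, c("date", "rh")],
      by = "date"
    )
    names(d)[names(d) == "flag"] <- "hw"
    d <- merge(d, stats::setNames(nws[nws$region == reg,
                                      c("date", "flag")],
                                  c("date", "nws")), by = "date")
    d <- d[order(d$date), ]
    counts[[reg]] <- simulate_counts(d, reg, config)
  }
  hri_raw <- do.call(rbind, counts)
  rownames(hri_raw) <- NULL
  hri <- apply_censoring(hri_raw, cutoff = config$censor_cutoff)
  hri$count[hri$censored] <- NA  # the surveillance product suppresses them
  list(stations = stations, weather_baseline = weather_baseline,
       weather_study = weather_study, alerts = alerts$intervals,
       region_map = alerts$region_map, nws = nws,
       true_flags = fl$flags, hri_raw = hri_raw, hri = hri,
       config = config)
}
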