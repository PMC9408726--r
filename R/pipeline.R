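#' Pipeline stage commands
#'
#' Each `cmd_*` function is one stage of the analysis, reading its inputs
#' from and writing plain CSV outputs to a working directory, so every
#' intermediate is independently inspectable. [run_pipeline()] chains them.
#' All stages are deterministic given the seed recorded in the manifest.
#'
#' @name pipeline
NULL

write_manifest <- function(dir, stage, config) {
  cfg_json <- jsonlite::toJSON(config[!vapply(config, is.function,
                                              logical(1))],
                               auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  tmp <- file.path(dir, ".config.json")
  writeLines(cfg_json, tmp)
  manifest <- list(
    stage = stage,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("hwdsens")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, paste0("manifest_", stage, ".json")))
  invisible(manifest)
}

require_upstream <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing input ", path, "; run ", producer, " first")
  }
  path
}

#' @describeIn pipeline generate a synthetic dataset directory (weather,
#'   alerts, region map, censored HRI counts).
#' @param config an [synthetic_config()] object.
#' @param dir working directory for stage inputs/outputs.
#' @export
cmd_simulate <- function(config = synthetic_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_dataset(config)
  utils::write.csv(ds$stations, file.path(dir, "weather.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$alerts, file.path(dir, "alerts.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(county = names(ds$region_map),
                              region = unname(ds$region_map)),
                   file.path(dir, "region_map.csv"), row.names = FALSE)
  utils::write.csv(ds$hri[, c("date", "region", "count", "censored")],
                   file.path(dir, "hri.csv"), row.names = FALSE)
  write_manifest(dir, "simulate", config)
  invisible(dir)
}

load_weather_stage <- function(config, dir) {
  path <- require_upstream(file.path(dir, "weather.csv"), "cmd_simulate")
  stations <- read_daily_weather(path)
  regional <- derive_metrics(aggregate_to_region(stations))
  study_dates <- summer_dates(config$study_years)
  list(study = regional[regional$date %in% study_dates, ],
       baseline = regional[!regional$date %in% study_dates, ],
       study_dates = study_dates)
}

#' @describeIn pipeline compute per-region percentile thresholds for every
#'   definition from the baseline climatology; writes `thresholds.csv`.
#' @export
cmd_thresholds <- function(config = synthetic_config(), dir) {
  w <- load_weather_stage(config, dir)
  th <- compute_thresholds(w$baseline, standard_definitions())
  utils::write.csv(th, file.path(dir, "thresholds.csv"), row.names = FALSE)
  write_manifest(dir, "thresholds", config)
  invisible(th)
}

#' @describeIn pipeline flag heat-wave days for all definitions; writes
#'   `flags.csv` and `flag_counts.csv`.
#' @export
cmd_flag <- function(config = synthetic_config(), dir) {
  w <- load_weather_stage(config, dir)
  thp <- require_upstream(file.path(dir, "thresholds.csv"),
                          "cmd_thresholds")
  th <- utils::read.csv(thp, stringsAsFactors = FALSE)
  fl <- flag_all(w$study, standard_definitions(), th)
  utils::write.csv(fl$flags, file.path(dir, "flags.csv"),
                   row.names = FALSE)
  utils::write.csv(fl$counts, file.path(dir, "flag_counts.csv"),
                   row.names = FALSE)
  write_manifest(dir, "flag", config)
  invisible(fl)
}

#' @describeIn pipeline fit the count model per definition and region,
#'   rank by AIC; writes `results.csv` and `optimal.csv`.
#' @export
cmd_fit <- function(config = synthetic_config(), dir) {
  w <- load_weather_stage(config, dir)
  flp <- require_upstream(file.path(dir, "flags.csv"), "cmd_flag")
  flags <- utils::read.csv(flp, stringsAsFactors = FALSE)
  flags$date <- as.Date(flags$date)
  th <- utils::read.csv(require_upstream(file.path(dir, "thresholds.csv"),
                                         "cmd_thresholds"),
                        stringsAsFactors = FALSE)
  hri <- read_hri(require_upstream(file.path(dir, "hri.csv"),
                                   "cmd_simulate"))
  hri <- impute_censored(hri, config$impute_value)
  alerts <- read_alerts(require_upstream(file.path(dir, "alerts.csv"),
                                         "cmd_simulate"))
  region_map <- read_region_map(require_upstream(
    file.path(dir, "region_map.csv"), "cmd_simulate"))
  nws <- expand_alerts(alerts, region_map, w$study_dates)
  res <- fit_all_definitions(flags, w$study, nws, hri,
                             standard_definitions(), th,
                             config$population)
  write_results(res, file.path(dir, "results.csv"))
  opt <- do.call(rbind, lapply(split(res, res$region), function(r) {
    rk <- rank_definitions(r[, c("definition_id", "aic")])
    data.frame(region = r$region[1], optimal = rk$optimal,
               aic = rk$ranking$aic[1], stringsAsFactors = FALSE)
  }))
  utils::write.csv(opt, file.path(dir, "optimal.csv"), row.names = FALSE)
  write_manifest(dir, "fit", config)
  invisible(res)
}

#' @describeIn pipeline McNemar comparison of each region's AIC-optimal
#'   definition against NWS alert days; writes `comparison.csv`.
#' @param continuity apply the McNemar continuity correction.
#' @export
cmd_compare <- function(config = synthetic_config(), dir,
                        continuity = TRUE) {
  w <- load_weather_stage(config, dir)
  flags <- utils::read.csv(require_upstream(file.path(dir, "flags.csv"),
                                            "cmd_flag"),
                           stringsAsFactors = FALSE)
  flags$date <- as.Date(flags$date)
  opt <- utils::read.csv(require_upstream(file.path(dir, "optimal.csv"),
                                          "cmd_fit"),
                         stringsAsFactors = FALSE)
  alerts <- read_alerts(file.path(dir, "alerts.csv"))
  region_map <- read_region_map(file.path(dir, "region_map.csv"))
  nws <- expand_alerts(alerts, region_map, w$study_dates)
  sel <- stats::setNames(opt$optimal, opt$region)
  cmp <- compare_with_alerts(flags, nws, sel, continuity = continuity)
  utils::write.csv(cmp, file.path(dir, "comparison.csv"),
                   row.names = FALSE)
  write_manifest(dir, "compare", config)
  invisible(cmp)
}

#' Run the full pipeline in one call
#'
#' simulate -> thresholds -> flag -> fit -> compare, in a working
#' directory. With fixed seed and config every output is reproduced
#' byte-for-byte.
#'
#' @param config an [synthetic_config()] object.
#' @param dir working directory (created if needed).
#' @param continuity McNemar continuity correction.
#' @return invisibly, a list with `results`, `optimal`, `comparison`.
#' @export
run_pipeline <- function(config = synthetic_config(),
                         dir = tempfile("hwdsens_run_"),
                         continuity = TRUE) {
  cmd_simulate(config, dir)
  cmd_thresholds(config, dir)
  cmd_flag(config, dir)
  res <- cmd_fit(config, dir)
  cmp <- cmd_compare(config, dir, continuity = continuity)
  opt <- utils::read.csv(file.path(dir, "optimal.csv"),
                         stringsAsFactors = FALSE)
  invisible(list(dir = dir, results = res, optimal = opt,
                 comparison = cmp))
}
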