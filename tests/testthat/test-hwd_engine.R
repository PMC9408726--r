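test_that("the standard grammar has the 28 expected definitions", {
  defs <- standard_definitions()
  expect_equal(nrow(defs), 28)
  expect_equal(defs$id, sprintf("HW_%02d", 1:28))
  hw15 <- defs[defs$id == "HW_15", ]
  expect_equal(hw15$metric, "max")
  expect_equal(hw15$duration, "2+")
  expect_equal(hw15$threshold_type, "relative")
  expect_equal(hw15$intensity, 90)
  hw17 <- defs[defs$id == "HW_17", ]
  expect_equal(unlist(hw17[, c("metric", "duration", "threshold_type")]),
               c(metric = "max", duration = "1-day",
                 threshold_type = "absolute"))
  expect_equal(hw17$intensity, 35)
  app <- defs[defs$metric == "apparent_max", ]
  expect_equal(app$id, c("HW_26", "HW_27", "HW_28"))
  expect_equal(app$intensity, c(95, 90, 85))
  expect_true(all(app$duration == "1-day"))
  # metric families
  expect_true(all(defs$metric[1:8] == "mean"))
  expect_true(all(defs$metric[18:25] == "min"))
})

test_that("percentile thresholds use order-statistic interpolation", {
  expect_equal(compute_threshold(rep(30, 50), 95), 30)
  expect_equal(compute_threshold(1:100, 90), 90.1)
  expect_equal(compute_threshold(c(1, 2, 3, 4, 5), 50), 3)
  expect_equal(compute_threshold(c(NA, 1:100, NA), 90), 90.1)
  expect_error(compute_threshold(c(NA_real_, NA_real_), 90), "empty")
  # non-decreasing in percentile for a fixed baseline
  set.seed(1)
  x <- rnorm(500, 30, 3)
  th <- vapply(c(85, 90, 95, 98, 99), compute_threshold, numeric(1),
               baseline = x)
  expect_true(all(diff(th) >= 0))
})

test_that("run-length flagging honours duration, strictness and gaps", {
  defs <- standard_definitions()
  d2 <- defs[defs$id == "HW_15", ]  # 2+
  d3 <- defs[defs$id == "HW_16", ]  # 3+
  d1 <- defs[defs$id == "HW_17", ]  # 1-day
  dates <- as.Date("2011-07-01") + 0:4
  vals <- c(30, 33, 33, 30, 33)
  expect_equal(flag_days(dates, vals, d2, 32), c(0, 1, 1, 0, 0))
  expect_equal(flag_days(dates, vals, d3, 32), rep(0, 5))
  # strict inequality: a day exactly at the threshold is not an exceedance
  expect_equal(flag_days(dates[1], 35.0, d1, 35), 0L)
  expect_equal(flag_days(dates[1], 35.01, d1, 35), 1L)
  # missing values break runs and are never flagged
  expect_equal(flag_days(dates, c(33, 33, NA, 33, 33), d3, 32), rep(0, 5))
  expect_equal(flag_days(dates, c(33, 33, NA, 33, 33), d2, 32),
               c(1, 1, 0, 1, 1))
  # the off-season gap breaks runs; month boundaries inside a summer do not
  gap_dates <- c(as.Date("2011-09-29"), as.Date("2011-09-30"),
                 as.Date("2012-05-01"), as.Date("2012-05-02"))
  expect_equal(flag_days(gap_dates, rep(40, 4), d3, 32), rep(0, 4))
  may_jun <- seq(as.Date("2011-05-30"), as.Date("2011-06-02"), by = "day")
  expect_equal(flag_days(may_jun, rep(40, 4), d3, 32), rep(1, 4))
  expect_error(flag_days(dates, vals[-1], d2, 32), "length")
})

test_that("flag_days matches the brute-force window oracle", {
  defs <- standard_definitions()
  set.seed(42)
  for (rep_i in 1:60) {
    s <- random_series()
    th <- sample(c(28, 30, 32), 1)
    for (k in 1:3) {
      def <- defs[match(c("HW_17", "HW_15", "HW_16"), defs$id)[k], ]
      expect_equal(flag_days(s$dates, s$values, def, th),
                   flag_days_bruteforce(s$dates, s$values, k, th),
                   info = sprintf("replicate %d, k = %d", rep_i, k))
    }
  }
})

test_that("flag_all respects subset and monotonicity structure", {
  cfg <- fast_config(seed = 3)
  ds <- simulate_dataset(cfg)
  defs <- standard_definitions()
  th <- compute_thresholds(ds$weather_baseline, defs)
  fl <- flag_all(ds$weather_study, defs, th)
  counts <- fl$counts
  getf <- function(id, reg) {
    fl$flags$flag[fl$flags$definition_id == id & fl$flags$region == reg]
  }
  for (reg in cfg$regions) {
    # 3+ runs are a subset of 2+ runs, pointwise
    expect_true(all(getf("HW_16", reg) <= getf("HW_15", reg)))
    expect_true(all(getf("HW_08", reg) <= getf("HW_07", reg)))
    # higher percentile flags a subset, pointwise (same metric/duration)
    expect_true(all(getf("HW_13", reg) <= getf("HW_15", reg)))  # 95 vs 90
    expect_true(all(getf("HW_09", reg) <= getf("HW_11", reg)))  # 99 vs 98
    # counts equal pointwise sums
    for (id in c("HW_07", "HW_15", "HW_26")) {
      expect_equal(counts$hw_days[counts$region == reg &
                                    counts$definition_id == id],
                   sum(getf(id, reg)))
    }
  }
  # thresholds non-decreasing in percentile for fixed metric
  th_max <- th[th$region == "Coastal" &
                 th$definition_id %in% c("HW_15", "HW_13", "HW_11", "HW_09"), ]
  expect_true(all(diff(th_max$threshold_c[order(-as.integer(
    substr(th_max$definition_id, 4, 5)))]) >= 0))
})

test_that("an all-cold series yields zero flags for every definition", {
  cfg <- fast_config(seed = 4)
  ds <- simulate_dataset(cfg)
  cold <- ds$weather_study
  for (col in c("tmean", "tmax", "tmin", "at_max")) cold[[col]] <- -10
  defs <- standard_definitions()
  th <- compute_thresholds(ds$weather_baseline, defs)
  fl <- flag_all(cold, defs, th)
  expect_true(all(fl$counts$hw_days == 0))
})
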