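make_study_frame <- function(n_years = 5, seed = 1) {
  set.seed(seed)
  yrs <- c(2011, 2012, 2014, 2015, 2016)[seq_len(n_years)]
  dates <- summer_dates(yrs)
  data.frame(date = dates,
             count = rpois(length(dates), 6),
             hw = rbinom(length(dates), 1, 0.27),
             rh = runif(length(dates), 40, 100),
             nws = rbinom(length(dates), 1, 0.025))
}

test_that("design matrix has the documented column structure", {
  d <- make_study_frame()
  des <- build_design(d, population = 1e6, include_rh = TRUE)
  # intercept + hw + rh + nws + weekend + 4 month + 4 year dummies
  expect_equal(ncol(des$X), 13)
  expect_equal(colnames(des$X)[1:5],
               c("(Intercept)", "hw", "rh", "nws", "weekend"))
  expect_true(all(grepl("^month", colnames(des$X)[6:9])))
  expect_true(all(grepl("^year", colnames(des$X)[10:13])))
  # May and the first year are reference levels (no dummy)
  expect_false(any(grepl("May|2011", colnames(des$X))))
  # apparent-temperature plan omits humidity
  des2 <- build_design(d, population = 1e6, include_rh = FALSE)
  expect_equal(ncol(des2$X), 12)
  expect_false("rh" %in% colnames(des2$X))
  # offset is the log population
  expect_equal(unique(des$offset), log(1e6))
  # a missing covariate drops exactly that row
  d$rh[10] <- NA
  des3 <- build_design(d, population = 1e6, include_rh = TRUE)
  expect_equal(nrow(des3$X), nrow(des$X) - 1)
  expect_equal(des3$n_dropped, 1)
  expect_error(build_design(rbind(d, d[1, ]), 1e6), "duplicates")
  expect_error(build_design(d, population = 0), "positive")
})

test_that("weekend indicator marks Saturdays and Sundays", {
  d <- make_study_frame(n_years = 2)
  des <- build_design(d, population = 1e6)
  # 2011-07-02 was a Saturday, 2011-07-04 a Monday
  i_sat <- which(d$date == as.Date("2011-07-02"))
  i_mon <- which(d$date == as.Date("2011-07-04"))
  expect_equal(unname(des$X[i_sat, "weekend"]), 1)
  expect_equal(unname(des$X[i_mon, "weekend"]), 0)
})

test_that("intercept-only NB fit recovers the closed-form mean", {
  n <- 200
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  y <- rep(7L, n)
  fit <- fit_nb(X, y, offset = rep(log(1e5), n))
  expect_equal(unname(fit$coefficients[1]), log(7 / 1e5), tolerance = 1e-6)
  # internal consistency of the information criterion
  expect_equal(fit$aic, 2 * fit$df - 2 * fit$loglik, tolerance = 1e-10)
})

test_that("NB fit agrees with the reference implementation (MASS)", {
  skip_if_not_installed("MASS")
  set.seed(11)
  for (rep_i in 1:3) {
    n <- 400
    X <- cbind("(Intercept)" = 1, hw = rbinom(n, 1, 0.3),
               rh = runif(n, 40, 100))
    beta <- c(-11.8, log(2.5), 0.004)
    off <- rep(log(1e6), n)
    y <- rnbinom(n, size = 4, mu = exp(drop(X %*% beta) + off))
    fit <- fit_nb(X, y, off)
    ref <- MASS::glm.nb(y ~ hw + rh + offset(off),
                        data = data.frame(y = y, hw = X[, "hw"],
                                          rh = X[, "rh"], off = off))
    expect_equal(unname(fit$coefficients), unname(coef(ref)),
                 tolerance = 1e-5)
    expect_equal(fit$theta, ref$theta, tolerance = 1e-4)
    expect_equal(fit$aic, AIC(ref), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-4)
  }
})

test_that("degenerate designs and bad counts are rejected", {
  n <- 100
  X <- cbind("(Intercept)" = 1, hw = rep(0, n))
  y <- rpois(n, 5)
  expect_error(fit_nb(X, y), "hw")
  expect_error(fit_nb(matrix(1, 3, 1), c(1, 2, 2.5)), "integers")
  expect_error(fit_nb(matrix(1, 2, 2), c(1, 2)), "more observations")
})

test_that("adding a pure-noise column never lowers the log-likelihood", {
  set.seed(21)
  n <- 300
  X <- cbind("(Intercept)" = 1, hw = rbinom(n, 1, 0.3))
  y <- rnbinom(n, size = 5, mu = exp(1.5 + 0.8 * X[, "hw"]))
  base <- fit_nb(X, y)
  for (i in 1:5) {
    noisy <- fit_nb(cbind(X, z = rnorm(n)), y)
    expect_gte(noisy$loglik, base$loglik - 1e-6)
    expect_equal(noisy$df, base$df + 1)
  }
})

test_that("rate ratios exponentiate the heat-wave coefficient", {
  fit <- structure(list(coefficients = c(hw = 0), se = c(hw = 0.1)),
                   class = "nb_fit")
  rr <- rate_ratio(fit)
  expect_equal(rr$rr, 1)
  expect_true(rr$ci_lo < 1 && rr$ci_hi > 1)
  fit$coefficients <- c(hw = 1.0116)
  fit$se <- c(hw = 0.0636)
  rr <- rate_ratio(fit)
  expect_equal(round(rr$rr, 2), 2.75)
  expect_equal(round(rr$ci_lo, 2), 2.43)
  expect_equal(round(rr$ci_hi, 2), 3.12)
  fit$coefficients <- c(hw = -0.5)
  fit$se <- c(hw = 0)
  rr <- rate_ratio(fit)
  expect_equal(c(rr$ci_lo, rr$rr, rr$ci_hi), rep(exp(-0.5), 3))
  expect_error(rate_ratio(fit, "absent"), "absent")
})

test_that("AIC ranking is ascending with lexicographic tie-break", {
  tab <- utils::read.csv(system.file("extdata", "published_model_fit.csv",
                                     package = "hwdsens"))
  coastal <- rank_definitions(setNames(tab$coastal_aic, tab$definition_id))
  expect_equal(coastal$optimal, "HW_15")
  expect_equal(coastal$ranking$aic[1], 4192.6)
  piedmont <- rank_definitions(setNames(tab$piedmont_aic,
                                        tab$definition_id))
  expect_equal(piedmont$optimal, "HW_07")
  expect_equal(piedmont$ranking$aic[1], 4547.9)
  expect_true(all(diff(coastal$ranking$aic) >= 0))
  # single fit ranks as itself; ties break by id
  expect_equal(rank_definitions(c(HW_03 = 10))$optimal, "HW_03")
  expect_equal(rank_definitions(c(HW_09 = 5, HW_02 = 5))$optimal, "HW_02")
})
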