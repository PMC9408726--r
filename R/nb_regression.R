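#' Build the design matrix for one definition's count model
#'
#' The daily HRI count model regresses counts on the heat-wave flag,
#' adjusting for relative humidity (only for plain-temperature metrics), the
#' NWS alert flag, a weekend indicator, and month and year factors, with the
#' log of the regional census population as offset. Month reference level is
#' May and the year reference is the first study year. Rows with any missing
#' covariate or count are dropped and the drop count reported.
#'
#' @param data a `data.frame` with columns `date`, `count`, `hw` (0/1),
#'   `nws` (0/1) and, when `include_rh`, `rh` (percent), all aligned on the
#'   same dates.
#' @param population regional population for the offset (> 0).
#' @param include_rh include the relative-humidity covariate (`TRUE` for
#'   temperature metrics, `FALSE` for apparent-temperature metrics).
#' @return a list: `X` (design matrix), `y` (counts), `offset`
#'   (log-population vector), `n_dropped` (rows removed for missingness).
#' @export
build_design <- function(data, population, include_rh = TRUE) {
  if (population <= 0) stop("population must be positive")
  need <- c("date", "count", "hw", "nws")
  if (include_rh) need <- c(need, "rh")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(data$date)) stop("dates are not aligned: duplicates")
  complete <- stats::complete.cases(data[, need])
  n_dropped <- sum(!complete)
  d <- data[complete, ]
  if (nrow(d) == 0) stop("no complete rows")
  # ISO weekday number is locale-independent; 6/7 = Sat/Sun
  weekend <- as.integer(format(d$date, "%u") %in% c("6", "7"))
  mo <- as.integer(format(d$date, "%m"))
  yr <- as.integer(format(d$date, "%Y"))
  mo_lev <- sort(unique(mo))
  mo_lev <- c(5, setdiff(mo_lev, 5))  # May as reference
  frame <- data.frame(
    hw = as.numeric(d$hw),
    nws = as.numeric(d$nws),
    weekend = weekend,
    month = factor(month.abb[mo], levels = month.abb[mo_lev]),
    year = factor(yr, levels = sort(unique(yr)))
  )
  if (include_rh) {
    frame <- cbind(frame[, "hw", drop = FALSE], rh = d$rh,
                   frame[, c("nws", "weekend", "month", "year")])
  }
  # a factor observed at a single level carries no information
  for (fc in c("month", "year")) {
    frame[[fc]] <- droplevels(frame[[fc]])
    if (nlevels(frame[[fc]]) < 2) frame[[fc]] <- NULL
  }
  X <- stats::model.matrix(~ ., frame)
  list(X = X, y = d$count, offset = rep(log(population), nrow(d)),
       n_dropped = n_dropped)
}

# NB2 log-likelihood at mean mu, dispersion theta
nb2_loglik <- function(y, mu, theta) {
  sum(lgamma(y + theta) - lgamma(theta) - lfactorial(y) +
        theta * log(theta) + y * log(mu) - (y + theta) * log(theta + mu))
}

#' Fit a negative binomial (NB2) GLM by maximum likelihood
#'
#' Log link, mean mu = exp(X beta + offset), variance mu + mu^2/theta.
#' Alternates iteratively reweighted least squares for the regression
#' coefficients (at fixed theta) with a one-dimensional ML update of theta,
#' until the joint log-likelihood converges. Standard errors come from the
#' expected information at the converged fit with theta held fixed, the
#' convention of the standard epidemiology toolchain. AIC counts theta as an
#' estimated parameter: AIC = 2 (p + 1) - 2 logLik.
#'
#' @param X design matrix (first column typically an intercept).
#' @param y non-negative integer counts.
#' @param offset offset vector on the log scale (default 0).
#' @param max_iter maximum outer iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return an object of class `nb_fit`: list with `coefficients`, `se`,
#'   `theta`, `loglik`, `aic`, `vcov`, `fitted`, `n`, `df`, `iterations`.
#' @export
fit_nb <- function(X, y, offset = rep(0, length(y)), max_iter = 200,
                   tol = 1e-10) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need more observations than columns")
  if (any(y < 0) || any(y != round(y))) {
    stop("counts must be non-negative integers")
  }
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop("design matrix is rank-deficient; degenerate column(s): ",
         paste(bad, collapse = ", "))
  }
  # Poisson start for beta, moment start for theta
  init <- stats::glm.fit(X, y, family = stats::poisson(), offset = offset)
  beta <- init$coefficients
  mu <- pmax(init$fitted.values, 1e-8)
  excess <- sum((y - mu)^2 - mu)
  theta <- if (excess > 0) sum(mu^2) / excess else 1e4
  theta <- min(max(theta, 1e-3), 1e6)

  irls_beta <- function(beta, theta) {
    for (it in 1:50) {
      eta <- drop(X %*% beta) + offset
      mu <- pmax(exp(eta), 1e-10)
      w <- mu / (1 + mu / theta)
      z <- (eta - offset) + (y - mu) / mu
      fit <- stats::lm.wfit(X, z, w)
      delta <- max(abs(fit$coefficients - beta))
      beta <- fit$coefficients
      if (delta < 1e-12) break
    }
    beta
  }
  ll_old <- -Inf
  trace <- numeric(0)
  for (iter in 1:max_iter) {
    beta <- irls_beta(beta, theta)
    mu <- pmax(exp(drop(X %*% beta) + offset), 1e-10)
    opt <- stats::optimize(function(lt) nb2_loglik(y, mu, exp(lt)),
                           interval = c(log(1e-4), log(1e7)),
                           maximum = TRUE, tol = 1e-10)
    theta <- exp(opt$maximum)
    ll <- nb2_loglik(y, mu, theta)
    trace <- c(trace, ll)
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
    if (iter == max_iter) {
      stop("NB2 fit did not converge in ", max_iter,
           " iterations; log-likelihood trace: ",
           paste(sprintf("%.6f", utils::tail(trace, 5)), collapse = ", "))
    }
  }
  w <- mu / (1 + mu / theta)
  info <- crossprod(X * sqrt(w))
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  names(se) <- colnames(X)
  aic <- 2 * (p + 1) - 2 * ll
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 se = se, theta = theta, loglik = ll, aic = aic,
                 vcov = vcov, fitted = mu, n = n, df = p + 1,
                 iterations = iter),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("Negative binomial (NB2) GLM fit\n")
  cat(sprintf("  n = %d, parameters = %d (incl. theta)\n", x$n, x$df))
  cat(sprintf("  theta = %.4f, logLik = %.3f, AIC = %.2f\n",
              x$theta, x$loglik, x$aic))
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Rate ratio for a fitted model term
#'
#' RR = exp(beta) with a Wald 95% interval exp(beta +/- 1.96 se).
#'
#' @param fit an `nb_fit`.
#' @param term coefficient name (default `"hw"`, the heat-wave flag).
#' @return a list with `rr`, `ci_lo`, `ci_hi`.
#' @export
rate_ratio <- function(fit, term = "hw") {
  if (!term %in% names(fit$coefficients)) {
    stop("term not in fit: ", term)
  }
  b <- fit$coefficients[[term]]
  s <- fit$se[[term]]
  list(rr = exp(b), ci_lo = exp(b - 1.96 * s), ci_hi = exp(b + 1.96 * s))
}

#' Rank definitions by AIC
#'
#' Ascending AIC; ties broken by definition id (lexicographic), so the
#' ranking is deterministic.
#'
#' @param aic named numeric vector (names = definition ids), or a
#'   `data.frame` with `definition_id` and `aic` columns.
#' @return a list: `ranking` (a `data.frame` `definition_id`, `aic` in
#'   rank order) and `optimal` (the lowest-AIC id).
#' @export
rank_definitions <- function(aic) {
  if (is.data.frame(aic)) {
    tab <- data.frame(definition_id = aic$definition_id, aic = aic$aic,
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(names(aic))) stop("AIC vector must be named")
    tab <- data.frame(definition_id = names(aic), aic = unname(aic),
                      stringsAsFactors = FALSE)
  }
  tab <- tab[!is.na(tab$aic), ]
  if (nrow(tab) == 0) stop("no fits to rank")
  tab <- tab[order(tab$aic, tab$definition_id), ]
  rownames(tab) <- NULL
  list(ranking = tab, optimal = tab$definition_id[1])
}

#' Fit the count model for every definition and region
#'
#' Assembles, per (region, definition), the flag series, covariates and
#' imputed counts; fits [fit_nb()]; and collects rate ratios, AIC and
#' dispersion into the tidy results layout of [write_results()]. Relative
#' humidity is included as a covariate except for apparent-temperature
#' metrics (the heat index already embodies humidity).
#'
#' @param flags long flag table from [flag_all()]`$flags`.
#' @param weather study-window weather with derived `rh`.
#' @param nws daily NWS flag table (`region`, `date`, `flag`).
#' @param hri imputed count table (`region`, `date`, `count`).
#' @param definitions definition table.
#' @param thresholds threshold table (for the report columns).
#' @param population named numeric vector of regional populations.
#' @return a results `data.frame`, one row per (region, definition).
#' @export
fit_all_definitions <- function(flags, weather, nws, hri,
                                definitions = standard_definitions(),
                                thresholds, population) {
  rows <- list()
  for (reg in sort(unique(flags$region))) {
    if (!reg %in% names(population)) {
      stop("no population for region ", reg)
    }
    w <- weather[weather$region == reg, c("date", "rh")]
    nw <- nws[nws$region == reg, c("date", "flag")]
    names(nw)[2] <- "nws"
    h <- hri[hri$region == reg, c("date", "count")]
    for (i in seq_len(nrow(definitions))) {
      def <- definitions[i, ]
      fl <- flags[flags$region == reg & flags$definition_id == def$id,
                  c("date", "flag")]
      names(fl)[2] <- "hw"
      d <- merge(merge(merge(fl, w, by = "date"), nw, by = "date"),
                 h, by = "date")
      d <- d[order(d$date), ]
      include_rh <- def$metric != "apparent_max"
      des <- build_design(d, population = population[[reg]],
                          include_rh = include_rh)
      th_row <- thresholds[thresholds$region == reg &
                             thresholds$definition_id == def$id, ]
      if (stats::var(des$X[, "hw"]) == 0) {
        # no (or only) flagged days: the heat-wave effect is inestimable
        warning("definition ", def$id, " in region ", reg,
                " has a constant flag series; recorded as NA")
        rows[[paste(reg, def$id)]] <- data.frame(
          region = reg, definition_id = def$id, metric = def$metric,
          duration = def$duration, threshold_type = def$threshold_type,
          intensity = def$intensity, threshold_c = th_row$threshold_c,
          hw_days = sum(fl$hw), rr = NA_real_, ci_lo = NA_real_,
          ci_hi = NA_real_, aic = NA_real_, theta = NA_real_,
          n = length(des$y), n_dropped = des$n_dropped,
          stringsAsFactors = FALSE
        )
        next
      }
      fit <- fit_nb(des$X, des$y, des$offset)
      rr <- rate_ratio(fit, "hw")
      th <- thresholds$threshold_c[thresholds$region == reg &
                                     thresholds$definition_id == def$id]
      rows[[paste(reg, def$id)]] <- data.frame(
        region = reg, definition_id = def$id, metric = def$metric,
        duration = def$duration, threshold_type = def$threshold_type,
        intensity = def$intensity, threshold_c = th,
        hw_days = sum(fl$hw), rr = rr$rr, ci_lo = rr$ci_lo,
        ci_hi = rr$ci_hi, aic = fit$aic, theta = fit$theta,
        n = fit$n, n_dropped = des$n_dropped,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
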