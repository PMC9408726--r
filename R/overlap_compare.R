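#' Cross-tabulate study heat-wave flags against NWS alert flags
#'
#' @param study,nws binary flag vectors on the same dates (same region),
#'   or `data.frame`s with `date` and `flag` columns which are aligned on
#'   `date` before tabulating.
#' @return a list of day counts: `a` (both flagged), `b` (study only),
#'   `c` (NWS only), `d` (neither), and `n = a+b+c+d`.
#' @export
build_overlap <- function(study, nws) {
  if (is.data.frame(study) || is.data.frame(nws)) {
    if (!is.data.frame(study) || !is.data.frame(nws)) {
      stop("study and nws must both be vectors or both data.frames")
    }
    if (!identical(study$date, nws$date)) {
      m <- merge(study[, c("date", "flag")], nws[, c("date", "flag")],
                 by = "date")
      if (nrow(m) != nrow(study) || nrow(m) != nrow(nws)) {
        stop("study and NWS series are not aligned on the same dates")
      }
      study <- m$flag.x
      nws <- m$flag.y
    } else {
      study <- study$flag
      nws <- nws$flag
    }
  }
  if (length(study) != length(nws)) {
    stop("study and NWS series differ in length")
  }
  s <- study == 1
  w <- nws == 1
  out <- list(a = sum(s & w), b = sum(s & !w), c = sum(!s & w),
              d = sum(!s & !w))
  out$n <- out$a + out$b + out$c + out$d
  out
}

#' McNemar test on a 2x2 agreement table
#'
#' Paired test of marginal homogeneity driven by the discordant cells b
#' (study-only days) and c (NWS-only days). With the default continuity
#' correction, chi-square = (max(|b - c| - 1, 0))^2 / (b + c); without,
#' (b - c)^2 / (b + c). One degree of freedom. The |b-c|-1 term is clamped
#' at zero so the statistic stays defined when b and c nearly agree.
#'
#' @param table an overlap table from [build_overlap()] (only `b` and `c`
#'   are used).
#' @param continuity apply the continuity correction (default `TRUE`).
#' @return a list: `chisq`, `df` (always 1), `p_value`.
#' @export
mcnemar <- function(table, continuity = TRUE) {
  b <- table$b
  c <- table$c
  if (b + c == 0) {
    stop("McNemar statistic undefined: no discordant days (b + c = 0)")
  }
  chisq <- if (continuity) {
    max(abs(b - c) - 1, 0)^2 / (b + c)
  } else {
    (b - c)^2 / (b + c)
  }
  list(chisq = chisq, df = 1L,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Overlap and McNemar comparison for selected definitions
#'
#' @param flags long flag table from [flag_all()]`$flags`.
#' @param nws daily NWS flag table (`region`, `date`, `flag`).
#' @param selection named character vector: region -> definition id to
#'   compare (typically the AIC-optimal definition per region).
#' @param continuity passed to [mcnemar()].
#' @return a `data.frame`: `region`, `definition_id`, `a`, `b`, `c`, `d`,
#'   `chi2`, `df`, `p`.
#' @export
compare_with_alerts <- function(flags, nws, selection, continuity = TRUE) {
  rows <- lapply(names(selection), function(reg) {
    id <- selection[[reg]]
    st <- flags[flags$region == reg & flags$definition_id == id,
                c("date", "flag")]
    nw <- nws[nws$region == reg, c("date", "flag")]
    tab <- build_overlap(st, nw)
    mc <- mcnemar(tab, continuity = continuity)
    data.frame(region = reg, definition_id = id, a = tab$a, b = tab$b,
               c = tab$c, d = tab$d, chi2 = mc$chisq, df = mc$df,
               p = mc$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
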