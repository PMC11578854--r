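# Post hoc linear trend tests on annual posterior-mean demographic
# rates: ordinary least squares of the annual mean estimate on
# calendar year, with a t-test on the slope.

#' Linear trend in an annual demographic rate
#'
#' Ordinary least squares of the annual posterior means on calendar
#' year (centered before fitting for conditioning; the slope is
#' reported per calendar year).  `mask` drops named years before
#' fitting — used for years whose estimates are unreliable, e.g. the
#' final first-year-survival years when too few marked birds have had
#' time to return.  A constant series has zero residual variance; its
#' p-value is returned as `NA` with `degenerate = TRUE`.
#'
#' @param means annual posterior means
#' @param years calendar years (same length)
#' @param mask calendar years to exclude
#' @param label rate name carried into the result
#' @return list of class `trend_result`: `slope`, `intercept` (value at
#'   the mean retained year), `p_value`, `se`, `label`, `years_used`,
#'   `degenerate`
#' @export
fit_trend <- function(means, years, mask = NULL, label = "") {
  if (length(means) != length(years)) stopf("means and years differ in length")
  keep <- !(years %in% mask) & !is.na(means)
  y <- means[keep]; x <- years[keep]
  if (length(y) < 3) stopf("need at least 3 unmasked points")
  if (length(unique(x)) < 2) stopf("degenerate predictor: a single year")
  if (stats::var(y) == 0) {
    # an exactly constant series carries no trend information
    return(structure(list(slope = 0, intercept = y[1], p_value = NA_real_,
                          se = NA_real_, label = label, years_used = x,
                          degenerate = TRUE),
                     class = "trend_result"))
  }
  xc <- x - mean(x)
  fit <- suppressWarnings(lm(y ~ xc))
  sm <- suppressWarnings(summary(fit))$coefficients
  degenerate <- nrow(sm) < 2 || is.na(sm["xc", 4])
  structure(list(slope = unname(coef(fit)["xc"]),
                 intercept = unname(coef(fit)[1]),
                 p_value = if (degenerate) NA_real_ else unname(sm["xc", 4]),
                 se = if (degenerate) NA_real_ else unname(sm["xc", 2]),
                 label = label, years_used = x, degenerate = degenerate),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("trend %s: slope %.4g per year, p = %s (%d years)\n",
              if (nzchar(x$label)) paste0("in ", x$label) else "",
              x$slope,
              if (is.na(x$p_value)) "NA (zero residual variance)"
              else format.pval(x$p_value, digits = 3),
              length(x$years_used)))
  invisible(x)
}

#' Trend tests for the standard set of annual rates from a fit
#'
#' Runs [fit_trend()] on the posterior means of first-year survival,
#' adult survival and productivity.  `mask` is a named list of
#' calendar years to exclude per rate (e.g. the last first-year
#' survival years, which are lower bounds until the cohorts recruit).
#'
#' @param fit an `ipm_fit`
#' @param mask named list of excluded years per series
#' @return data.frame with one row per rate
#' @export
trend_table <- function(fit, mask = list()) {
  rows <- lapply(c("alpha1", "alpha2", "f"), function(nm) {
    s <- extract_series(fit, nm)
    yrs <- fit$design$years[seq_len(ncol(s))]
    tr <- fit_trend(colMeans(s), yrs, mask = mask[[nm]], label = nm)
    data.frame(rate = nm, slope = tr$slope, p_value = tr$p_value,
               n_years = length(tr$years_used))
  })
  do.call(rbind, rows)
}
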