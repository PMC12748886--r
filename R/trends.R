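#' Linear temporal trend with spline alternatives
#'
#' Ordinary least squares regression of an annual quantity on year; the
#' slope is reported per decade with its 95% t-interval. Natural cubic
#' spline fits with 2, 3 and 4 degrees of freedom (boundary knots at the
#' first and last year) are compared by Gaussian AIC.
#'
#' @param year integer years.
#' @param value annual values (same length, at least 5).
#' @return object of class `trend_fit`: `slope_decade`, `ci` (lower/upper,
#'   per decade), `se_decade`, `aic_linear`, `aic_spline` (named by df),
#'   `n`.
#' @export
fit_trend <- function(year, value) {
  ok <- is.finite(value) & is.finite(year)
  year <- year[ok]; value <- value[ok]
  if (length(year) < 5L) stopf("need at least 5 annual values")
  fit <- stats::lm(value ~ year)
  se <- summary(fit)$coefficients[2, 2]
  slope <- unname(stats::coef(fit)[2])
  tcrit <- stats::qt(0.975, df = length(year) - 2L)
  aic_spl <- vapply(2:4, function(df) {
    stats::AIC(stats::lm(value ~ splines::ns(year, df = df,
                                             Boundary.knots = range(year))))
  }, numeric(1))
  names(aic_spl) <- paste0("df", 2:4)
  structure(list(
    slope_decade = slope * 10,
    se_decade = se * 10,
    ci = c(lower = (slope - tcrit * se) * 10, upper = (slope + tcrit * se) * 10),
    aic_linear = stats::AIC(fit), aic_spline = aic_spl,
    n = length(year)
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend: %+.3f per decade (95%% CI %+.3f, %+.3f), n = %d\n",
              x$slope_decade, x$ci["lower"], x$ci["upper"], x$n))
  invisible(x)
}

#' Wilcoxon rank test of two groups of city-specific trends
#'
#' Two-sided rank-sum test comparing, e.g., the 15 factual city trend
#' estimates against the pooled counterfactual trend estimates (15 cities
#' x 9 ensemble variants). Exact for small samples without ties, normal
#' approximation with tie correction otherwise ([stats::wilcox.test()]
#' defaults).
#'
#' @param x,y numeric vectors of trend estimates (both non-empty).
#' @return list `statistic`, `p`, `n_x`, `n_y`.
#' @export
compare_trends <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stopf("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_x = length(x), n_y = length(y))
}
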