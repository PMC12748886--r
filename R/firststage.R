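#' Subperiod scheme
#'
#' Splits the study period into contiguous, non-overlapping blocks: six
#' 5-year subperiods 1993-1997 ... 2018-2022 by default, or five 6-year
#' blocks as a sensitivity variant.
#'
#' @param start,end first and last study year.
#' @param width block width in years; must divide the period length.
#' @return data frame `label`, `start`, `end`, `mid` (block midpoint year).
#' @export
subperiod_scheme <- function(start = 1993L, end = 2022L, width = 5L) {
  n_years <- end - start + 1L
  if (n_years %% width != 0L) {
    stopf("%d-year period cannot be split into %d-year blocks", n_years, width)
  }
  s <- seq(start, end, by = width)
  data.frame(label = sprintf("%d-%d", s, s + width - 1L),
             start = s, end = s + width - 1L, mid = s + (width - 1) / 2)
}

subperiod_of <- function(years, scheme) {
  idx <- findInterval(years, scheme$start)
  idx[years < scheme$start[1] | years > scheme$end[nrow(scheme)]] <- NA_integer_
  scheme$label[idx]
}

#' Quasi-Poisson distributed-lag model for one city and subperiod
#'
#' Fits warm-season daily death counts on a distributed-lag cross-basis of
#' temperature, adjusting for day of week (6 indicator contrasts) and for
#' seasonal and long-term trends through year-stratified natural cubic
#' splines of day-of-season (2 equally spaced inner knots per year) plus
#' year indicators. The quasi-Poisson dispersion is the Pearson chi-square
#' divided by the residual degrees of freedom, and the coefficient
#' covariance is dispersion times the inverse Fisher information.
#'
#' @param deaths non-negative integer daily death counts, aligned with the
#'   rows of `cb`.
#' @param cb a [cross_basis()] for the same days.
#' @param seasonal_knots number of inner knots of the per-year seasonal
#'   spline.
#' @param city,subperiod labels carried through.
#' @return object of class `dlnm_fit`: coefficients and covariance of the
#'   cross-basis terms, dispersion, convergence flag, and the basis specs.
#' @export
fit_dlnm <- function(deaths, cb, seasonal_knots = 2L,
                     city = NA_character_, subperiod = NA_character_) {
  # non-integer counts are allowed (day-of-year-averaged baseline variant)
  if (any(!is.finite(deaths)) || any(deaths < 0)) {
    stopf("death counts must be non-negative")
  }
  if (all(deaths == 0)) stopf("all-zero death counts")
  dates <- attr(cb, "dates")
  if (length(deaths) != nrow(cb)) stopf("deaths and cross-basis rows differ")

  yearf <- factor(date_year(dates))
  dow <- factor(format(dates, "%u"), levels = as.character(1:7))
  season_start <- as.Date(paste0(date_year(dates), "-06-01"))
  dos <- as.numeric(dates - season_start) + 1
  dk <- stats::quantile(range(dos)[1]:range(dos)[2],
                        seq_len(seasonal_knots) / (seasonal_knots + 1))
  S <- splines::ns(dos, knots = dk, Boundary.knots = range(dos))

  cbm <- unclass(cb)
  X <- stats::model.matrix(~ cbm + dow + yearf + yearf:S)
  cb_cols <- grep("^cbm", colnames(X))

  fit <- suppressWarnings(stats::glm.fit(X, deaths, family = stats::poisson()))
  ok <- !is.na(fit$coefficients)
  if (!all(ok)) {
    if (any(!ok[cb_cols])) warnf("aliased cross-basis columns in %s %s", city, subperiod)
    else warnf("dropping %d aliased control columns", sum(!ok))
    X <- X[, ok, drop = FALSE]
    fit <- suppressWarnings(stats::glm.fit(X, deaths, family = stats::poisson()))
    cb_cols <- grep("^cbm", colnames(X))
  }
  mu <- fit$fitted.values
  df_res <- length(deaths) - ncol(X)
  dispersion <- sum((deaths - mu)^2 / mu) / df_res
  W <- mu
  XtWX <- crossprod(X * sqrt(W))
  V <- tryCatch(dispersion * solve(XtWX), error = function(e) NULL)
  converged <- fit$converged && !is.null(V) && all(is.finite(fit$coefficients))
  if (is.null(V)) V <- matrix(NA_real_, ncol(X), ncol(X))

  structure(list(
    city = city, subperiod = subperiod,
    coef = fit$coefficients, vcov = V, cb_cols = cb_cols,
    dispersion = dispersion, n_days = length(deaths),
    converged = converged,
    exposure_spec = attr(cb, "exposure_spec"),
    lag_spec = attr(cb, "lag_spec")
  ), class = "dlnm_fit")
}

#' @export
print.dlnm_fit <- function(x, ...) {
  cat(sprintf("quasi-Poisson DLNM fit [%s %s]: %d days, dispersion %.2f%s\n",
              x$city, x$subperiod, x$n_days, x$dispersion,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Reduce a distributed-lag fit to cumulative coefficients
#'
#' Sums the exposure-lag coefficient surface over all lags by exact linear
#' algebra: `theta = M eta`, `S = M V M'` where `M` is the lag-summation
#' contrast built from the lag basis. Predictions from `theta` give the
#' cumulative (over all lags) log relative risk versus a centering
#' temperature.
#'
#' @param fit a [fit_dlnm()] result.
#' @param center centering temperature stored with the association (default:
#'   the first inner knot, the 50th-percentile temperature).
#' @return object of class `reduced_assoc`: list with `city`, `subperiod`,
#'   `theta` (length 3), `S` (3 x 3), `center`, `exposure_spec`.
#' @export
reduce_dlnm <- function(fit, center = NULL) {
  if (!fit$converged) stopf("cannot reduce a non-converged fit (%s %s)",
                            fit$city, fit$subperiod)
  eta <- fit$coef[fit$cb_cols]
  V <- fit$vcov[fit$cb_cols, fit$cb_cols, drop = FALSE]
  n_exposure <- length(fit$exposure_spec$knots) + 1L
  M <- lag_sum_matrix(fit$lag_spec, n_exposure)
  if (ncol(M) != length(eta)) stopf("cross-basis dimension mismatch in reduction")
  theta <- as.numeric(M %*% eta)
  S <- M %*% V %*% t(M)
  S <- (S + t(S)) / 2
  structure(list(city = fit$city, subperiod = fit$subperiod,
                 theta = theta, S = S,
                 center = center %||% fit$exposure_spec$knots[1],
                 exposure_spec = fit$exposure_spec),
            class = "reduced_assoc")
}

#' Cumulative relative-risk curve
#'
#' `RR(x) = exp((b(x) - b(center)) theta)` with pointwise 95% confidence
#' intervals from the delta method on the coefficient covariance.
#'
#' @param theta cumulative exposure-response coefficients (or a
#'   `reduced_assoc`, in which case `theta`, `S` and `spec` are taken from
#'   it).
#' @param at temperatures at which to evaluate.
#' @param center centering temperature (risk reference); must lie within
#'   the boundary knots.
#' @param S coefficient covariance (optional; omit for point estimates).
#' @param spec the [exposure_spec()].
#' @return data frame `temp`, `rr`, `rr_lo`, `rr_hi`.
#' @export
predict_rr <- function(theta, at, center, S = NULL, spec = NULL) {
  if (inherits(theta, "reduced_assoc")) {
    obj <- theta
    spec <- obj$exposure_spec
    S <- S %||% obj$S
    if (missing(center)) center <- obj$center
    theta <- obj$theta
  }
  if (center < spec$boundary[1] || center > spec$boundary[2]) {
    stopf("centering temperature %.2f outside boundary knots", center)
  }
  D <- ns_basis(at, spec) - matrix(ns_basis(center, spec),
                                   length(at), length(theta), byrow = TRUE)
  logrr <- as.numeric(D %*% theta)
  se <- if (is.null(S)) rep(0, length(at)) else sqrt(pmax(rowSums((D %*% S) * D), 0))
  data.frame(temp = at, rr = exp(logrr),
             rr_lo = exp(logrr - 1.959964 * se),
             rr_hi = exp(logrr + 1.959964 * se))
}

#' First-stage fits for every city and subperiod
#'
#' Builds per-city exposure specs from the pooled study-period warm-season
#' temperatures, then fits and reduces a quasi-Poisson distributed-lag model
#' for every city x subperiod. Non-converged fits are excluded with a
#' warning.
#'
#' @param temps data frame `city`, `date`, `tmean` covering at least the
#'   warm seasons plus the 10-day pre-season buffer of all study years.
#' @param deaths data frame `city`, `date`, `deaths` for warm-season days.
#' @param scheme a [subperiod_scheme()].
#' @param lspec a [lag_spec()].
#' @param exposure_probs inner-knot percentiles.
#' @param exclude_years years dropped from the fits (sensitivity).
#' @return list with `reduced` (list of `reduced_assoc`), `specs` (per-city
#'   exposure specs), `scheme`.
#' @export
first_stage <- function(temps, deaths, scheme = subperiod_scheme(),
                        lspec = lag_spec(), exposure_probs = c(0.5, 0.9),
                        exclude_years = integer(0)) {
  temps$date <- as.Date(temps$date)
  deaths$date <- as.Date(deaths$date)
  study_years <- seq(scheme$start[1], scheme$end[nrow(scheme)])
  keep_years <- setdiff(study_years, exclude_years)

  cities <- sort(unique(temps$city))
  specs <- lapply(cities, function(ct) {
    tt <- temps[temps$city == ct & is_warm_season(temps$date) &
                  date_year(temps$date) %in% study_years, "tmean"]
    exposure_spec(tt, probs = exposure_probs)
  })
  names(specs) <- cities

  reduced <- list()
  for (ct in cities) {
    tc <- temps[temps$city == ct, , drop = FALSE]
    dc <- deaths[deaths$city == ct, , drop = FALSE]
    for (i in seq_len(nrow(scheme))) {
      yrs <- intersect(seq(scheme$start[i], scheme$end[i]), keep_years)
      if (length(yrs) == 0L) next
      ti <- tc[date_year(tc$date) %in% yrs & is_season_or_buffer(tc$date), ]
      ti <- ti[order(ti$date), ]
      di <- dc[date_year(dc$date) %in% yrs & is_warm_season(dc$date), ]
      di <- di[order(di$date), ]
      cb <- cross_basis(ti$date, ti$tmean, specs[[ct]], lspec,
                        out_dates = di$date)
      fit <- fit_dlnm(di$deaths, cb, city = ct, subperiod = scheme$label[i])
      if (!fit$converged) {
        warnf("first-stage fit did not converge for %s %s; excluded",
              ct, scheme$label[i])
        next
      }
      reduced[[paste(ct, scheme$label[i])]] <- reduce_dlnm(fit)
    }
  }
  list(reduced = reduced, specs = specs, scheme = scheme)
}

#' Per-city empirical temperature percentiles
#'
#' Linear-interpolation (type 7) quantiles of warm-season daily means, and
#' the average percentile distribution across cities (the mean across
#' cities of per-city percentile values at each requested percentile).
#'
#' @param temps data frame `city`, `date`, `tmean`.
#' @param probs percentile grid (fractions).
#' @param years optional years filter.
#' @return matrix cities x percentiles, with an `average` attribute.
#' @export
city_percentiles <- function(temps, probs = seq(0, 1, by = 0.001), years = NULL) {
  temps$date <- as.Date(temps$date)
  sel <- is_warm_season(temps$date)
  if (!is.null(years)) sel <- sel & date_year(temps$date) %in% years
  temps <- temps[sel, , drop = FALSE]
  cities <- sort(unique(temps$city))
  out <- t(vapply(cities, function(ct) {
    stats::quantile(temps$tmean[temps$city == ct], probs, type = 7, names = FALSE)
  }, numeric(length(probs))))
  dimnames(out) <- list(cities, sprintf("%.1f", probs * 100))
  attr(out, "average") <- colMeans(out)
  attr(out, "probs") <- probs
  out
}
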