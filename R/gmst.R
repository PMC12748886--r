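#' Re-baseline a series to a reference window
#'
#' Subtracts the mean over a reference sub-window (e.g. the pre-industrial
#' period 1850-1900 for global mean surface temperature anomalies) so that
#' the series mean over that window is zero.
#'
#' @param x numeric series.
#' @param ref logical or integer index of the reference window within `x`.
#' @return `x` shifted by minus its reference-window mean.
#' @export
rebaseline <- function(x, ref) {
  if (is.logical(ref)) {
    if (length(ref) != length(x)) stopf("logical `ref` must match series length")
    ref <- which(ref)
  }
  if (length(ref) == 0L || any(ref < 1L) || any(ref > length(x))) {
    stopf("reference window lies outside the series")
  }
  x - mean(x[ref])
}

#' Smooth and re-baseline monthly GMST anomalies
#'
#' Applies singular spectrum analysis smoothing (window 120 months by
#' default) independently to the central estimate and to the lower/upper
#' 95% confidence bounds of a monthly global mean surface temperature
#' (GMST) anomaly series, then re-baselines both the raw and the smoothed
#' series so their 1850-1900 (configurable) means are zero.
#'
#' The alternative `method = "annual_ma"` replaces SSA by a centred 5-year
#' moving average of annual-mean anomalies (each month of a year takes that
#' year's smoothed value), a sensitivity variant.
#'
#' @param gmst data frame with columns `year`, `month`, `anomaly`,
#'   `anomaly_lower`, `anomaly_upper` (degrees Celsius, any vendor baseline),
#'   months contiguous.
#' @param window SSA embedding window in months.
#' @param ref_years length-2 integer vector: first and last year of the
#'   pre-industrial reference period.
#' @param method `"ssa"` or `"annual_ma"`.
#' @param ma_window moving-average window in years for `method = "annual_ma"`.
#' @return data frame `year`, `month`, `anomaly` (re-baselined raw central)
#'   and `smooth`, `smooth_lower`, `smooth_upper` (re-baselined smoothed
#'   bounds).
#' @export
smooth_gmst <- function(gmst, window = 120L, ref_years = c(1850L, 1900L),
                        method = c("ssa", "annual_ma"), ma_window = 5L) {
  method <- match.arg(method)
  check_gmst(gmst)
  gmst <- gmst[order(gmst$year, gmst$month), , drop = FALSE]
  ref <- gmst$year >= ref_years[1] & gmst$year <= ref_years[2]
  if (!any(ref)) stopf("reference period %d-%d not covered by the GMST series",
                       ref_years[1], ref_years[2])

  smooth_one <- function(x) {
    if (method == "ssa") {
      ssa_smooth(x, window = window)
    } else {
      ann <- tapply(x, gmst$year, mean)
      sm <- moving_average_smooth(as.numeric(ann), window = ma_window)
      sm[match(gmst$year, as.integer(names(ann)))]
    }
  }

  out <- data.frame(
    year = gmst$year, month = gmst$month,
    anomaly = rebaseline(gmst$anomaly, ref),
    smooth = rebaseline(smooth_one(gmst$anomaly), ref),
    smooth_lower = rebaseline(smooth_one(gmst$anomaly_lower), ref),
    smooth_upper = rebaseline(smooth_one(gmst$anomaly_upper), ref)
  )
  out
}

check_gmst <- function(gmst) {
  need <- c("year", "month", "anomaly", "anomaly_lower", "anomaly_upper")
  miss <- setdiff(need, names(gmst))
  if (length(miss)) stopf("GMST table lacks columns: %s", paste(miss, collapse = ", "))
  if (any(gmst$anomaly_lower > gmst$anomaly | gmst$anomaly > gmst$anomaly_upper)) {
    stopf("GMST bounds must satisfy lower <= central <= upper")
  }
  o <- order(gmst$year, gmst$month)
  ym <- gmst$year[o] * 12L + gmst$month[o]
  if (any(diff(ym) != 1L)) stopf("GMST months are not contiguous")
  invisible(TRUE)
}

#' Annual warm-season mean temperatures
#'
#' Arithmetic mean of daily mean temperature over June-September for each
#' year. Years with any missing warm-season day are excluded with a warning.
#'
#' @param daily data frame with columns `date` (Date) and `tmean`.
#' @return data frame `year`, `tmean`: one row per complete warm season.
#' @export
warm_season_means <- function(daily) {
  if (!inherits(daily$date, "Date")) daily$date <- as.Date(daily$date)
  ws <- daily[is_warm_season(daily$date) & !is.na(daily$tmean), , drop = FALSE]
  yr <- date_year(ws$date)
  cnt <- table(yr)
  complete <- as.integer(names(cnt))[cnt == 122L]
  dropped <- setdiff(unique(yr), complete)
  if (length(dropped)) {
    warnf("excluding years with incomplete warm seasons: %s",
          paste(sort(dropped), collapse = ", "))
  }
  keep <- yr %in% complete
  means <- tapply(ws$tmean[keep], yr[keep], mean)
  data.frame(year = as.integer(names(means)), tmean = as.numeric(means))
}

#' City-specific GMST scaling regression
#'
#' Ordinary least squares regression of annual warm-season mean city
#' temperature on the annual mean of the smoothed GMST anomaly over a fit
#' window (1950-2022 by default). The slope expresses local warm-season
#' warming per degree of smoothed global warming; its 95% confidence
#' interval (t distribution, n - 2 df) feeds the counterfactual ensemble.
#'
#' @param annual_tmean data frame `year`, `tmean` from [warm_season_means()].
#' @param smoothed_gmst output of [smooth_gmst()] (its `smooth` column is
#'   averaged by year), or a data frame `year`, `smooth`.
#' @param fit_years length-2 vector: first and last year of the fit window.
#' @param city optional city label carried through.
#' @return object of class `scaling_fit`: list with `city`, `slope`,
#'   `slope_se`, `slope_ci` (named lower/central/upper), `intercept`,
#'   `n_years`.
#' @export
fit_city_scaling <- function(annual_tmean, smoothed_gmst,
                             fit_years = c(1950L, 2022L), city = NA_character_) {
  g_ann <- stats::aggregate(smooth ~ year, data = smoothed_gmst, FUN = mean)
  d <- merge(annual_tmean, g_ann, by = "year")
  d <- d[d$year >= fit_years[1] & d$year <= fit_years[2], , drop = FALSE]
  if (nrow(d) < 10L) stopf("scaling fit needs >= 10 overlapping years, got %d", nrow(d))
  if (stats::var(d$smooth) < 1e-12) stopf("smoothed GMST has zero variance over the fit window")
  fit <- stats::lm(tmean ~ smooth, data = d)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  se <- sm$coefficients[2, 2]
  tcrit <- stats::qt(0.975, df = nrow(d) - 2L)
  structure(list(
    city = city,
    slope = slope,
    slope_se = se,
    slope_ci = c(lower = slope - tcrit * se, central = slope,
                 upper = slope + tcrit * se),
    intercept = unname(stats::coef(fit)[1]),
    n_years = nrow(d)
  ), class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("GMST scaling fit%s: slope %.3f degC/degC (95%% CI %.3f, %.3f), n = %d years\n",
              if (is.na(x$city)) "" else paste0(" [", x$city, "]"),
              x$slope, x$slope_ci["lower"], x$slope_ci["upper"], x$n_years))
  invisible(x)
}

#' Counterfactual daily temperature series
#'
#' Removes the climate-change signal from a factual daily series by
#' subtracting slope x smoothed monthly GMST anomaly from each day's mean
#' temperature. Only warm-season days and the 10-day pre-season buffer are
#' modified (buffer days use their own calendar month's anomaly); any other
#' days present pass through unchanged.
#'
#' @param daily data frame `date`, `tmean` (one city).
#' @param slope scaling slope (degrees local per degree GMST).
#' @param smoothed_gmst data frame with `year`, `month` and the smoothed
#'   anomaly column named by `gmst_col`.
#' @param gmst_col which smoothed bound to use (default `"smooth"`).
#' @param variant label recorded on the output.
#' @return `daily` with `tmean` replaced by the counterfactual values and a
#'   `variant` column.
#' @export
build_counterfactual <- function(daily, slope, smoothed_gmst,
                                 gmst_col = "smooth", variant = "cf") {
  if (!inherits(daily$date, "Date")) daily$date <- as.Date(daily$date)
  sel <- is_season_or_buffer(daily$date)
  key <- paste(date_year(daily$date), date_month(daily$date))
  gkey <- paste(smoothed_gmst$year, smoothed_gmst$month)
  g <- smoothed_gmst[[gmst_col]][match(key, gkey)]
  if (anyNA(g[sel])) {
    bad <- unique(key[sel][is.na(g[sel])])[1]
    stopf("smoothed GMST series lacks month %s needed for the counterfactual", bad)
  }
  out <- daily
  out$tmean <- daily$tmean - ifelse(sel, slope * g, 0)
  out$variant <- variant
  out
}

#' Nine-member counterfactual temperature ensemble
#'
#' Crosses the three smoothed GMST bounds (lower, central, upper) with the
#' three scaling-slope bounds to produce nine counterfactual variants. The
#' central x central member is the best-estimate counterfactual used in the
#' main analysis.
#'
#' @inheritParams build_counterfactual
#' @param scaling a `scaling_fit`.
#' @return named list of nine data frames (variants
#'   `cf_<gmst bound>_<slope bound>`).
#' @export
build_cf_ensemble <- function(daily, scaling, smoothed_gmst) {
  bounds <- c("lower", "central", "upper")
  gcols <- c(lower = "smooth_lower", central = "smooth", upper = "smooth_upper")
  out <- list()
  for (g in bounds) {
    for (b in bounds) {
      lab <- sprintf("cf_%s_%s", g, b)
      out[[lab]] <- build_counterfactual(
        daily, slope = scaling$slope_ci[[b]], smoothed_gmst,
        gmst_col = gcols[[g]], variant = lab)
    }
  }
  out
}

#' Climate-change attributable warm-season warming
#'
#' Per-year difference between factual and counterfactual warm-season mean
#' temperatures, with the ensemble spread (min, max) across counterfactual
#' variants, and the period mean.
#'
#' @param daily factual series (`date`, `tmean`).
#' @param cf_list list of counterfactual series as from [build_cf_ensemble()]
#'   (or a single-element list).
#' @param years optional vector of years to restrict to.
#' @return list with `annual` (data frame `year`, `delta` for the central
#'   variant — or the first element if no central is present — plus
#'   `delta_min`, `delta_max` across variants) and `period` (named vector
#'   `mean`, `min`, `max`).
#' @export
attributable_temperature <- function(daily, cf_list, years = NULL) {
  fact <- warm_season_means(daily)
  if (!is.null(years)) fact <- fact[fact$year %in% years, , drop = FALSE]
  deltas <- sapply(cf_list, function(cf) {
    m <- warm_season_means(cf)
    if (!identical(m$year[m$year %in% fact$year], fact$year)) {
      stopf("counterfactual series does not cover the factual years")
    }
    fact$tmean - m$tmean[match(fact$year, m$year)]
  })
  deltas <- matrix(deltas, nrow = nrow(fact),
                   dimnames = list(NULL, names(cf_list)))
  central <- if ("cf_central_central" %in% colnames(deltas)) {
    deltas[, "cf_central_central"]
  } else deltas[, 1]
  annual <- data.frame(
    year = fact$year, delta = central,
    delta_min = apply(deltas, 1, min), delta_max = apply(deltas, 1, max))
  list(annual = annual,
       period = c(mean = mean(central),
                  min = min(colMeans(deltas)), max = max(colMeans(deltas))))
}
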