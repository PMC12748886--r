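#' Minimum mortality temperature
#'
#' Searches a percentile grid (25th to 99th, 0.1-percentile steps) of a
#' city's daily mean temperatures for the temperature minimising the
#' cumulative log relative risk; ties are broken to the lowest temperature.
#'
#' @param theta cumulative exposure-response coefficients (length 3).
#' @param spec the city's [exposure_spec()].
#' @param temps the city's daily mean temperatures defining the percentile
#'   grid (use the temperature variant under analysis: counterfactual
#'   percentiles define their own grid).
#' @param probs percentile search range as fractions.
#' @return list `mmt` (temperature), `percentile` (grid percentile, in %).
#' @export
find_mmt <- function(theta, spec, temps, probs = seq(0.25, 0.99, by = 0.001)) {
  grid <- stats::quantile(temps[!is.na(temps)], probs, type = 7, names = FALSE)
  vals <- as.numeric(ns_basis(grid, spec) %*% theta)
  if (any(!is.finite(vals))) stopf("non-finite risk predictions on the MMT grid")
  i <- which.min(vals)  # grid ascends in temperature: first minimum = lowest
  list(mmt = grid[i], percentile = probs[i] * 100)
}

# Forward moving average of deaths within each warm season, truncated at
# the season end (days within max_lag of Sep 30 average the available days).
forward_mean_deaths <- function(dates, deaths, max_lag = 10L) {
  yr <- date_year(dates)
  out <- numeric(length(deaths))
  for (y in unique(yr)) {
    ix <- which(yr == y)
    D <- deaths[ix]
    nb <- length(D)
    cs <- cumsum(c(0, D))
    ends <- pmin(seq_len(nb) + max_lag, nb)
    out[ix] <- (cs[ends + 1L] - cs[seq_len(nb)]) / (ends - seq_len(nb) + 1L)
  }
  out
}

#' Daily and seasonal heat-attributable deaths
#'
#' Forward-perspective attribution: for each warm-season day `t` with
#' temperature above the minimum mortality temperature,
#' `AN(t) = (1 - exp(-Delta(t))) * mean(deaths[t .. t+L])`, where `Delta(t)`
#' is the cumulative log relative risk at the day's temperature versus the
#' MMT and the forward average runs over the lag window (truncated at the
#' season end). Days at or below the MMT contribute zero.
#'
#' @param dates,tmean,deaths aligned warm-season daily series for one city.
#' @param theta cumulative exposure-response coefficients.
#' @param spec the [exposure_spec()].
#' @param mmt minimum mortality temperature.
#' @param max_lag lag window (days).
#' @return list `daily` (data frame `date`, `an`), `annual` (data frame
#'   `year`, `an`, `deaths`, `af` with AF in % of total warm-season deaths).
#' @export
attributable_deaths <- function(dates, tmean, deaths, theta, spec, mmt,
                                max_lag = 10L) {
  if (!inherits(dates, "Date")) dates <- as.Date(dates)
  if (anyNA(deaths)) stopf("missing death counts in the attribution window")
  fwd <- forward_mean_deaths(dates, deaths, max_lag)
  delta <- as.numeric((ns_basis(tmean, spec) -
                         matrix(ns_basis(mmt, spec), length(tmean), length(theta),
                                byrow = TRUE)) %*% theta)
  an <- ifelse(tmean > mmt, (1 - exp(-delta)) * fwd, 0)
  yr <- date_year(dates)
  ann <- rowsum(cbind(an = an, deaths = deaths), yr)
  annual <- data.frame(year = as.integer(rownames(ann)), an = ann[, "an"],
                       deaths = ann[, "deaths"],
                       af = 100 * ann[, "an"] / ann[, "deaths"])
  rownames(annual) <- NULL
  list(daily = data.frame(date = dates, an = an), annual = annual)
}

#' Aggregate attributable numbers across cities
#'
#' @param annual_list list of per-city annual data frames (`year`, `an`,
#'   `deaths`) as returned by [attributable_deaths()].
#' @return data frame `year`, `an`, `deaths`, `af` summed across cities.
#' @export
aggregate_attribution <- function(annual_list) {
  yrs <- lapply(annual_list, `[[`, "year")
  if (length(unique(lapply(yrs, sort))) != 1L) {
    stopf("cities cover different years; cannot aggregate")
  }
  base <- annual_list[[1]][order(annual_list[[1]]$year), c("year", "an", "deaths")]
  for (a in annual_list[-1]) {
    a <- a[order(a$year), ]
    base$an <- base$an + a$an
    base$deaths <- base$deaths + a$deaths
  }
  base$af <- 100 * base$an / base$deaths
  base
}

#' Climate-change attributable mortality
#'
#' Differences between attribution results under factual and counterfactual
#' temperatures (same association variant): `AN_CC = AN_f - AN_cf`,
#' `AF_CC = AF_f - AF_cf` (percentage points), and the relative proportion
#' `P_CC = 100 * AF_CC / AF_f`. The period aggregate uses
#' `P_CC = 100 * sum(AN_CC) / sum(AN_f)`.
#'
#' @param factual,counterfactual annual data frames (`year`, `an`, `deaths`,
#'   `af`) from [attributable_deaths()] or [aggregate_attribution()].
#' @return list `annual` (per-year `an_cc`, `af_cc`, `p_cc`) and `period`
#'   (named vector with period sums/means).
#' @export
climate_attribution <- function(factual, counterfactual) {
  if (!identical(sort(factual$year), sort(counterfactual$year))) {
    stopf("factual and counterfactual results cover different years")
  }
  f <- factual[order(factual$year), ]
  cf <- counterfactual[order(counterfactual$year), ]
  an_cc <- f$an - cf$an
  af_cc <- f$af - cf$af
  p_cc <- ifelse(f$af == 0, NA_real_, 100 * af_cc / f$af)
  list(
    annual = data.frame(year = f$year, an_cc = an_cc, af_cc = af_cc, p_cc = p_cc),
    period = c(an_cc_total = sum(an_cc), an_cc_per_year = mean(an_cc),
               af_cc = 100 * sum(an_cc) / sum(f$deaths),
               p_cc = if (sum(f$an) == 0) NA_real_ else 100 * sum(an_cc) / sum(f$an))
  )
}

#' Day-of-year averaged baseline mortality (sensitivity variant)
#'
#' Replaces observed daily death counts by their day-of-year mean over all
#' study years, per city.
#'
#' @param deaths data frame `city`, `date`, `deaths`.
#' @return same shape, `deaths` replaced by the day-of-year average.
#' @export
doy_baseline <- function(deaths) {
  deaths$date <- as.Date(deaths$date)
  key <- paste(deaths$city, format(deaths$date, "%m-%d"))
  m <- tapply(deaths$deaths, key, mean)
  out <- deaths
  out$deaths <- as.numeric(m[key])
  out
}

#' Monte Carlo empirical confidence intervals
#'
#' Samples coefficient vectors from their assumed multivariate normal
#' distributions (independently across units), re-evaluates a quantity
#' function per draw, and returns 2.5th/97.5th empirical percentiles.
#' Reproducible given `seed`; minimum-mortality temperatures and any other
#' conditioning quantities inside `fun` stay at their point-estimate values
#' unless `fun` recomputes them.
#'
#' @param theta list of coefficient vectors (one per unit).
#' @param vcov list of matching covariance matrices (PSD).
#' @param fun function taking a list of drawn coefficient vectors and
#'   returning a named numeric vector of quantities.
#' @param n number of draws (default 1000).
#' @param seed RNG seed.
#' @param level interval level.
#' @return list `point` (fun at the means), `lo`, `hi`, `draws` (n x q
#'   matrix).
#' @export
mc_eci <- function(theta, vcov, fun, n = 1000L, seed = 1L, level = 0.95) {
  stopifnot(length(theta) == length(vcov))
  chols <- lapply(vcov, function(v) {
    if (!is_psd(v)) stopf("coefficient covariance is not PSD")
    psd_chol(v)
  })
  point <- fun(theta)
  # reproducible under `seed` without clobbering the caller's RNG stream
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  nu <- length(theta)
  dims <- lengths(theta)
  draws <- matrix(NA_real_, n, length(point))
  colnames(draws) <- names(point)
  Z <- lapply(seq_len(nu), function(i) {
    matrix(stats::rnorm(n * dims[i]), n, dims[i])
  })
  for (m in seq_len(n)) {
    th <- lapply(seq_len(nu), function(i) {
      theta[[i]] + drop(Z[[i]][m, ] %*% chols[[i]])
    })
    draws[m, ] <- fun(th)
  }
  a <- (1 - level) / 2
  list(point = point,
       lo = apply(draws, 2, stats::quantile, probs = a, na.rm = TRUE, type = 7),
       hi = apply(draws, 2, stats::quantile, probs = 1 - a, na.rm = TRUE, type = 7),
       draws = draws)
}
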