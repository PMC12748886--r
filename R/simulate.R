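#' Configuration of the synthetic multi-city world
#'
#' Defines every parameter of the data-generating world used for
#' validation: a global mean surface temperature (GMST) anomaly series with
#' a smooth anthropogenic trend, multi-city daily temperatures coupled to
#' it through known scaling slopes, rising life-expectancy trajectories,
#' and overdispersed daily death counts whose exposure-lag-response surface
#' steepens or flattens with life expectancy. Defaults mimic the scale of
#' the study setting: 15 cities, warm seasons (Jun-Sep) 1993-2022 with
#' temperature history from 1950, mean daily deaths between 15 and 90 per
#' city, and a 99th-percentile relative risk declining from about 1.45 as
#' life expectancy rises.
#'
#' @param n_cities number of cities.
#' @param study_years analysis years.
#' @param history_start first year of the temperature record (scaling-fit
#'   window).
#' @param gmst list: logistic trend amplitude `amp` (degC), midpoint year
#'   `mid`, width `width` (years), linear remainder `lin` (degC/yr), AR(1)
#'   coefficient `ar` and innovation SD `sd` of monthly noise, fixed 95%-CI
#'   half-width `ci_offset`, and an arbitrary vendor `baseline_offset`.
#' @param temp list: per-city warm-season base level range `base_range`
#'   (degC), seasonal amplitude `seasonal_amp` and peak day `peak_doy`,
#'   GMST scaling slopes `beta_range` (degC local per degC global), daily
#'   AR(1) coefficient `ar` and innovation SD `sd`.
#' @param mort list: mean daily deaths range `base_range`, day-of-week
#'   log-effects `dow` (length 7, Monday first), seasonal log-amplitude
#'   `season_amp`, linear year log-trend `year_trend`, negative-binomial
#'   variance/mean ratio `dispersion` (1 = Poisson).
#' @param assoc list: 99th-percentile relative risk `rr99_base` at each
#'   city's first-subperiod life expectancy, decline of log RR per year of
#'   life-expectancy gain `le_slope`, minimum log RR `floor`, hockey-stick
#'   knee percentile `knee_prob`, exponential lag-weight decay `lag_decay`
#'   (days), maximum lag `max_lag`.
#' @param le list: base life expectancy `base` (years), city offset range
#'   `offset_range`, city slope range `slope_range` (years per calendar
#'   year).
#' @return a `world_config` list.
#' @export
world_config <- function(n_cities = 15L,
                         study_years = 1993:2022,
                         history_start = 1950L,
                         gmst = list(),
                         temp = list(),
                         mort = list(),
                         assoc = list(),
                         le = list()) {
  cfg <- list(
    n_cities = n_cities,
    study_years = study_years,
    history_start = history_start,
    gmst = utils::modifyList(list(
      start = 1850L, amp = 1.6, mid = 1995, width = 18, lin = 3e-4,
      ar = 0.5, sd = 0.12, ci_offset = 0.05, baseline_offset = -0.36), gmst),
    temp = utils::modifyList(list(
      base_range = c(9, 12), seasonal_amp = 8.5, peak_doy = 201,
      beta_range = c(1.2, 2.0), ar = 0.7, sd = 1.3), temp),
    mort = utils::modifyList(list(
      base_range = c(15, 90),
      dow = c(0.01, 0, -0.005, 0, 0.005, 0.02, 0.015),
      season_amp = 0.04, year_trend = 0.001, dispersion = 1.3), mort),
    assoc = utils::modifyList(list(
      rr99_base = 1.45, le_slope = 0.045, floor = 0.12,
      knee_prob = 0.6, lag_decay = 1.5, max_lag = 10L), assoc),
    le = utils::modifyList(list(
      base = 76, offset_range = c(-1.5, 1.5), slope_range = c(0.15, 0.35)), le)
  )
  class(cfg) <- "world_config"
  cfg
}

# monthly anthropogenic trend, relative to the vendor baseline
gmst_trend <- function(cfg, year, month) {
  t <- year + (month - 0.5) / 12
  g <- cfg$gmst
  g$amp / (1 + exp(-(t - g$mid) / g$width)) + g$lin * (t - g$start)
}

#' Simulate a monthly GMST anomaly series
#'
#' Smooth logistic-plus-linear anthropogenic trend plus AR(1) monthly
#' noise; the 95% CI bounds are the central estimate plus/minus a fixed
#' offset. The noise-free trend (re-baselined so the 1850-1900 mean is
#' zero) is returned as the known truth.
#'
#' @param cfg a [world_config()].
#' @param seed RNG seed.
#' @return list `gmst` (data frame `year`, `month`, `anomaly`,
#'   `anomaly_lower`, `anomaly_upper`) and `g_true` (data frame `year`,
#'   `month`, `g`: the true re-baselined smooth signal).
#' @export
simulate_gmst <- function(cfg, seed = 1L) {
  g <- cfg$gmst
  years <- g$start:max(cfg$study_years)
  grid <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
  trend <- gmst_trend(cfg, grid$year, grid$month)
  set.seed(derive_seed(seed, 1L))
  noise <- as.numeric(stats::filter(stats::rnorm(nrow(grid), 0, g$sd),
                                    g$ar, method = "recursive"))
  anomaly <- g$baseline_offset + trend + noise
  ref <- grid$year >= 1850 & grid$year <= 1900
  list(
    gmst = data.frame(year = grid$year, month = grid$month,
                      anomaly = anomaly,
                      anomaly_lower = anomaly - g$ci_offset,
                      anomaly_upper = anomaly + g$ci_offset),
    g_true = data.frame(year = grid$year, month = grid$month,
                        g = trend - mean(trend[ref]))
  )
}

# season + buffer dates (May 22 - Sep 30) for a set of years
season_dates <- function(years) {
  as.Date(unlist(lapply(years, function(y) {
    seq(as.Date(sprintf("%d-05-22", y)), as.Date(sprintf("%d-09-30", y)), by = 1)
  })), origin = "1970-01-01")
}

#' Simulate daily city temperatures
#'
#' `t(d) = base_i + seasonal(doy) + beta_i * G_true(month) + AR(1) noise`
#' for warm-season days plus the 10-day pre-season buffer (May 22 onward),
#' from `history_start` through the last study year.
#'
#' @param cfg a [world_config()].
#' @param g_true true smooth GMST signal from [simulate_gmst()].
#' @param seed RNG seed.
#' @return list `temps` (data frame `city`, `date`, `tmean`) and `truth`
#'   (data frame `city`, `base`, `beta_true`).
#' @export
simulate_city_temperatures <- function(cfg, g_true, seed = 1L) {
  n <- cfg$n_cities
  tp <- cfg$temp
  cities <- sprintf("city%02d", seq_len(n))
  base <- seq(tp$base_range[1], tp$base_range[2], length.out = n)
  beta <- seq(tp$beta_range[1], tp$beta_range[2], length.out = n)
  years <- cfg$history_start:max(cfg$study_years)
  dates <- season_dates(years)
  doy <- as.integer(format(dates, "%j"))
  seas <- tp$seasonal_amp * cos(2 * pi * (doy - tp$peak_doy) / 365.25)
  gkey <- paste(g_true$year, g_true$month)
  gval <- g_true$g[match(paste(date_year(dates), date_month(dates)), gkey)]
  yr <- date_year(dates)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, 10L + i))
    # AR(1) within each year's block, independent across blocks
    noise <- unlist(lapply(split(seq_along(dates), yr), function(ix) {
      as.numeric(stats::filter(stats::rnorm(length(ix), 0, tp$sd),
                               tp$ar, method = "recursive"))
    }), use.names = FALSE)
    out[[i]] <- data.frame(city = cities[i], date = dates,
                           tmean = base[i] + seas + beta[i] * gval + noise)
  }
  list(temps = do.call(rbind, out),
       truth = data.frame(city = cities, base = base, beta_true = beta))
}

#' Simulate life-expectancy and other meta-predictors
#'
#' Life expectancy rises linearly per city (city-specific slope and
#' offset); the remaining meta-predictors are computed from the simulated
#' temperatures (subperiod mean warm-season temperature and range) or drawn
#' as stationary/mildly trending indicators.
#'
#' @param cfg a [world_config()].
#' @param temps simulated temperatures.
#' @param scheme a [subperiod_scheme()].
#' @param seed RNG seed.
#' @return data frame `city`, `subperiod`, `mid`, `le`, `tmean_annual`,
#'   `trange`, `heat_alert_days`, `mean_age`, `pct_over65`.
#' @export
simulate_meta_predictors <- function(cfg, temps, scheme = subperiod_scheme(),
                                     seed = 1L) {
  n <- cfg$n_cities
  cities <- sprintf("city%02d", seq_len(n))
  off <- seq(cfg$le$offset_range[1], cfg$le$offset_range[2], length.out = n)
  slp <- seq(cfg$le$slope_range[1], cfg$le$slope_range[2], length.out = n)
  temps$date <- as.Date(temps$date)
  ws <- temps[is_warm_season(temps$date), ]
  ws$year <- date_year(ws$date)
  ws$subperiod <- subperiod_of(ws$year, scheme)
  ws <- ws[!is.na(ws$subperiod), ]
  set.seed(derive_seed(seed, 40L))
  out <- expand.grid(city = cities, subperiod = scheme$label,
                     stringsAsFactors = FALSE)
  out$mid <- scheme$mid[match(out$subperiod, scheme$label)]
  i <- match(out$city, cities)
  out$le <- cfg$le$base + off[i] + slp[i] * (out$mid - scheme$mid[1])
  key <- paste(ws$city, ws$subperiod)
  okey <- paste(out$city, out$subperiod)
  out$tmean_annual <- as.numeric(tapply(ws$tmean, key, mean)[okey]) - 4
  out$trange <- as.numeric(tapply(ws$tmean, key,
                                  function(x) diff(range(x)))[okey]) + 10
  out$heat_alert_days <- stats::rpois(nrow(out),
                                      pmax(2, 2 + (out$tmean_annual - 12)))
  out$mean_age <- 42 + 0.03 * (out$mid - scheme$mid[1]) +
    stats::rnorm(nrow(out), 0, 0.3)
  out$pct_over65 <- 17 + 0.08 * (out$mid - scheme$mid[1]) +
    stats::rnorm(nrow(out), 0, 0.4)
  out
}

# project a mildly U-shaped excess-risk target onto the exposure basis:
# quadratic heat rise above the knee percentile plus a weaker cool-side
# rise, so the curve has a well-defined interior minimum (as observed
# warm-season curves do). Returns unit-scale shape coefficients.
association_shape <- function(spec, temps_ws, knee_prob, cold_prob = 0.4,
                              cold_amp = 0.35) {
  qs <- stats::quantile(temps_ws, c(cold_prob, knee_prob, 0.99),
                        type = 7, names = FALSE)
  grid <- seq(spec$boundary[1], spec$boundary[2], length.out = 200)
  target <- pmax((grid - qs[2]) / (qs[3] - qs[2]), 0)^2 +
    cold_amp * pmax((qs[1] - grid) / (qs[1] - spec$boundary[1]), 0)^2
  B <- ns_basis(grid, spec)
  as.numeric(stats::coef(stats::lm(target ~ B))[-1])
}

#' Simulate daily death counts with a known exposure-lag-response surface
#'
#' Negative-binomial daily deaths whose log mean combines a city baseline,
#' mild seasonality, day-of-week effects, a slow year trend, and a
#' distributed-lag heat effect: exponentially decaying lag weights applied
#' to a natural-cubic-spline cumulative curve whose 99th-percentile
#' relative risk declines with the city's life expectancy
#' (`log RR99 = max(floor, log(rr99_base) - le_slope * (LE - LE_first))`).
#' The true cumulative coefficients, minimum mortality temperature and
#' baseline components are recorded per city and subperiod.
#'
#' @param cfg a [world_config()].
#' @param temps simulated temperatures (all cities).
#' @param metapred meta-predictor table with the `le` trajectories.
#' @param scheme a [subperiod_scheme()].
#' @param seed RNG seed.
#' @return list `deaths` (data frame `city`, `date`, `deaths` for
#'   warm-season study days) and `truth` (per-city list: exposure spec,
#'   `theta_true` per subperiod, `mmt_true`, `rr99_true`, lag weights,
#'   baseline parameters).
#' @export
simulate_mortality <- function(cfg, temps, metapred,
                               scheme = subperiod_scheme(), seed = 1L) {
  mt <- cfg$mort; ac <- cfg$assoc
  n <- cfg$n_cities
  cities <- sprintf("city%02d", seq_len(n))
  base <- seq(mt$base_range[1], mt$base_range[2], length.out = n)
  w <- exp(-(0:ac$max_lag) / ac$lag_decay)
  w <- w / sum(w)
  temps$date <- as.Date(temps$date)
  study <- cfg$study_years

  deaths_out <- vector("list", n)
  truth <- vector("list", n)
  names(truth) <- cities
  mmt_probs <- seq(0.25, 0.99, by = 0.001)

  for (i in seq_len(n)) {
    tc <- temps[temps$city == cities[i] & date_year(temps$date) %in% study, ]
    tc <- tc[order(tc$date), ]
    ws_t <- tc$tmean[is_warm_season(tc$date)]
    spec <- exposure_spec(ws_t)
    shape <- association_shape(spec, ws_t, ac$knee_prob)
    grid <- stats::quantile(ws_t, mmt_probs, type = 7, names = FALSE)
    cvals <- as.numeric(ns_basis(grid, spec) %*% shape)
    mmt_true <- grid[which.min(cvals)]
    p99 <- stats::quantile(ws_t, 0.99, type = 7, names = FALSE)
    span <- as.numeric((ns_basis(p99, spec) - ns_basis(mmt_true, spec)) %*% shape)

    mp <- metapred[metapred$city == cities[i], ]
    mp <- mp[match(scheme$label, mp$subperiod), ]
    logrr99 <- pmax(ac$floor, log(ac$rr99_base) -
                      ac$le_slope * (mp$le - mp$le[1]))
    theta_true <- lapply(logrr99 / span, function(lam) lam * shape)
    names(theta_true) <- scheme$label

    # distributed-lag contribution for each warm-season day
    out_idx <- which(is_warm_season(tc$date))
    Ball <- ns_basis(tc$tmean, spec)
    cmmt <- as.numeric(ns_basis(mmt_true, spec))
    sub <- subperiod_of(date_year(tc$date[out_idx]), scheme)
    lag_ok <- vapply(0:ac$max_lag, function(l) {
      all(tc$date[out_idx - l] == tc$date[out_idx] - l)
    }, logical(1))
    if (!all(lag_ok)) stopf("temperature series has gaps inside the lag buffer")
    delta <- numeric(length(out_idx))
    for (s in seq_len(nrow(scheme))) {
      rows <- which(sub == scheme$label[s])
      if (!length(rows)) next
      crel <- as.numeric(Ball %*% theta_true[[s]]) -
        as.numeric(cmmt %*% theta_true[[s]])
      for (l in 0:ac$max_lag) {
        delta[rows] <- delta[rows] + w[l + 1] * crel[out_idx[rows] - l]
      }
    }
    dts <- tc$date[out_idx]
    doy <- as.integer(format(dts, "%j"))
    dow <- as.integer(format(dts, "%u"))
    dow_eff <- mt$dow - mean(mt$dow)
    logmu <- log(base[i]) + mt$season_amp * cos(2 * pi * (doy - 32) / 365.25) +
      dow_eff[dow] + mt$year_trend * (date_year(dts) - study[1]) + delta
    if (any(logmu > 20)) stopf("mortality rate overflow")
    mu <- exp(logmu)
    set.seed(derive_seed(seed, 60L + i))
    d <- if (mt$dispersion > 1) {
      stats::rnbinom(length(mu), mu = mu, size = mu / (mt$dispersion - 1))
    } else {
      stats::rpois(length(mu), mu)
    }
    deaths_out[[i]] <- data.frame(city = cities[i], date = dts, deaths = d)
    truth[[i]] <- list(
      spec = spec, theta_true = theta_true, mmt_true = mmt_true,
      rr99_true = exp(logrr99), lag_weights = w,
      baseline = list(log_base = log(base[i]), season_amp = mt$season_amp,
                      dow = dow_eff, year_trend = mt$year_trend,
                      year0 = study[1])
    )
  }
  list(deaths = do.call(rbind, deaths_out), truth = truth)
}

# expected baseline (no-heat) death rate for given dates of one city
baseline_rate <- function(city_truth, dates) {
  b <- city_truth$baseline
  doy <- as.integer(format(dates, "%j"))
  dow <- as.integer(format(dates, "%u"))
  exp(b$log_base + b$season_amp * cos(2 * pi * (doy - 32) / 365.25) +
        b$dow[dow] + b$year_trend * (date_year(dates) - b$year0))
}

#' Closed-form expected attributable deaths under the true surface
#'
#' For a temperature series (factual or counterfactual) and an association
#' variant, computes the true expected heat-attributable deaths per year:
#' `sum over days with x > MMT of lambda0(t) * (exp(Delta(t)) - 1)`, where
#' `Delta(t)` is the true cumulative log relative risk at the day's
#' temperature versus the true MMT.
#'
#' @param truth per-city truth from [simulate_mortality()].
#' @param temps data frame `date`, `tmean` for one city (warm seasons).
#' @param scheme a [subperiod_scheme()].
#' @param association `"factual"` (subperiod-specific true coefficients) or
#'   `"counterfactual"` (first-subperiod coefficients throughout, the
#'   no-life-expectancy-improvement world).
#' @return data frame `year`, `an_true`.
#' @export
expected_attribution <- function(truth, temps, scheme = subperiod_scheme(),
                                 association = c("factual", "counterfactual")) {
  association <- match.arg(association)
  temps$date <- as.Date(temps$date)
  sel <- is_warm_season(temps$date)
  dts <- temps$date[sel]
  x <- temps$tmean[sel]
  yr <- date_year(dts)
  sub <- subperiod_of(yr, scheme)
  lam0 <- baseline_rate(truth, dts)
  delta <- numeric(length(x))
  B <- ns_basis(x, truth$spec)
  cmmt <- as.numeric(ns_basis(truth$mmt_true, truth$spec))
  for (s in scheme$label) {
    rows <- which(sub == s)
    if (!length(rows)) next
    th <- if (association == "factual") truth$theta_true[[s]] else truth$theta_true[[1]]
    delta[rows] <- as.numeric(B[rows, , drop = FALSE] %*% th) - sum(cmmt * th)
  }
  an <- ifelse(x > truth$mmt_true, lam0 * (exp(delta) - 1), 0)
  agg <- rowsum(an, yr)
  data.frame(year = as.integer(rownames(agg)), an_true = agg[, 1])
}

#' Simulate a complete synthetic world
#'
#' Runs all generators under a hierarchical seeding scheme derived from one
#' master seed and returns every input the pipeline reads plus the truth
#' bundle.
#'
#' @param cfg a [world_config()].
#' @param seed master seed.
#' @param scheme a [subperiod_scheme()].
#' @return list `gmst`, `temps`, `deaths`, `metapred`, `truth` (with
#'   `g_true`, per-city temperature and association truth), `config`,
#'   `seed`.
#' @export
simulate_world <- function(cfg = world_config(), seed = 1L,
                           scheme = subperiod_scheme()) {
  gm <- simulate_gmst(cfg, seed)
  ct <- simulate_city_temperatures(cfg, gm$g_true, seed)
  mp <- simulate_meta_predictors(cfg, ct$temps, scheme, seed)
  mo <- simulate_mortality(cfg, ct$temps, mp, scheme, seed)
  list(gmst = gm$gmst, temps = ct$temps, deaths = mo$deaths, metapred = mp,
       truth = list(g_true = gm$g_true, cities = ct$truth, assoc = mo$truth),
       config = cfg, seed = seed, scheme = scheme)
}

#' Write a synthetic world to CSV files
#'
#' Writes `gmst.csv`, `citytemp.csv`, `citymort.csv`, `metapred.csv` and a
#' `truth.json` summary in the formats the pipeline reads.
#'
#' @param world a [simulate_world()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(world$gmst, file.path(dir, "gmst.csv"), row.names = FALSE)
  utils::write.csv(world$temps, file.path(dir, "citytemp.csv"), row.names = FALSE)
  utils::write.csv(world$deaths, file.path(dir, "citymort.csv"), row.names = FALSE)
  utils::write.csv(world$metapred, file.path(dir, "metapred.csv"), row.names = FALSE)
  truth <- list(
    seed = world$seed,
    beta_true = stats::setNames(world$truth$cities$beta_true,
                                world$truth$cities$city),
    mmt_true = vapply(world$truth$assoc, `[[`, numeric(1), "mmt_true"),
    rr99_true = lapply(world$truth$assoc, `[[`, "rr99_true")
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
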