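test_that("GMST generator is exact without noise and reproducible with it", {
  cfg0 <- world_config(gmst = list(sd = 1e-12))
  gm0 <- simulate_gmst(cfg0, seed = 1)
  trend <- heatattr:::gmst_trend(cfg0, gm0$gmst$year, gm0$gmst$month) +
    cfg0$gmst$baseline_offset
  expect_equal(gm0$gmst$anomaly, trend, tolerance = 1e-8)
  gm1 <- simulate_gmst(world_config(), seed = 5)
  gm2 <- simulate_gmst(world_config(), seed = 5)
  expect_identical(gm1$gmst$anomaly, gm2$gmst$anomaly)
  # noise averages out over the long series
  resid <- gm1$gmst$anomaly - (heatattr:::gmst_trend(world_config(),
    gm1$gmst$year, gm1$gmst$month) + world_config()$gmst$baseline_offset)
  se <- stats::sd(resid) / sqrt(length(resid) / 20)  # generous for AR(1)
  expect_lt(abs(mean(resid)), 3 * se)
  expect_equal(gm1$gmst$anomaly_upper - gm1$gmst$anomaly_lower,
               rep(0.1, nrow(gm1$gmst)))
})

test_that("city temperatures carry the configured GMST coupling", {
  cfg <- world_config(n_cities = 2L, study_years = 2001:2010,
                      history_start = 1981L,
                      temp = list(sd = 1e-9, seasonal_amp = 0,
                                  beta_range = c(1.5, 1.5)))
  gm <- simulate_gmst(cfg, seed = 2)
  ct <- simulate_city_temperatures(cfg, gm$g_true, seed = 2)
  t1 <- ct$temps[ct$temps$city == "city01", ]
  g <- gm$g_true$g[match(paste(heatattr:::date_year(t1$date),
                               heatattr:::date_month(t1$date)),
                         paste(gm$g_true$year, gm$g_true$month))]
  # noise- and seasonality-free: t - beta * G is the constant city base
  expect_lt(diff(range(t1$tmean - 1.5 * g)), 1e-6)
  # beta = 0: regressing warm-season means on the smooth signal finds nothing
  cfg0 <- world_config(n_cities = 1L, study_years = 2001:2030,
                       history_start = 1951L,
                       temp = list(beta_range = c(0, 0)))
  gm0 <- simulate_gmst(cfg0, seed = 3)
  ct0 <- simulate_city_temperatures(cfg0, gm0$g_true, seed = 3)
  ann <- warm_season_means(ct0$temps)
  g_ann <- stats::aggregate(g ~ year, data.frame(year = gm0$g_true$year,
                                                 g = gm0$g_true$g), mean)
  d <- merge(ann, g_ann)
  t_stat <- summary(stats::lm(tmean ~ g, d))$coefficients[2, 3]
  expect_lt(abs(t_stat), 3)
})

test_that("the scaling fit recovers the true coupling through the pipeline", {
  cfg <- world_config(n_cities = 3L)
  w <- simulate_world(cfg, seed = 11)
  sg <- smooth_gmst(w$gmst)
  covered <- vapply(sprintf("city%02d", 1:3), function(ct) {
    ann <- warm_season_means(w$temps[w$temps$city == ct, ])
    f <- fit_city_scaling(ann, sg, city = ct)
    bt <- w$truth$cities$beta_true[w$truth$cities$city == ct]
    f$slope_ci["lower"] <= bt && bt <= f$slope_ci["upper"]
  }, logical(1))
  expect_gte(sum(covered), 2L)
})

test_that("meta-predictor table follows its configuration", {
  cfg <- world_config(n_cities = 4L, le = list(slope_range = c(0, 0)))
  w <- simulate_world(cfg, seed = 4)
  le_by_city <- split(w$metapred$le, w$metapred$city)
  for (v in le_by_city) expect_lt(diff(range(v)), 1e-10)
  cfg2 <- world_config(n_cities = 2L, le = list(slope_range = c(0.2, 0.2)))
  mp2 <- simulate_meta_predictors(cfg2, simulate_world(cfg, seed = 4)$temps[
    simulate_world(cfg, seed = 4)$temps$city %in% c("city01", "city02"), ],
    seed = 4)
  inc <- diff(mp2$le[mp2$city == "city01"][order(mp2$mid[mp2$city == "city01"])])
  expect_equal(inc, rep(0.2 * 5, 5), tolerance = 1e-10)
  expect_identical(simulate_meta_predictors(cfg2, w$temps, seed = 9),
                   simulate_meta_predictors(cfg2, w$temps, seed = 9))
})

test_that("mortality without a heat effect yields a flat fitted association", {
  cfg <- world_config(n_cities = 1L, study_years = 2001:2005,
                      history_start = 2001L,
                      assoc = list(rr99_base = 1.0000001, floor = 0),
                      mort = list(base_range = c(60, 60)))
  w <- simulate_world(cfg, seed = 6, scheme = subperiod_scheme(2001, 2005, 5))
  fs <- first_stage(w$temps, w$deaths, scheme = subperiod_scheme(2001, 2005, 5))
  red <- fs$reduced[[1]]
  tw <- w$temps[heatattr:::is_warm_season(as.Date(w$temps$date)), ]
  p99 <- stats::quantile(tw$tmean, 0.99, type = 7)
  p50 <- stats::quantile(tw$tmean, 0.5, type = 7)
  pr <- predict_rr(red, at = p99, center = p50)
  expect_gt(pr$rr_hi, 1)
  expect_lt(pr$rr_lo, 1.12)
})

test_that("negative-binomial dispersion approaches Poisson in the limit", {
  world <- make_assoc_world(years = 2001:2003, seed = 7, dispersion = 1)
  set.seed(7)
  d <- draw_deaths(world)
  expect_lt(abs(stats::var(d[1:122] / world$mu[1:122] * mean(world$mu[1:122])) /
                  mean(world$mu[1:122]) - 1), 0.4)
  world2 <- make_assoc_world(years = 2001:2003, seed = 7, dispersion = 2)
  set.seed(7)
  d2 <- draw_deaths(world2)
  expect_gt(stats::var(d2 / world2$mu) * mean(world2$mu) /
              stats::var(d / world$mu) / mean(world$mu), 1.2)
})

test_that("declining RR(LE) is recovered as declining fitted subperiod RRs", {
  cfg <- world_config(n_cities = 2L)
  w <- simulate_world(cfg, seed = 8)
  fs <- first_stage(w$temps, w$deaths)
  for (ct in c("city01", "city02")) {
    tr <- w$truth$assoc[[ct]]
    ix <- grep(ct, names(fs$reduced))
    rr <- vapply(ix, function(k) {
      red <- fs$reduced[[k]]
      tw <- w$temps[w$temps$city == ct, ]
      tw <- tw[heatattr:::is_warm_season(as.Date(tw$date)), ]
      p99 <- stats::quantile(tw$tmean, 0.99, type = 7)
      predict_rr(red, at = p99, center = tr$mmt_true)$rr
    }, numeric(1))
    # monotone-trend sign: later subperiods have lower fitted RR on average
    expect_lt(mean(rr[4:6]), mean(rr[1:3]))
  }
})

test_that("closed-form expected attribution obeys its degenerate identities", {
  cfg <- world_config(n_cities = 1L, study_years = 2001:2005,
                      history_start = 2001L)
  w <- simulate_world(cfg, seed = 9, scheme = subperiod_scheme(2001, 2005, 5))
  tr <- w$truth$assoc$city01
  temps1 <- w$temps[w$temps$city == "city01", ]
  # zero effect: zero expected attributable deaths
  tr0 <- tr
  tr0$theta_true <- lapply(tr$theta_true, function(x) x * 0)
  ea0 <- expected_attribution(tr0, temps1,
                              scheme = subperiod_scheme(2001, 2005, 5))
  expect_equal(ea0$an_true, rep(0, 5))
  # a single day at RR 2 above the baseline contributes lambda0 deaths
  b <- heatattr:::baseline_rate(tr, as.Date("2003-07-15"))
  expect_equal(b * (exp(log(2)) - 1), b)
})

test_that("generators are bit-reproducible under the master seed", {
  cfg <- world_config(n_cities = 2L, study_years = 2001:2005,
                      history_start = 1996L)
  s1 <- subperiod_scheme(2001, 2005, 5)
  w1 <- simulate_world(cfg, seed = 123, scheme = s1)
  w2 <- simulate_world(cfg, seed = 123, scheme = s1)
  expect_identical(w1$temps, w2$temps)
  expect_identical(w1$deaths, w2$deaths)
  expect_identical(w1$metapred, w2$metapred)
  w3 <- simulate_world(cfg, seed = 124, scheme = s1)
  expect_false(identical(w1$deaths, w3$deaths))
})
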