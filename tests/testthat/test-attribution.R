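test_that("MMT search matches its defining brute-force minimum", {
  set.seed(31)
  temps <- rnorm(2000, 18, 4)
  spec <- exposure_spec(temps)
  # strictly increasing curve: minimum at the lower search bound
  th_up <- heatattr:::association_shape(spec, temps, 0.3, cold_amp = 0)
  m <- find_mmt(th_up, spec, temps)
  expect_equal(m$percentile, 25)
  # random coefficients: equals exhaustive grid minimum
  for (i in 1:10) {
    th <- rnorm(3, 0, 0.3)
    grid <- stats::quantile(temps, seq(0.25, 0.99, 0.001), type = 7,
                            names = FALSE)
    vals <- as.numeric(ns_basis(grid, spec) %*% th)
    expect_equal(find_mmt(th, spec, temps)$mmt, grid[which.min(vals)])
  }
})

test_that("a U-shaped curve yields its interior vertex as the MMT", {
  set.seed(32)
  temps <- rnorm(3000, 18, 4)
  spec <- exposure_spec(temps)
  vertex <- stats::quantile(temps, 0.60, type = 7, names = FALSE)
  # quadratic in the spline space: project (x - vertex)^2 onto the basis
  grid <- seq(spec$boundary[1], spec$boundary[2], length.out = 300)
  th <- unname(stats::coef(stats::lm(I((grid - vertex)^2) ~
                                       ns_basis(grid, spec)))[-1])
  m <- find_mmt(th, spec, temps)
  expect_lt(abs(m$mmt - vertex), 0.3)
})

test_that("single-day attribution follows the forward formula exactly", {
  # one hot day with cumulative RR 2 and forward-mean deaths 10 -> AN 5
  dates <- seq(as.Date("2010-06-01"), as.Date("2010-09-30"), by = 1)
  n <- length(dates)
  temps <- rep(15, n); temps[40] <- 25
  deaths <- rep(10L, n)
  spec <- exposure_spec(seq(10, 26, length.out = 200))
  # coefficients giving log-RR exactly log(2) at 25 vs MMT 15
  D <- as.numeric(ns_basis(25, spec) - ns_basis(15, spec))
  th <- log(2) * D / sum(D^2)
  ad <- attributable_deaths(dates, temps, deaths, th, spec, mmt = 15)
  expect_equal(sum(ad$daily$an), 5)
  expect_equal(ad$annual$af, 100 * 5 / sum(deaths))
  # all days at or below the MMT: zero
  ad0 <- attributable_deaths(dates, rep(15, n), deaths, th, spec, mmt = 15)
  expect_equal(sum(ad0$daily$an), 0)
})

test_that("daily attribution matches a hand spreadsheet on a toy series", {
  dates <- seq(as.Date("2011-06-01"), as.Date("2011-06-20"), by = 1)
  set.seed(33)
  temps <- c(14, 16, 22, 25, 24, 15, 14, 23, 22, 13,
             12, 26, 25, 24, 14, 13, 12, 22, 21, 20)
  deaths <- rpois(20, 30)
  spec <- exposure_spec(seq(10, 27, length.out = 100))
  th <- c(0.08, 0.15, 0.1)
  mmt <- 18
  ad <- attributable_deaths(dates, temps, deaths, th, spec, mmt, max_lag = 3)
  hand <- numeric(20)
  for (t in 1:20) {
    if (temps[t] > mmt) {
      delta <- sum((ns_basis(temps[t], spec) - ns_basis(mmt, spec)) * th)
      fwd <- mean(deaths[t:min(t + 3, 20)])
      hand[t] <- (1 - exp(-delta)) * fwd
    }
  }
  expect_equal(ad$daily$an, hand, tolerance = 1e-12)
  expect_true(all(ad$daily$an >= 0))
})

test_that("attributable deaths are monotone in heat for monotone curves", {
  dates <- seq(as.Date("2012-06-01"), as.Date("2012-09-30"), by = 1)
  set.seed(34)
  temps <- rnorm(length(dates), 18, 4)
  deaths <- rpois(length(dates), 40)
  spec <- exposure_spec(temps)
  th <- heatattr:::association_shape(spec, temps, 0.5, cold_amp = 0) * 0.5
  mmt <- find_mmt(th, spec, temps)$mmt
  base <- sum(attributable_deaths(dates, temps, deaths, th, spec, mmt)$daily$an)
  hot <- which(temps > mmt)[1]
  temps2 <- temps; temps2[hot] <- temps2[hot] + 2
  more <- sum(attributable_deaths(dates, temps2, deaths, th, spec, mmt)$daily$an)
  expect_gte(more, base)
  # uniformly colder counterfactual cannot raise the attributable burden
  cold <- sum(attributable_deaths(dates, temps - 1.5, deaths, th, spec,
                                  find_mmt(th, spec, temps - 1.5)$mmt)$daily$an)
  expect_gte(base, cold)
})

test_that("city aggregation sums attributable numbers and deaths", {
  a1 <- data.frame(year = 2001:2003, an = c(10, 12, 8), deaths = 1000)
  a2 <- data.frame(year = 2001:2003, an = c(20, 18, 25), deaths = 1000)
  agg <- aggregate_attribution(list(a1, a2))
  expect_equal(agg$an, c(30, 30, 33))
  expect_equal(agg$af[1], 100 * 30 / 2000)
  expect_error(aggregate_attribution(list(a1, a2[-1, ])), "different years")
})

test_that("climate-change attribution identities hold", {
  f <- data.frame(year = 2001:2005, an = c(10, 12, 8, 15, 9), deaths = 1000)
  f$af <- 100 * f$an / f$deaths
  same <- climate_attribution(f, f)
  expect_equal(same$annual$an_cc, rep(0, 5))
  expect_equal(unname(same$period["af_cc"]), 0)
  zero <- transform(f, an = 0, af = 0)
  all_cc <- climate_attribution(f, zero)
  expect_equal(all_cc$annual$p_cc, rep(100, 5))
  expect_equal(unname(all_cc$period["p_cc"]), 100)
  f0 <- transform(f, an = 0, af = 0)
  und <- climate_attribution(f0, f0)
  expect_true(all(is.na(und$annual$p_cc)))
})

test_that("day-of-year baseline averages across years", {
  dates <- c(seq(as.Date("2001-06-01"), as.Date("2001-09-30"), by = 1),
             seq(as.Date("2002-06-01"), as.Date("2002-09-30"), by = 1))
  d <- data.frame(city = "a", date = dates,
                  deaths = rep(c(10, 20), each = 122))
  out <- doy_baseline(d)
  expect_equal(out$deaths, rep(15, 244))
  d2 <- transform(d, deaths = rep(c(10, 10), each = 122))
  expect_equal(doy_baseline(d2)$deaths, d2$deaths)
})

test_that("Monte Carlo empirical CIs are reproducible and calibrated", {
  th <- list(c(0.5, -0.2, 0.1))
  V <- list(diag(c(0.04, 0.01, 0.02)))
  f <- function(tl) c(q = sum(tl[[1]] * c(1, 2, 3)))
  # zero covariance collapses the interval
  z <- mc_eci(th, list(diag(0, 3)), f, n = 200, seed = 5)
  expect_equal(unname(z$lo), unname(z$point))
  expect_equal(unname(z$hi), unname(z$point))
  # linear quantity: matches analytic normal quantiles
  e <- mc_eci(th, V, f, n = 4000, seed = 6)
  sd_true <- sqrt(sum(c(1, 2, 3)^2 * diag(V[[1]])))
  mu <- sum(th[[1]] * c(1, 2, 3))
  expect_lt(abs(unname(e$lo) - (mu - 1.959964 * sd_true)), 0.06)
  expect_lt(abs(unname(e$hi) - (mu + 1.959964 * sd_true)), 0.06)
  # determinism under the seed
  e2 <- mc_eci(th, V, f, n = 100, seed = 7)
  e3 <- mc_eci(th, V, f, n = 100, seed = 7)
  expect_identical(e2$draws, e3$draws)
  expect_error(mc_eci(th, list(matrix(c(1, 2, 2, 1), 2)), f), "PSD")
})
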