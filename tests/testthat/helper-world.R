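# shared helpers for building small synthetic inputs in tests

# a single city's season+buffer daily series with AR(1) noise
make_city_series <- function(years, seed = 1, base = 11, amp = 8.5,
                             sd = 1.3, ar = 0.7, beta = 0, gval = NULL) {
  set.seed(seed)
  dates <- heatattr:::season_dates(years)
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  noise <- unlist(lapply(split(seq_along(dates), yr), function(ix) {
    as.numeric(stats::filter(rnorm(length(ix), 0, sd), ar, method = "recursive"))
  }), use.names = FALSE)
  warm <- if (is.null(gval)) 0 else beta * gval[match(
    paste(yr, as.integer(format(dates, "%m"))), paste(gval$year, gval$month))]
  data.frame(date = dates,
             tmean = base + amp * cos(2 * pi * (doy - 201) / 365.25) + noise)
}

# one city-subperiod world with a known cumulative exposure-response:
# returns everything needed to simulate deaths and check recovery
make_assoc_world <- function(years = 2001:2005, seed = 1, rr99 = 1.30,
                             base_deaths = 40, dispersion = 1.3,
                             lag_decay = 1.5, max_lag = 10L) {
  tc <- make_city_series(years, seed = seed)
  ws <- heatattr::ns_basis  # force package resolution
  warm <- heatattr:::is_warm_season(tc$date)
  spec <- exposure_spec(tc$tmean[warm])
  shape <- heatattr:::association_shape(spec, tc$tmean[warm], 0.6)
  grid <- stats::quantile(tc$tmean[warm], seq(0.25, 0.99, 0.001), type = 7)
  mmt <- grid[which.min(as.numeric(ns_basis(grid, spec) %*% shape))]
  p99 <- stats::quantile(tc$tmean[warm], 0.99, type = 7, names = FALSE)
  span <- as.numeric((ns_basis(p99, spec) - ns_basis(mmt, spec)) %*% shape)
  theta <- shape * (log(rr99) / span)
  w <- exp(-(0:max_lag) / lag_decay); w <- w / sum(w)
  crel <- as.numeric(ns_basis(tc$tmean, spec) %*% theta) -
    as.numeric(ns_basis(mmt, spec) %*% theta)
  oi <- which(warm)
  delta <- numeric(length(oi))
  for (l in 0:max_lag) delta <- delta + w[l + 1] * crel[oi - l]
  dow <- as.integer(format(tc$date[oi], "%u"))
  doy <- as.integer(format(tc$date[oi], "%j"))
  logmu <- log(base_deaths) + 0.03 * cos(2 * pi * (doy - 32) / 365.25) +
    c(0.01, 0, -0.005, 0, 0.005, 0.02, 0.015)[dow] + delta
  list(temps = tc, out_dates = tc$date[oi], mu = exp(logmu), spec = spec,
       theta = theta, mmt = mmt, p99 = p99, delta = delta,
       dispersion = dispersion)
}

draw_deaths <- function(world) {
  if (world$dispersion > 1) {
    rnbinom(length(world$mu), mu = world$mu,
            size = world$mu / (world$dispersion - 1))
  } else rpois(length(world$mu), world$mu)
}

# small meta-analysis dataset: nc cities x ns subperiods, d = 3 outcomes
make_meta_data <- function(nc = 15, ns = 6, psi_sd = 0.1, seed = 1,
                           beta_x = c(0, 0, 0), s_range = c(0.005, 0.02)) {
  set.seed(seed)
  n <- nc * ns
  g <- rep(seq_len(nc), each = ns)
  x <- rnorm(n)
  th <- matrix(NA_real_, n, 3)
  S <- vector("list", n)
  for (i in seq_len(nc)) {
    u <- rnorm(3, 0, psi_sd)
    for (k in seq_len(ns)) {
      r <- (i - 1) * ns + k
      Sk <- diag(runif(3, s_range[1], s_range[2]))
      S[[r]] <- Sk
      th[r, ] <- c(0.1, 0.2, 0.3) + beta_x * x[r] + u +
        drop(t(chol(Sk)) %*% rnorm(3))
    }
  }
  list(theta = th, S = S, groups = g, data = data.frame(x = x),
       subperiod = rep(seq_len(ns), nc))
}
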