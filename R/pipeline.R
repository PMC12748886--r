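#' Pipeline configuration
#'
#' Collects every switch of the end-to-end analysis, including the four
#' sensitivity-analysis variants: 5-year moving-average GMST smoothing
#' instead of SSA, day-of-year-averaged baseline mortality, five 6-year
#' subperiods instead of six 5-year ones, and exclusion of individual years.
#'
#' @param study_years analysis years.
#' @param subperiod_width 5 (default) or 6.
#' @param gmst_method `"ssa"` or `"annual_ma"`.
#' @param baseline `"observed"` or `"doy_mean"`.
#' @param exclude_years years excluded from model fitting and attribution.
#' @param n_mc Monte Carlo samples for empirical CIs (0 disables).
#' @param seed master seed for all randomness.
#' @param select run stepwise meta-predictor selection; if `FALSE`,
#'   `meta_formula` is used as-is.
#' @param meta_formula fixed meta-regression formula when `select = FALSE`
#'   (must include `le` for counterfactual BLUPs); `NULL` means the base
#'   year-spline model plus `le`.
#' @param candidates candidate meta-predictors for selection.
#' @param ensemble_trends also compute per-city trends for all 9
#'   counterfactual ensemble members (needed for the rank tests).
#' @param max_lag distributed-lag window in days.
#' @param out_dir if non-`NULL`, write all outputs there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(study_years = 1993:2022, subperiod_width = 5L,
                            gmst_method = c("ssa", "annual_ma"),
                            baseline = c("observed", "doy_mean"),
                            exclude_years = integer(0), n_mc = 1000L,
                            seed = 1L, select = TRUE, meta_formula = NULL,
                            candidates = c("le", "tmean_annual", "trange",
                                           "heat_alert_days", "mean_age",
                                           "pct_over65"),
                            ensemble_trends = TRUE, max_lag = 10L,
                            out_dir = NULL) {
  structure(list(
    study_years = study_years, subperiod_width = as.integer(subperiod_width),
    gmst_method = match.arg(gmst_method), baseline = match.arg(baseline),
    exclude_years = as.integer(exclude_years), n_mc = as.integer(n_mc),
    seed = as.integer(seed), select = select, meta_formula = meta_formula,
    candidates = candidates, ensemble_trends = ensemble_trends,
    max_lag = as.integer(max_lag), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Validate pipeline input tables
#'
#' Checks column presence and types, duplicated or gappy dates (including
#' the 10-day pre-season buffer), negative death counts, and GMST month
#' contiguity and bound ordering. All violations are collected rather than
#' stopping at the first.
#'
#' @param inputs list with elements `gmst`, `temps`, `deaths`, `metapred`
#'   (any subset), or a directory containing the corresponding CSV files.
#' @param study_years years whose warm-season continuity is enforced.
#' @return data frame `table`, `problem` (zero rows if clean).
#' @export
validate_inputs <- function(inputs, study_years = 1993:2022) {
  if (is.character(inputs)) inputs <- read_inputs(inputs)
  probs <- list()
  add <- function(tab, msg) probs[[length(probs) + 1L]] <<- data.frame(
    table = tab, problem = msg, stringsAsFactors = FALSE)

  need <- list(gmst = c("year", "month", "anomaly", "anomaly_lower", "anomaly_upper"),
               temps = c("city", "date", "tmean"),
               deaths = c("city", "date", "deaths"),
               metapred = c("city", "subperiod", "le"))
  for (tab in names(need)) {
    df <- inputs[[tab]]
    if (is.null(df)) next
    miss <- setdiff(need[[tab]], names(df))
    if (length(miss)) {
      add(tab, sprintf("missing columns: %s", paste(miss, collapse = ", ")))
      next
    }
    if (tab == "gmst") {
      o <- order(df$year, df$month)
      ym <- df$year[o] * 12L + df$month[o]
      if (anyDuplicated(ym)) add(tab, "duplicated year-month rows")
      else if (any(diff(ym) != 1L)) add(tab, "non-contiguous months")
      if (any(df$anomaly_lower > df$anomaly | df$anomaly > df$anomaly_upper)) {
        add(tab, "bounds violate lower <= central <= upper")
      }
    }
    if (tab %in% c("temps", "deaths")) {
      df$date <- as.Date(df$date)
      key <- paste(df$city, df$date)
      if (anyDuplicated(key)) add(tab, "duplicated city-date rows")
      if (tab == "deaths" && any(df$deaths < 0, na.rm = TRUE)) {
        add(tab, "negative death counts")
      }
      full <- if (tab == "temps") season_dates(study_years) else {
        d <- season_dates(study_years); d[is_warm_season(d)]
      }
      for (ct in unique(df$city)) {
        have <- df$date[df$city == ct]
        gap <- setdiff(as.integer(full), as.integer(have))
        if (length(gap)) {
          add(tab, sprintf("%s: %d missing days in study seasons (first: %s)",
                           ct, length(gap),
                           format(as.Date(gap[1], origin = "1970-01-01"))))
        }
      }
    }
  }
  if (length(probs)) do.call(rbind, probs) else
    data.frame(table = character(0), problem = character(0))
}

read_inputs <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  list(gmst = rd("gmst.csv"), temps = rd("citytemp.csv"),
       deaths = rd("citymort.csv"), metapred = rd("metapred.csv"))
}

# scenario attribution engine: point estimates and Monte Carlo draws for
# the four (temperature x association) scenario families
attribute_scenarios <- function(blups_f, blups_cf, units, temps_f, temps_cf,
                                deaths, specs, scheme, max_lag = 10L,
                                n_mc = 0L, seed = 1L, years = NULL) {
  temps_f$date <- as.Date(temps_f$date)
  temps_cf$date <- as.Date(temps_cf$date)
  deaths$date <- as.Date(deaths$date)
  cities <- sort(unique(units$city))
  scen <- expand.grid(temp = c("factual", "counterfactual"),
                      assoc = c("with_le", "wo_le"),
                      stringsAsFactors = FALSE)
  scen$label <- paste(scen$temp, scen$assoc, sep = "_")

  if (n_mc > 0L) set.seed(derive_seed(seed, 99L))
  annual <- list(); percity_climate <- list()
  allcity <- NULL; allcity_draws <- NULL

  for (ct in cities) {
    tf <- temps_f[temps_f$city == ct & is_warm_season(temps_f$date), ]
    tf <- tf[order(tf$date), ]
    tc <- temps_cf[temps_cf$city == ct & is_warm_season(temps_cf$date), ]
    tc <- tc[order(tc$date), ]
    dd <- deaths[deaths$city == ct, ]
    dd <- dd[order(dd$date), ]
    if (!is.null(years)) {
      tf <- tf[date_year(tf$date) %in% years, ]
      tc <- tc[date_year(tc$date) %in% years, ]
      dd <- dd[date_year(dd$date) %in% years, ]
    }
    if (!identical(tf$date, dd$date) || !identical(tc$date, dd$date)) {
      stopf("temperature and death dates misaligned for %s", ct)
    }
    spec <- specs[[ct]]
    yr <- date_year(dd$date)
    yrs <- sort(unique(yr))
    fwd <- forward_mean_deaths(dd$date, dd$deaths, max_lag)
    deaths_year <- rowsum(dd$deaths, yr)[, 1]
    B_f <- ns_basis(tf$tmean, spec)
    B_c <- ns_basis(tc$tmean, spec)
    urows <- which(units$city == ct)
    sub <- subperiod_of(yr, scheme)

    an_point <- array(0, c(length(yrs), nrow(scen)),
                      dimnames = list(yrs, scen$label))
    an_draws <- if (n_mc > 0L) array(0, c(length(yrs), n_mc, nrow(scen)),
                                     dimnames = list(yrs, NULL, scen$label))
    Zs <- if (n_mc > 0L) lapply(urows, function(k) matrix(stats::rnorm(3 * n_mc), 3))

    for (jj in seq_along(urows)) {
      k <- urows[jj]
      s <- units$subperiod[k]
      rows <- which(sub == s)
      if (!length(rows)) next
      th_f <- blups_f$theta[k, ]
      th_c <- blups_cf$theta[k, ]
      draws_f <- if (n_mc > 0L) th_f + t(psd_chol(blups_f$vcov[[k]])) %*% Zs[[jj]]
      for (si in seq_len(nrow(scen))) {
        x <- if (scen$temp[si] == "factual") tf$tmean[rows] else tc$tmean[rows]
        Bx <- if (scen$temp[si] == "factual") B_f[rows, , drop = FALSE] else
          B_c[rows, , drop = FALSE]
        th <- if (scen$assoc[si] == "with_le") th_f else th_c
        gridtemps <- if (scen$temp[si] == "factual") tf$tmean else tc$tmean
        mmt <- find_mmt(th, spec, gridtemps)$mmt
        D <- Bx - matrix(ns_basis(mmt, spec), length(rows), 3, byrow = TRUE)
        hot <- x > mmt
        contrib <- (1 - exp(-as.numeric(D %*% th))) * fwd[rows] * hot
        an_point[, si] <- an_point[, si] +
          rowsum_padded(contrib, yr[rows], yrs)
        if (n_mc > 0L) {
          # counterfactual-association draws share the factual residual
          thd <- if (scen$assoc[si] == "with_le") draws_f else
            draws_f + (th_c - th_f)
          E <- 1 - exp(-(D %*% thd))
          an_draws[, , si] <- an_draws[, , si] +
            rowsum_padded_mat(E * (fwd[rows] * hot), yr[rows], yrs)
        }
      }
    }

    af_point <- 100 * an_point / deaths_year
    ann <- do.call(rbind, lapply(seq_len(nrow(scen)), function(si) {
      out <- data.frame(city = ct, year = yrs, scenario = scen$label[si],
                        an = an_point[, si], af = af_point[, si])
      if (n_mc > 0L) {
        qs <- apply(an_draws[, , si, drop = FALSE], 1, stats::quantile,
                    probs = c(0.025, 0.975), type = 7)
        out$an_lo <- qs[1, ]; out$an_hi <- qs[2, ]
        out$af_lo <- 100 * qs[1, ] / deaths_year
        out$af_hi <- 100 * qs[2, ] / deaths_year
      }
      out
    }))
    annual[[ct]] <- ann

    # per-city period climate-change attribution by association variant
    for (av in c("with_le", "wo_le")) {
      f_lab <- paste0("factual_", av); c_lab <- paste0("counterfactual_", av)
      an_cc <- an_point[, f_lab] - an_point[, c_lab]
      pc <- data.frame(
        city = ct, assoc = av,
        an_cc_total = sum(an_cc), an_cc_per_year = mean(an_cc),
        af_cc = 100 * sum(an_cc) / sum(deaths_year),
        p_cc = 100 * sum(an_cc) / sum(an_point[, f_lab]))
      if (n_mc > 0L) {
        dcc <- an_draws[, , f_lab] - an_draws[, , c_lab]
        tot <- colSums(dcc)
        pc$an_cc_lo <- stats::quantile(tot, 0.025, type = 7)
        pc$an_cc_hi <- stats::quantile(tot, 0.975, type = 7)
        pcc <- 100 * tot / colSums(an_draws[, , f_lab])
        pc$p_cc_lo <- stats::quantile(pcc, 0.025, na.rm = TRUE, type = 7)
        pc$p_cc_hi <- stats::quantile(pcc, 0.975, na.rm = TRUE, type = 7)
      }
      percity_climate[[paste(ct, av)]] <- pc
    }

    ac <- data.frame(year = yrs, deaths = deaths_year)
    for (si in seq_len(nrow(scen))) ac[[scen$label[si]]] <- an_point[, si]
    allcity <- if (is.null(allcity)) ac else {
      stopifnot(identical(allcity$year, ac$year))
      allcity[-1] <- allcity[-1] + ac[-1]
      allcity
    }
    if (n_mc > 0L) {
      allcity_draws <- if (is.null(allcity_draws)) an_draws else
        allcity_draws + an_draws
    }
  }

  # all-cities annual AF and climate-change quantities
  allcities <- do.call(rbind, lapply(scen$label, function(lab) {
    out <- data.frame(year = allcity$year, scenario = lab,
                      an = allcity[[lab]],
                      af = 100 * allcity[[lab]] / allcity$deaths)
    if (n_mc > 0L) {
      qs <- apply(allcity_draws[, , lab], 1, stats::quantile,
                  probs = c(0.025, 0.975), type = 7)
      out$an_lo <- qs[1, ]; out$an_hi <- qs[2, ]
      out$af_lo <- 100 * qs[1, ] / allcity$deaths
      out$af_hi <- 100 * qs[2, ] / allcity$deaths
    }
    out
  }))

  climate <- list()
  for (av in c("with_le", "wo_le")) {
    f_lab <- paste0("factual_", av); c_lab <- paste0("counterfactual_", av)
    an_cc <- allcity[[f_lab]] - allcity[[c_lab]]
    af_f <- 100 * allcity[[f_lab]] / allcity$deaths
    af_cc <- 100 * an_cc / allcity$deaths
    p_cc <- ifelse(af_f == 0, NA_real_, 100 * af_cc / af_f)
    annual_cc <- data.frame(year = allcity$year, an_cc = an_cc,
                            af_cc = af_cc, p_cc = p_cc)
    period <- c(an_cc_total = sum(an_cc), an_cc_per_year = mean(an_cc),
                af_cc = 100 * sum(an_cc) / sum(allcity$deaths),
                p_cc = 100 * sum(an_cc) / sum(allcity[[f_lab]]))
    if (n_mc > 0L) {
      dcc <- allcity_draws[, , f_lab] - allcity_draws[, , c_lab]
      annual_cc$an_cc_lo <- apply(dcc, 1, stats::quantile, 0.025, type = 7)
      annual_cc$an_cc_hi <- apply(dcc, 1, stats::quantile, 0.975, type = 7)
      annual_cc$af_cc_lo <- 100 * annual_cc$an_cc_lo / allcity$deaths
      annual_cc$af_cc_hi <- 100 * annual_cc$an_cc_hi / allcity$deaths
      tot <- colSums(dcc)
      totf <- colSums(allcity_draws[, , f_lab])
      period <- c(period,
                  an_cc_total_lo = stats::quantile(tot, 0.025, type = 7, names = FALSE),
                  an_cc_total_hi = stats::quantile(tot, 0.975, type = 7, names = FALSE),
                  af_cc_lo = 100 * stats::quantile(tot, 0.025, type = 7, names = FALSE) /
                    sum(allcity$deaths),
                  af_cc_hi = 100 * stats::quantile(tot, 0.975, type = 7, names = FALSE) /
                    sum(allcity$deaths),
                  p_cc_lo = stats::quantile(100 * tot / totf, 0.025, na.rm = TRUE,
                                            type = 7, names = FALSE),
                  p_cc_hi = stats::quantile(100 * tot / totf, 0.975, na.rm = TRUE,
                                            type = 7, names = FALSE))
    }
    climate[[av]] <- list(annual = annual_cc, period = period)
  }

  list(annual = do.call(rbind, annual),
       allcities = allcities,
       climate = climate,
       percity_climate = do.call(rbind, percity_climate),
       scenarios = scen)
}

rowsum_padded <- function(x, group, levels) {
  r <- rowsum(x, factor(group, levels = levels))
  out <- numeric(length(levels)); names(out) <- levels
  out[rownames(r)] <- r[, 1]
  out
}

rowsum_padded_mat <- function(x, group, levels) {
  r <- rowsum(x, factor(group, levels = levels))
  out <- matrix(0, length(levels), ncol(x), dimnames = list(levels, NULL))
  out[rownames(r), ] <- r
  out
}

#' Run the full attribution pipeline
#'
#' Orchestrates counterfactual temperature construction, first-stage
#' distributed-lag models, the multivariate meta-regression with factual
#' and counterfactual BLUPs, scenario attribution with Monte Carlo
#' empirical CIs, and trend assessment, optionally writing all outputs as
#' CSV/JSON.
#'
#' @param inputs list with `gmst`, `temps`, `deaths`, `metapred` (e.g. a
#'   [simulate_world()] result), or a directory of CSV files.
#' @param config a [pipeline_config()].
#' @return list with elements `scaling`, `delta_t`, `reduced`, `meta`,
#'   `heterogeneity`, `blups`, `attribution`, `trends`, `comparisons`,
#'   `config`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config()) {
  if (is.character(inputs)) inputs <- read_inputs(inputs)
  rep0 <- validate_inputs(inputs[c("gmst", "temps", "deaths", "metapred")],
                          study_years = config$study_years)
  if (nrow(rep0)) {
    stopf("input validation failed:\n%s",
          paste(sprintf("  [%s] %s", rep0$table, rep0$problem), collapse = "\n"))
  }
  scheme <- subperiod_scheme(min(config$study_years), max(config$study_years),
                             config$subperiod_width)
  temps <- inputs$temps; temps$date <- as.Date(temps$date)
  deaths <- inputs$deaths; deaths$date <- as.Date(deaths$date)
  if (config$baseline == "doy_mean") deaths <- doy_baseline(deaths)
  keep_years <- setdiff(config$study_years, config$exclude_years)
  cities <- sort(unique(temps$city))

  # --- counterfactual temperatures -----------------------------------
  sg <- smooth_gmst(inputs$gmst, method = config$gmst_method)
  temps_study <- temps[date_year(temps$date) %in% config$study_years, ]
  scaling <- list(); ensembles <- list(); delta_annual <- list()
  for (ct in cities) {
    tc_all <- temps[temps$city == ct, ]
    ann <- suppressWarnings(warm_season_means(tc_all))
    scaling[[ct]] <- fit_city_scaling(ann, sg, city = ct)
    tc_study <- temps_study[temps_study$city == ct, ]
    ensembles[[ct]] <- build_cf_ensemble(tc_study, scaling[[ct]], sg)
    delta_annual[[ct]] <- attributable_temperature(tc_study, ensembles[[ct]],
                                                   years = keep_years)
  }
  # city-average attributable warming (period mean, ensemble min/max)
  dt_mat <- sapply(delta_annual, function(d) d$annual$delta)
  dt_rng <- sapply(delta_annual, function(d) d$period[c("min", "max")])
  delta_t <- list(
    annual = data.frame(year = delta_annual[[1]]$annual$year,
                        delta = rowMeans(dt_mat)),
    period = c(mean = mean(rowMeans(dt_mat)),
               min = mean(dt_rng["min", ]), max = mean(dt_rng["max", ])))

  # --- first stage ----------------------------------------------------
  fs <- first_stage(temps, deaths, scheme = scheme,
                    lspec = lag_spec(config$max_lag),
                    exclude_years = config$exclude_years)
  red <- fs$reduced
  theta <- t(vapply(red, `[[`, numeric(3), "theta"))
  S <- lapply(red, `[[`, "S")
  units <- data.frame(city = vapply(red, `[[`, character(1), "city"),
                      subperiod = vapply(red, `[[`, character(1), "subperiod"))
  units$mid <- scheme$mid[match(units$subperiod, scheme$label)]
  mp <- inputs$metapred
  units <- cbind(units, mp[match(paste(units$city, units$subperiod),
                                 paste(mp$city, mp$subperiod)),
                           setdiff(names(mp), c("city", "subperiod", "mid")),
                           drop = FALSE])

  # --- meta-regression ------------------------------------------------
  mid_knot <- stats::median(scheme$mid)
  base_f <- stats::as.formula(sprintf(
    "~ splines::ns(mid, knots = %.3f, Boundary.knots = c(%.3f, %.3f))",
    mid_knot, scheme$mid[1], scheme$mid[nrow(scheme)]))
  if (config$select) {
    sel <- select_meta_model(theta, S, units, units$city,
                             base = base_f,
                             candidates = intersect(config$candidates, names(units)),
                             keep = "le")
    meta <- sel$fit; trace <- sel$trace; meta_formula <- sel$formula
  } else {
    meta_formula <- config$meta_formula %||%
      stats::update(base_f, ~ . + le)
    meta <- fit_mvmeta(theta, S, meta_formula, data = units,
                       groups = units$city)
    trace <- NULL
  }
  meta0 <- fit_mvmeta(theta, S, ~1, data = units, groups = units$city)
  het <- list(intercept_only = heterogeneity(meta0), final = heterogeneity(meta))

  blups_f <- compute_blups(meta)
  blups_cf <- counterfactual_blups(meta, blups_f, var = "le",
                                   order_by = units$mid)

  # --- attribution ----------------------------------------------------
  cf_central <- do.call(rbind, lapply(ensembles, `[[`, "cf_central_central"))
  attribution <- attribute_scenarios(
    blups_f, blups_cf, units, temps_study, cf_central, deaths, fs$specs,
    scheme, max_lag = config$max_lag, n_mc = config$n_mc,
    seed = config$seed, years = keep_years)

  # --- trends and rank tests -----------------------------------------
  yrs <- attribution$allcities$year[attribution$allcities$scenario ==
                                      attribution$scenarios$label[1]]
  trends <- list()
  for (lab in attribution$scenarios$label) {
    a <- attribution$allcities[attribution$allcities$scenario == lab, ]
    trends[[paste0("af_", lab)]] <- fit_trend(a$year, a$af)
  }
  for (av in c("with_le", "wo_le")) {
    cl <- attribution$climate[[av]]$annual
    trends[[paste0("af_cc_", av)]] <- fit_trend(cl$year, cl$af_cc)
    trends[[paste0("p_cc_", av)]] <- fit_trend(cl$year, cl$p_cc)
  }
  tf_ann <- lapply(cities, function(ct) {
    warm_season_means(temps_study[temps_study$city == ct &
                                    date_year(temps_study$date) %in% keep_years, ])
  })
  names(tf_ann) <- cities
  trends$temp_factual <- fit_trend(
    tf_ann[[1]]$year, rowMeans(sapply(tf_ann, `[[`, "tmean")))
  cfc_ann <- lapply(cities, function(ct) {
    warm_season_means(ensembles[[ct]]$cf_central_central)
  })
  trends$temp_counterfactual <- fit_trend(
    cfc_ann[[1]]$year[cfc_ann[[1]]$year %in% keep_years],
    rowMeans(sapply(cfc_ann, function(d) d$tmean[d$year %in% keep_years])))

  comparisons <- NULL
  if (config$ensemble_trends) {
    comparisons <- ensemble_comparisons(
      blups_f, blups_cf, units, temps_study, ensembles, deaths, fs$specs,
      scheme, tf_ann, config, keep_years)
  }

  result <- list(scaling = scaling, gmst_smoothed = sg, delta_t = delta_t,
                 reduced = red, meta = meta, meta_formula = meta_formula,
                 selection_trace = trace, heterogeneity = het,
                 blups = list(factual = blups_f, counterfactual = blups_cf),
                 units = units, specs = fs$specs, scheme = scheme,
                 attribution = attribution, trends = trends,
                 comparisons = comparisons, config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  invisible(result)
}

# per-city trend estimates for the factual series and each ensemble member,
# with two-sided Wilcoxon rank tests on the trend samples
ensemble_comparisons <- function(blups_f, blups_cf, units, temps_f, ensembles,
                                 deaths, specs, scheme, tf_ann, config,
                                 keep_years) {
  cities <- names(ensembles)
  variants <- names(ensembles[[1]])
  # temperature trends
  t_fact <- vapply(cities, function(ct) {
    a <- tf_ann[[ct]]; fit_trend(a$year, a$tmean)$slope_decade
  }, numeric(1))
  t_cf <- unlist(lapply(variants, function(v) {
    vapply(cities, function(ct) {
      a <- warm_season_means(ensembles[[ct]][[v]])
      a <- a[a$year %in% keep_years, ]
      fit_trend(a$year, a$tmean)$slope_decade
    }, numeric(1))
  }))
  # AF trends per association variant: factual temps vs ensemble members
  af_trend <- function(temp_df_by_city) {
    att <- attribute_scenarios(
      blups_f, blups_cf, units, temps_f, temp_df_by_city, deaths, specs,
      scheme, max_lag = config$max_lag, n_mc = 0L, seed = config$seed,
      years = keep_years)
    vapply(c("with_le", "wo_le"), function(av) {
      vapply(cities, function(ct) {
        a <- att$annual[att$annual$city == ct &
                          att$annual$scenario == paste0("counterfactual_", av), ]
        fit_trend(a$year, a$af)$slope_decade
      }, numeric(1))
    }, numeric(length(cities)))
  }
  # factual AF trends come from the factual scenarios of the central run
  att_f <- attribute_scenarios(
    blups_f, blups_cf, units, temps_f,
    do.call(rbind, lapply(ensembles, `[[`, "cf_central_central")),
    deaths, specs, scheme, max_lag = config$max_lag, n_mc = 0L,
    seed = config$seed, years = keep_years)
  af_fact <- vapply(c("with_le", "wo_le"), function(av) {
    vapply(cities, function(ct) {
      a <- att_f$annual[att_f$annual$city == ct &
                          att_f$annual$scenario == paste0("factual_", av), ]
      fit_trend(a$year, a$af)$slope_decade
    }, numeric(1))
  }, numeric(length(cities)))
  af_cf <- lapply(variants, function(v) {
    af_trend(do.call(rbind, lapply(ensembles, `[[`, v)))
  })
  af_cf_with <- unlist(lapply(af_cf, function(m) m[, "with_le"]))
  af_cf_wo <- unlist(lapply(af_cf, function(m) m[, "wo_le"]))

  list(
    temperature = c(compare_trends(t_fact, t_cf),
                    list(trends_factual = t_fact, trends_cf = t_cf)),
    af_with_le = c(compare_trends(af_fact[, "with_le"], af_cf_with),
                   list(trends_factual = af_fact[, "with_le"],
                        trends_cf = af_cf_with)),
    af_wo_le = c(compare_trends(af_fact[, "wo_le"], af_cf_wo),
                 list(trends_factual = af_fact[, "wo_le"],
                      trends_cf = af_cf_wo))
  )
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f), row.names = FALSE)

  red_df <- do.call(rbind, lapply(result$reduced, function(r) {
    data.frame(city = r$city, subperiod = r$subperiod,
               t(stats::setNames(r$theta, paste0("theta_", 1:3))),
               t(stats::setNames(vech(r$S), paste0("s_", 1:6))))
  }))
  wr(red_df, "reduced.csv")

  blup_df <- do.call(rbind, lapply(c("factual", "counterfactual"), function(v) {
    b <- result$blups[[v]]
    data.frame(city = result$units$city, subperiod = result$units$subperiod,
               variant = v,
               stats::setNames(as.data.frame(b$theta), paste0("theta_", 1:3)),
               stats::setNames(as.data.frame(t(vapply(b$vcov, vech, numeric(6)))),
                               paste0("s_", 1:6)))
  }))
  wr(blup_df, "blups.csv")
  wr(result$attribution$annual, "attribution.csv")
  wr(result$attribution$allcities, "attribution_allcities.csv")
  clim <- do.call(rbind, lapply(names(result$attribution$climate), function(av) {
    cbind(assoc = av, result$attribution$climate[[av]]$annual)
  }))
  wr(clim, "climate_attrib.csv")
  wr(result$attribution$percity_climate, "climate_attrib_percity.csv")
  tr <- do.call(rbind, lapply(names(result$trends), function(nm) {
    t <- result$trends[[nm]]
    data.frame(quantity = nm, slope_decade = t$slope_decade,
               ci_lo = t$ci[["lower"]], ci_hi = t$ci[["upper"]],
               aic_linear = t$aic_linear)
  }))
  wr(tr, "trends.csv")

  model <- list(
    formula = paste(deparse(result$meta_formula), collapse = " "),
    coefficients = result$meta$coefficients,
    coefficients_original_scale = coef(result$meta, type = "original"),
    psi = result$meta$Psi, loglik = result$meta$loglik,
    aic = result$meta$aic, bic = result$meta$bic,
    heterogeneity = result$heterogeneity,
    selection_trace = result$selection_trace)
  jsonlite::write_json(model, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (!is.null(result$comparisons)) {
    jsonlite::write_json(result$comparisons, file.path(dir, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  manifest <- list(
    package = "heatattr",
    version = as.character(utils::packageVersion("heatattr")),
    seed = result$config$seed,
    config = unclass(result$config)[setdiff(names(result$config), "out_dir")],
    created = "run manifest")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
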