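test_that("fixed-effects pooling equals the inverse-variance-weighted mean", {
  th <- matrix(c(1.2, 0.8), 2, 1)
  S <- list(matrix(0.04), matrix(0.09))
  f <- fit_mvmeta(th, S, ~1, groups = c("a", "b"), method = "fixed")
  ivw <- (1.2 / 0.04 + 0.8 / 0.09) / (1 / 0.04 + 1 / 0.09)
  expect_equal(unname(f$beta), ivw, tolerance = 1e-10)
  expect_equal(unname(diag(f$vcov)), 1 / (1 / 0.04 + 1 / 0.09),
               tolerance = 1e-10)
})

test_that("duplicating every unit leaves fixed effects unchanged", {
  md <- make_meta_data(nc = 6, ns = 3, seed = 21, beta_x = c(0.1, 0, -0.1))
  f1 <- fit_mvmeta(md$theta, md$S, ~x, data = md$data, groups = md$groups)
  f2 <- fit_mvmeta(rbind(md$theta, md$theta), c(md$S, md$S), ~x,
                   data = rbind(md$data, md$data),
                   groups = c(md$groups, md$groups + 100))
  expect_equal(f2$beta, f1$beta, tolerance = 0.02)
  expect_false(isTRUE(all.equal(f2$loglik, f1$loglik)))
})

test_that("ML estimates agree with metafor on the univariate case", {
  skip_if_not_installed("metafor")
  set.seed(9)
  k <- 20
  yi <- rnorm(k, 0.3, 0.25)
  vi <- runif(k, 0.01, 0.05)
  f <- fit_mvmeta(matrix(yi), lapply(vi, function(v) matrix(v)), ~1,
                  groups = seq_len(k))
  r <- metafor::rma(yi, vi, method = "ML")
  expect_equal(unname(f$beta), unname(coef(r)), tolerance = 1e-5)
  expect_equal(f$Psi[1, 1], r$tau2, tolerance = 1e-4)
  expect_equal(f$loglik, as.numeric(stats::logLik(r)), tolerance = 1e-6)
  x <- rnorm(k)
  f2 <- fit_mvmeta(matrix(yi), lapply(vi, function(v) matrix(v)), ~x,
                   data = data.frame(x = x), groups = seq_len(k))
  r2 <- metafor::rma(yi, vi, mods = ~x, method = "ML")
  expect_equal(unname(coef(f2, type = "original")[1, ]), unname(coef(r2)),
               tolerance = 1e-4)
})

test_that("likelihood-ratio tests behave at their degenerate contracts", {
  md <- make_meta_data(nc = 8, ns = 3, seed = 22)
  f0 <- fit_mvmeta(md$theta, md$S, ~1, data = md$data, groups = md$groups)
  lr <- lr_test(f0, f0)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p, 1)
  f1 <- fit_mvmeta(md$theta, md$S, ~x, data = md$data, groups = md$groups)
  lr2 <- lr_test(f0, f1)
  expect_gte(lr2$statistic, 0)
  expect_equal(lr2$df, 3L)
  md2 <- make_meta_data(nc = 8, ns = 3, seed = 23)
  f0b <- fit_mvmeta(md2$theta, md2$S, ~1, data = md2$data, groups = md2$groups)
  expect_error(lr_test(f0b, f1), "same data")
})

test_that("heterogeneity matches the hand-computed univariate Q", {
  th <- matrix(c(0.1, 0.3, 0.25), 3, 1)
  vi <- c(0.01, 0.02, 0.015)
  f <- fit_mvmeta(th, lapply(vi, function(v) matrix(v)), ~1,
                  groups = 1:3, method = "fixed")
  h <- heterogeneity(f)
  wts <- 1 / vi
  mu <- sum(wts * th) / sum(wts)
  expect_equal(h$Q, sum(wts * (th - mu)^2), tolerance = 1e-10)
  expect_equal(h$df, 2L)
  # equal estimates: Q = 0 and I2 floored at 0
  f2 <- fit_mvmeta(matrix(rep(0.2, 3)), lapply(vi, function(v) matrix(v)),
                   ~1, groups = 1:3, method = "fixed")
  h2 <- heterogeneity(f2)
  expect_equal(h2$Q, 0, tolerance = 1e-12)
  expect_equal(h2$I2, 0)
  # I2 invariant to rescaling theta and S jointly
  c2 <- 3.7
  f3 <- fit_mvmeta(th * c2, lapply(vi, function(v) matrix(v * c2^2)), ~1,
                   groups = 1:3, method = "fixed")
  expect_equal(heterogeneity(f3)$I2, h$I2, tolerance = 1e-8)
})

test_that("pooled predictions are linear with delta-method covariance", {
  md <- make_meta_data(nc = 10, ns = 3, seed = 24, beta_x = c(0.2, -0.1, 0.3))
  f0 <- fit_mvmeta(md$theta, md$S, ~1, data = md$data, groups = md$groups)
  p <- predict_pooled(f0, data.frame(x = c(-5, 5)))
  expect_equal(p[[1]]$coef, p[[2]]$coef)
  f1 <- fit_mvmeta(md$theta, md$S, ~x, data = md$data, groups = md$groups)
  p1 <- predict_pooled(f1, data.frame(x = c(1, 2)))
  bO <- coef(f1, type = "original")
  expect_equal(p1[[2]]$coef - p1[[1]]$coef, unname(bO[, "x"]),
               tolerance = 1e-8)
  K <- kronecker(t(heatattr:::meta_design(f1, data.frame(x = 2))[1, ]), diag(3))
  expect_equal(p1[[2]]$vcov, K %*% f1$vcov %*% t(K))
  expect_error(predict_pooled(f1, data.frame(z = 1)), "missing")
})

test_that("BLUPs interpolate between fixed predictions and unit estimates", {
  md <- make_meta_data(nc = 10, ns = 3, seed = 25)
  ffix <- fit_mvmeta(md$theta, md$S, ~1, data = md$data, groups = md$groups,
                     method = "fixed")
  bf <- compute_blups(ffix)
  pred <- matrix(ffix$beta, nrow(md$theta), 3, byrow = TRUE)
  expect_equal(bf$theta, pred, tolerance = 1e-10)
  # unit-level random effects + tiny S: BLUP approaches the unit estimate
  th <- matrix(rnorm(36), 12, 3)
  tiny <- replicate(12, diag(1e-10, 3), simplify = FALSE)
  fs <- fit_mvmeta(th, tiny, ~1, groups = 1:12)
  expect_equal(compute_blups(fs)$theta, th, tolerance = 1e-6)
  # univariate two-study shrinkage weights by hand
  y <- c(1, 2); v <- c(0.5, 0.25); tau2 <- 0.3
  fit2 <- fit_mvmeta(matrix(y), lapply(v, function(x) matrix(x)), ~1,
                     groups = 1:2)
  # recompute with the model's own estimates to check the formula
  psi <- fit2$Psi[1, 1]
  mu <- fit2$beta
  shrink <- psi / (psi + v)
  expect_equal(as.numeric(compute_blups(fit2)$theta),
               mu + shrink * (y - mu), tolerance = 1e-6)
})

test_that("counterfactual BLUPs differ by the frozen-predictor fixed effect", {
  set.seed(26)
  nc <- 12; ns <- 5; n <- nc * ns
  g <- rep(1:nc, each = ns); sp <- rep(1:ns, nc)
  le <- 76 + 0.3 * (sp - 1) + 0.04 * (sp - 1) * g / nc + rnorm(n, 0, 0.1)
  x <- rnorm(n)
  B <- matrix(c(0.1, 0.2, 0.3, 0.05, -0.05, 0.02, -0.03, 0.01, 0.02), 3, 3)
  th <- matrix(NA_real_, n, 3)
  S <- vector("list", n)
  for (i in seq_len(n)) {
    S[[i]] <- diag(runif(3, 0.005, 0.02))
    th[i, ] <- B %*% c(1, x[i], (le[i] - mean(le)) / sd(le)) + rnorm(3, 0, 0.05)
  }
  dat <- data.frame(x = x, le = le)
  fit <- fit_mvmeta(th, S, ~ x + le, data = dat, groups = g)
  bl <- compute_blups(fit)
  cfb <- counterfactual_blups(fit, bl, var = "le", order_by = sp)
  bO <- coef(fit, type = "original")
  ref <- stats::ave(le, g, FUN = function(v) v[1])
  expect_equal(cfb$theta - bl$theta, outer(ref - le, unname(bO[, "le"])),
               tolerance = 1e-10)
  expect_equal(cfb$theta[sp == 1, ], bl$theta[sp == 1, ], tolerance = 1e-12)
  # zero LE coefficient: counterfactual equals factual
  fit0 <- fit
  fit0$coefficients[, "le"] <- 0
  fit0$beta <- as.numeric(fit0$coefficients)
  cfb0 <- counterfactual_blups(fit0, bl, var = "le", order_by = sp)
  expect_equal(cfb0$theta, bl$theta, tolerance = 1e-12)
  f_noLE <- fit_mvmeta(th, S, ~x, data = dat, groups = g)
  expect_error(counterfactual_blups(f_noLE, compute_blups(f_noLE),
                                    var = "le", order_by = sp), "not a main-effect")
})

test_that("stepwise selection keeps useful predictors and respects the base", {
  set.seed(27)
  nc <- 12; ns <- 5; n <- nc * ns
  g <- rep(1:nc, each = ns)
  le <- rnorm(n); junk <- rnorm(n)
  th <- matrix(NA_real_, n, 3)
  S <- vector("list", n)
  for (i in seq_len(n)) {
    S[[i]] <- diag(0.01, 3)
    th[i, ] <- c(0.1, 0.2, 0.3) + c(0.15, 0.1, -0.1) * le[i] +
      rnorm(3, 0, 0.05)
  }
  dat <- data.frame(le = le, junk = junk)
  sel <- select_meta_model(th, S, dat, g, base = ~1,
                           candidates = c("le", "junk"))
  expect_true("le" %in% colnames(sel$fit$X))
  expect_true(all(c("aic", "bic", "lr_p") %in% names(sel$trace)))
  # no useful candidate: base model returned
  sel0 <- select_meta_model(th[, , drop = FALSE] * 0 +
                              matrix(rnorm(n * 3, 0, 0.01), n, 3),
                            S, dat["junk"], g, base = ~1,
                            candidates = "junk")
  expect_false("junk" %in% colnames(sel0$fit$X))
  # keep forces a predictor in even when useless
  selk <- select_meta_model(matrix(rnorm(n * 3, 0, 0.01), n, 3), S,
                            dat, g, base = ~1, candidates = c("le", "junk"),
                            keep = "le")
  expect_true("le" %in% colnames(selk$fit$X))
})

test_that("between-city covariance is recovered across replicates", {
  set.seed(28)
  tr_hat <- replicate(100, {
    md <- make_meta_data(nc = 15, ns = 6, psi_sd = 0.1,
                         seed = sample.int(1e6, 1))
    f <- fit_mvmeta(md$theta, md$S, ~1, data = md$data, groups = md$groups)
    sum(diag(f$Psi))
  })
  expect_lt(abs(stats::median(tr_hat) - 0.03) / 0.03, 0.25)
})

test_that("alternative random-effect structures fit and report more parameters", {
  md <- make_meta_data(nc = 8, ns = 4, seed = 29)
  md$data$time <- rep(1:4, 8)
  f1 <- fit_mvmeta(md$theta, md$S, ~1, data = md$data, groups = md$groups)
  f2 <- fit_mvmeta(md$theta, md$S, ~1, data = md$data, groups = md$groups,
                   random = "city_slope", slope_var = "time")
  expect_gt(f2$df, f1$df)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  outer_g <- rep(rep(1:2, each = 4), each = 4)[seq_len(32)]
  f3 <- fit_mvmeta(md$theta, md$S, ~1, data = md$data, groups = md$groups,
                   random = "nested", outer_groups = outer_g)
  expect_equal(f3$df, f1$df + 6L)
  expect_true(heatattr:::is_psd(f3$Psi))
})
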