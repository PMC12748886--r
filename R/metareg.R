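#' Multivariate mixed-effects meta-regression (maximum likelihood)
#'
#' Pools vector-valued city-by-subperiod estimates `theta_ik` with known
#' within-unit covariances `S_ik` under the longitudinal model
#' `theta_ik = X_ik beta + Z u_i + e_ik`, where `u_i` is a random effect
#' shared by all subperiods of city `i` with unstructured between-city
#' covariance `Psi`, and `e_ik ~ N(0, S_ik)`. Estimation is maximum
#' likelihood: `beta` is profiled out by generalized least squares and
#' `Psi`, parameterised by its Cholesky factor to keep it positive
#' semi-definite, is maximised numerically (BFGS). ML (rather than REML) is
#' used throughout so that likelihood-ratio tests of fixed effects are valid
#' and AIC/BIC are comparable across meta-predictor sets.
#'
#' Alternative random-effect structures: `"city_slope"` adds a random slope
#' in `slope_var` (joint unstructured covariance), and `"nested"` adds a
#' random effect for an outer grouping (e.g. federal state) above the city
#' level.
#'
#' @param theta n x d matrix of unit estimates (d = 3 cumulative
#'   exposure-response coefficients).
#' @param S list of n positive semi-definite d x d within-unit covariances.
#' @param formula fixed-effects (meta-predictor) formula, evaluated in
#'   `data`; each meta-predictor multiplies all d outcome dimensions.
#' @param data data frame of meta-predictors, one row per unit.
#' @param groups city identifier of each unit.
#' @param method `"ml"` (default) or `"fixed"` (`Psi` fixed at zero:
#'   inverse-variance-weighted GLS).
#' @param random `"city"`, `"city_slope"` or `"nested"`.
#' @param slope_var column of `data` giving the (numeric) time variable for
#'   random slopes.
#' @param outer_groups outer grouping factor for `random = "nested"`.
#' @param scale centre and scale non-intercept design columns before
#'   fitting (improves optimizer conditioning; predictions and original
#'   scale coefficients back-transform).
#' @param control passed to [stats::optim()].
#' @return object of class `mvmeta_fit`.
#' @export
fit_mvmeta <- function(theta, S, formula = ~1, data = NULL, groups,
                       method = c("ml", "fixed"),
                       random = c("city", "city_slope", "nested"),
                       slope_var = NULL, outer_groups = NULL,
                       scale = TRUE, control = list()) {
  method <- match.arg(method)
  random <- match.arg(random)
  theta <- as.matrix(theta)
  n <- nrow(theta); d <- ncol(theta)
  if (n < 2L) stopf("need at least two units")
  if (length(S) != n) stopf("`S` must have one covariance per unit")
  S <- lapply(S, function(s) (as.matrix(s) + t(as.matrix(s))) / 2)
  bad <- which(!vapply(S, is_psd, logical(1)))
  if (length(bad)) stopf("within-unit covariance %d is not PSD", bad[1])
  groups <- factor(groups)
  if (is.null(data)) data <- data.frame(row.names = seq_len(n))

  mf <- stats::model.frame(formula, data)
  tr <- attr(mf, "terms")
  X <- stats::model.matrix(tr, mf)
  if (qr(X)$rank < ncol(X)) stopf("fixed-effects design is rank deficient")
  centers <- rep(0, ncol(X)); scales <- rep(1, ncol(X))
  names(centers) <- names(scales) <- colnames(X)
  if (scale) {
    for (j in seq_len(ncol(X))) {
      if (colnames(X)[j] == "(Intercept)") next
      centers[j] <- mean(X[, j]); scales[j] <- stats::sd(X[, j])
      if (scales[j] < 1e-12) scales[j] <- 1
      X[, j] <- (X[, j] - centers[j]) / scales[j]
    }
  }
  p <- ncol(X)

  # random-effect design: rows of W give each unit's loadings on its
  # block's random-effect columns
  if (random == "nested" && is.null(outer_groups)) {
    stopf("`outer_groups` required for nested random effects")
  }
  block <- if (random == "nested") factor(outer_groups) else groups
  slope <- NULL
  if (random == "city_slope") {
    if (is.null(slope_var) || !slope_var %in% names(data)) {
      stopf("`slope_var` must name a column of `data`")
    }
    slope <- as.numeric(scale(data[[slope_var]]))
  }

  blocks <- lapply(levels(block), function(bl) {
    idx <- which(block == bl)
    W <- switch(random,
      city = matrix(1, length(idx), 1),
      city_slope = cbind(1, slope[idx]),
      nested = {
        cl <- factor(groups[idx])
        cbind(1, stats::model.matrix(~ cl - 1))
      })
    list(idx = idx, W = W)
  })
  names(blocks) <- levels(block)

  # per-unit precomputations (constant during Psi optimisation)
  Sinv <- lapply(S, function(s) chol2inv(psd_chol(s + diag(1e-12, d))))
  logdetS <- vapply(S, function(s) 2 * sum(log(diag(psd_chol(s + diag(1e-12, d))))),
                    numeric(1))
  XtSiX <- matrix(0, d * p, d * p); XtSiy <- numeric(d * p); ytSiy <- 0
  for (k in seq_len(n)) {
    xk <- X[k, ]
    XtSiX <- XtSiX + kronecker(tcrossprod(xk), Sinv[[k]])
    XtSiy <- XtSiy + as.numeric(kronecker(xk, Sinv[[k]] %*% theta[k, ]))
    ytSiy <- ytSiy + drop(theta[k, ] %*% Sinv[[k]] %*% theta[k, ])
  }
  # per-block aggregates
  bpre <- lapply(blocks, function(b) {
    q <- ncol(b$W); dq <- d * q
    A <- matrix(0, dq, dq); ZtSiy <- numeric(dq); ZtSiX <- matrix(0, dq, d * p)
    for (j in seq_along(b$idx)) {
      k <- b$idx[j]; wk <- b$W[j, ]
      A <- A + kronecker(tcrossprod(wk), Sinv[[k]])
      ZtSiy <- ZtSiy + as.numeric(kronecker(wk, Sinv[[k]] %*% theta[k, ]))
      ZtSiX <- ZtSiX + kronecker(wk, kronecker(t(X[k, ]), Sinv[[k]]))
    }
    list(A = A, ZtSiy = ZtSiy, ZtSiX = ZtSiX, q = q)
  })

  # Psi builders -------------------------------------------------------
  nL <- d * (d + 1) / 2
  npar <- switch(random, city = nL, city_slope = (2 * d) * (2 * d + 1) / 2,
                 nested = 2 * nL)
  chol_from_par <- function(par, dim) {
    L <- matrix(0, dim, dim)
    L[lower.tri(L, diag = TRUE)] <- par
    L
  }
  psi_from_par <- function(par) {
    switch(random,
      city = {
        L <- chol_from_par(par, d); list(city = tcrossprod(L))
      },
      city_slope = {
        L <- chol_from_par(par, 2 * d); list(city = tcrossprod(L))
      },
      nested = {
        Lo <- chol_from_par(par[seq_len(nL)], d)
        Lc <- chol_from_par(par[nL + seq_len(nL)], d)
        list(outer = tcrossprod(Lo), city = tcrossprod(Lc))
      })
  }
  psi_block <- function(psi, q) {
    if (random == "nested") {
      m <- matrix(0, d * q, d * q)
      m[seq_len(d), seq_len(d)] <- psi$outer
      for (j in seq_len(q - 1L)) {
        ix <- d * j + seq_len(d)
        m[ix, ix] <- psi$city
      }
      m
    } else psi$city
  }

  profile_ll <- function(psi, want = "ll") {
    U <- XtSiX; v <- XtSiy; w <- ytSiy; ld <- sum(logdetS)
    Es <- vector("list", length(bpre))
    for (bi in seq_along(bpre)) {
      b <- bpre[[bi]]
      P <- psi_block(psi, b$q)
      G <- diag(d * b$q) + b$A %*% P
      E <- P %*% solve(G)
      E <- (E + t(E)) / 2
      U <- U - crossprod(b$ZtSiX, E %*% b$ZtSiX)
      v <- v - crossprod(b$ZtSiX, E %*% b$ZtSiy)
      w <- w - drop(b$ZtSiy %*% E %*% b$ZtSiy)
      ld <- ld + determinant(G, logarithm = TRUE)$modulus
      if (want == "full") Es[[bi]] <- list(G = G, P = P)
    }
    beta <- as.numeric(solve(U, v))
    ll <- -0.5 * (n * d * log(2 * pi) + ld + w - sum(v * beta))
    if (want == "ll") return(as.numeric(ll))
    list(ll = as.numeric(ll), beta = beta, U = U, blockaux = Es)
  }

  if (method == "fixed") {
    psi0 <- psi_from_par(rep(0, npar))
    aux <- profile_ll(psi0, want = "full")
    par <- rep(0, npar); conv <- TRUE
    psi <- psi0
  } else {
    # moment-style start: variance of city-mean crude residuals minus the
    # average within-unit variance, floored
    beta0 <- solve(XtSiX, XtSiy)
    res <- theta - X %*% t(matrix(beta0, nrow = d))
    cm <- apply(res, 2, function(col) tapply(col, groups, mean))
    v_emp <- diag(stats::cov(as.matrix(cm)))
    v_within <- Reduce(`+`, S) / n
    start_diag <- sqrt(pmax(v_emp - diag(v_within) / mean(table(groups)),
                            0.1 * v_emp, 1e-4))
    par0 <- rep(0, npar)
    diag_idx <- integer(d)
    pos <- 1L
    for (j in seq_len(d)) { diag_idx[j] <- pos; pos <- pos + (d - j + 1L) }
    par0[diag_idx] <- start_diag
    if (random == "city_slope") {
      par0 <- rep(0, npar)
      dd2 <- 2 * d; pos <- 1L
      for (j in seq_len(dd2)) {
        par0[pos] <- if (j <= d) start_diag[j] else 0.1 * start_diag[j - d]
        pos <- pos + (dd2 - j + 1L)
      }
    }
    if (random == "nested") par0 <- c(par0[seq_len(nL)] * 0.5, par0[seq_len(nL)])

    negll <- function(par) -profile_ll(psi_from_par(par))
    ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-12), control)
    opt <- stats::optim(par0, negll, method = "BFGS",
                        control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
    if (opt$convergence != 0) {
      opt2 <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                           control = list(maxit = 2000))
      if (opt2$value < opt$value) opt <- opt2
    }
    conv <- TRUE
    par <- opt$par
    psi <- psi_from_par(par)
    aux <- profile_ll(psi, want = "full")
  }

  beta <- aux$beta
  vcov_beta <- solve(aux$U)
  n_vpar <- if (method == "fixed") 0L else npar
  ll <- aux$ll
  k_par <- d * p + n_vpar
  fit <- structure(list(
    coefficients = matrix(beta, nrow = d,
                          dimnames = list(paste0("dim", seq_len(d)), colnames(X))),
    beta = as.numeric(beta), vcov = vcov_beta,
    Psi = psi$city, Psi_outer = psi$outer %||% NULL,
    loglik = ll, df = k_par, aic = -2 * ll + 2 * k_par,
    bic = -2 * ll + log(n * d) * k_par,
    converged = conv, method = method, random = random,
    formula = formula, terms = tr, data = data, groups = groups,
    X = X, centers = centers, scales = scales,
    theta = theta, S = S, Sinv = Sinv,
    blocks = blocks, bpre = bpre, blockaux = aux$blockaux,
    d = d, p = p, n = n
  ), class = "mvmeta_fit")
  fit
}

#' @export
logLik.mvmeta_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n * object$d,
            class = "logLik")
}

#' @export
coef.mvmeta_fit <- function(object, type = c("scaled", "original"), ...) {
  type <- match.arg(type)
  B <- object$coefficients
  if (type == "scaled") return(B)
  Bo <- B
  icpt <- which(colnames(B) == "(Intercept)")
  for (j in seq_len(ncol(B))) {
    if (length(icpt) && j == icpt) next
    Bo[, j] <- B[, j] / object$scales[j]
    if (length(icpt)) Bo[, icpt] <- Bo[, icpt] - Bo[, j] * object$centers[j]
  }
  Bo
}

#' @export
vcov.mvmeta_fit <- function(object, ...) object$vcov

#' @export
print.mvmeta_fit <- function(x, ...) {
  cat(sprintf("Multivariate mixed-effects meta-regression (%s, random = %s)\n",
              toupper(x$method), x$random))
  cat(sprintf("  %d units, %d cities, %d outcome dims, %d fixed terms\n",
              x$n, nlevels(x$groups), x$d, x$p))
  cat(sprintf("  logLik %.2f, AIC %.2f, BIC %.2f\n", x$loglik, x$aic, x$bic))
  cat("  Psi (between-city):\n")
  print(signif(x$Psi, 3))
  invisible(x)
}

#' Likelihood-ratio test of nested meta-regression models
#'
#' @param nested,full two [fit_mvmeta()] results on the same data, fitted by
#'   ML, with nested fixed-effects designs.
#' @return list `statistic`, `df`, `p`.
#' @export
lr_test <- function(nested, full) {
  if (nested$n != full$n || nested$d != full$d ||
      !isTRUE(all.equal(nested$theta, full$theta))) {
    stopf("models were not fitted to the same data")
  }
  lab_n <- colnames(nested$X); lab_f <- colnames(full$X)
  if (!all(lab_n %in% lab_f) || full$p <= nested$p) {
    if (!setequal(lab_n, lab_f)) stopf("models are not nested")
  }
  stat <- 2 * (full$loglik - nested$loglik)
  if (stat < -1e-6) stopf("nested log-likelihood exceeds the full model's: optimizer failure")
  stat <- max(stat, 0)
  df <- full$df - nested$df
  if (df <= 0) return(list(statistic = stat, df = 0L, p = 1))
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Residual heterogeneity statistics
#'
#' Cochran's Q from the fixed-effects (`Psi = 0`) GLS residuals of the
#' model's design, weighted by the within-unit covariances alone, with
#' `I^2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param fit a [fit_mvmeta()] result.
#' @return list `Q`, `df`, `p`, `I2`.
#' @export
heterogeneity <- function(fit) {
  d <- fit$d; n <- fit$n; p <- fit$p
  df <- d * n - d * p
  if (df <= 0) stopf("no residual degrees of freedom")
  U <- matrix(0, d * p, d * p); v <- numeric(d * p)
  for (k in seq_len(n)) {
    U <- U + kronecker(tcrossprod(fit$X[k, ]), fit$Sinv[[k]])
    v <- v + as.numeric(kronecker(fit$X[k, ], fit$Sinv[[k]] %*% fit$theta[k, ]))
  }
  beta0 <- solve(U, v)
  Q <- 0
  for (k in seq_len(n)) {
    r <- fit$theta[k, ] - drop(kronecker(t(fit$X[k, ]), diag(d)) %*% beta0)
    Q <- Q + drop(r %*% fit$Sinv[[k]] %*% r)
  }
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       I2 = max(0, (Q - df) / Q) * 100)
}

# model matrix for new data on the fit's (scaled) design scale
meta_design <- function(fit, newdata) {
  tr <- stats::delete.response(fit$terms)
  mf <- stats::model.frame(tr, newdata, xlev = NULL)
  X <- stats::model.matrix(tr, mf)
  for (j in colnames(X)) {
    X[, j] <- (X[, j] - fit$centers[j]) / fit$scales[j]
  }
  X
}

#' Pooled fixed-effects prediction
#'
#' Coefficient vector and delta-method covariance for given meta-predictor
#' values (e.g. the city-average of selected meta-predictors by subperiod).
#'
#' @param fit a [fit_mvmeta()] result.
#' @param newdata data frame of meta-predictor values.
#' @return list of per-row lists with `coef` (length d) and `vcov` (d x d).
#' @export
predict_pooled <- function(fit, newdata) {
  need <- all.vars(fit$terms)
  miss <- setdiff(need, names(newdata))
  if (length(miss)) stopf("missing meta-predictor values: %s", paste(miss, collapse = ", "))
  X <- meta_design(fit, newdata)
  d <- fit$d
  lapply(seq_len(nrow(X)), function(i) {
    K <- kronecker(t(X[i, ]), diag(d))
    list(coef = drop(K %*% fit$beta), vcov = K %*% fit$vcov %*% t(K))
  })
}

#' Factual best linear unbiased predictions
#'
#' City-specific coefficient predictions shrinking each observed unit
#' estimate toward the fixed-effects prediction:
#' `u_i = Psi Z' Sigma_i^{-1} (theta_i - X_i beta)` and
#' `BLUP_ik = X_ik beta + Z_ik u_i`. The covariance attached to each BLUP is
#' the conditional-variance form
#' `X_ik V_beta X_ik' + Z_ik (Psi - Psi Z' Sigma_i^{-1} Z Psi) Z_ik'`.
#'
#' @param fit a [fit_mvmeta()] result.
#' @return object of class `blup_set`: list with `theta` (n x d matrix),
#'   `vcov` (list of d x d), `groups`, `variant = "factual"`.
#' @export
compute_blups <- function(fit) {
  d <- fit$d
  theta_b <- matrix(NA_real_, fit$n, d)
  vcov_b <- vector("list", fit$n)
  for (bi in seq_along(fit$blocks)) {
    b <- fit$blocks[[bi]]; pre <- fit$bpre[[bi]]; aux <- fit$blockaux[[bi]]
    P <- aux$P; G <- aux$G
    # residual projections: Z' D^{-1} r = ZtSiy - ZtSiX beta
    br <- pre$ZtSiy - pre$ZtSiX %*% fit$beta
    u <- P %*% solve(G, br)
    postvar <- P - P %*% solve(G, pre$A %*% P)
    postvar <- (postvar + t(postvar)) / 2
    for (j in seq_along(b$idx)) {
      k <- b$idx[j]
      Zk <- kronecker(t(b$W[j, ]), diag(d))
      Kk <- kronecker(t(fit$X[k, ]), diag(d))
      theta_b[k, ] <- drop(Kk %*% fit$beta + Zk %*% u)
      vcov_b[[k]] <- Kk %*% fit$vcov %*% t(Kk) + Zk %*% postvar %*% t(Zk)
    }
  }
  structure(list(theta = theta_b, vcov = vcov_b, groups = fit$groups,
                 data = fit$data, variant = "factual"),
            class = "blup_set")
}

#' Counterfactual BLUPs with a meta-predictor held at its first-subperiod value
#'
#' Sum of the fixed-effect predictions, in which the chosen meta-predictor
#' (life expectancy by default) is held constant at each city's
#' first-subperiod value, and the residuals of the factual BLUP
#' computation: `cfBLUP_ik = BLUP_ik + B (xtilde_ik - x_ik)`. Covariances
#' are carried over unchanged from the factual BLUPs.
#'
#' @param fit a [fit_mvmeta()] result whose design includes `var`.
#' @param blups factual BLUPs from [compute_blups()].
#' @param var meta-predictor to freeze (default `"le"`).
#' @param ref named vector of reference values per city; if `NULL`, the
#'   value at each city's first unit in `order_by` order is used.
#' @param order_by numeric vector (e.g. subperiod midpoint year) defining
#'   "first" within each city.
#' @return a `blup_set` with `variant = "counterfactual"`.
#' @export
counterfactual_blups <- function(fit, blups, var = "le", ref = NULL,
                                 order_by = NULL) {
  if (!(var %in% colnames(fit$X))) {
    stopf("'%s' is not a main-effect column of the selected meta-regression", var)
  }
  g <- as.character(fit$groups)
  if (is.null(ref)) {
    if (is.null(order_by)) stopf("provide `ref` or `order_by`")
    ref <- vapply(split(seq_along(g), g), function(ix) {
      fit$data[[var]][ix[which.min(order_by[ix])]]
    }, numeric(1))
  }
  newdata <- fit$data
  newdata[[var]] <- as.numeric(ref[g])
  Xt <- meta_design(fit, newdata)
  B <- fit$coefficients  # d x p, scaled design
  delta <- (Xt - fit$X) %*% t(B)  # n x d
  out <- blups
  out$theta <- unname(blups$theta + delta)
  out$variant <- "counterfactual"
  out
}

#' Stepwise meta-predictor selection by AIC
#'
#' Forward then backward passes over candidate meta-predictors starting
#' from a base model (typically intercept plus a natural spline of the
#' subperiod midpoint), until no single addition or removal lowers the AIC.
#' Likelihood-ratio p-values are recorded in the trace but selection is by
#' AIC.
#'
#' @param theta,S,data,groups,method as in [fit_mvmeta()].
#' @param base base formula always kept (default `~1`).
#' @param candidates character vector of candidate meta-predictor columns.
#' @param keep candidates never removed once the base model is extended
#'   (and force-added at the end if absent), e.g. `"le"` when
#'   counterfactual BLUPs are required.
#' @param ... further arguments to [fit_mvmeta()].
#' @return list `fit` (final model), `formula`, `trace` (data frame of every
#'   tested model).
#' @export
select_meta_model <- function(theta, S, data, groups, base = ~1,
                              candidates, keep = character(0),
                              method = "ml", ...) {
  base_terms <- attr(stats::terms(base), "term.labels")
  has_icpt <- attr(stats::terms(base), "intercept") == 1
  make_formula <- function(terms) {
    if (length(terms) == 0L) {
      if (has_icpt) ~1 else stopf("empty model")
    } else stats::reformulate(terms, intercept = has_icpt)
  }
  fit_terms <- function(terms) {
    fit_mvmeta(theta, S, make_formula(terms), data = data, groups = groups,
               method = method, ...)
  }
  current_terms <- base_terms
  current <- fit_terms(current_terms)
  trace <- data.frame(step = "base", term = "",
                      formula = paste(deparse(make_formula(current_terms)), collapse = " "),
                      aic = current$aic, bic = current$bic, lr_p = NA_real_,
                      stringsAsFactors = FALSE)
  record <- function(step, term, terms, f, p) {
    trace <<- rbind(trace, data.frame(
      step = step, term = term, formula = paste(deparse(make_formula(terms)), collapse = " "),
      aic = f$aic, bic = f$bic, lr_p = p, stringsAsFactors = FALSE))
  }
  repeat {
    improved <- FALSE
    # forward pass: add the single best AIC-lowering candidate
    best_add <- NULL; best_term <- NULL
    for (cand in setdiff(candidates, current_terms)) {
      f <- fit_terms(c(current_terms, cand))
      record("add", cand, c(current_terms, cand), f, lr_test(current, f)$p)
      if (f$aic < current$aic - 1e-8 && (is.null(best_add) || f$aic < best_add$aic)) {
        best_add <- f; best_term <- cand
      }
    }
    if (!is.null(best_add)) {
      current <- best_add; current_terms <- c(current_terms, best_term)
      improved <- TRUE
    }
    # backward pass over removable candidate terms
    for (term in setdiff(intersect(current_terms, candidates), keep)) {
      f <- fit_terms(setdiff(current_terms, term))
      record("drop", term, setdiff(current_terms, term), f, lr_test(f, current)$p)
      if (f$aic < current$aic - 1e-8) {
        current <- f; current_terms <- setdiff(current_terms, term)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  if (length(keep) && !all(keep %in% current_terms)) {
    add <- setdiff(keep, current_terms)
    current_terms <- c(current_terms, add)
    current <- fit_terms(current_terms)
    record("force", paste(add, collapse = "+"), current_terms, current, NA_real_)
  }
  list(fit = current, formula = make_formula(current_terms), trace = trace)
}
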