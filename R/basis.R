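#' Exposure basis specification
#'
#' Defines the natural-cubic-spline exposure basis used throughout the first
#' stage and the attribution: two inner knots at the 50th and 90th
#' percentiles of the pooled 1993-2022 daily-mean temperature distribution
#' (per city) and boundary knots at the pooled minimum and maximum. The
#' basis has no intercept, so with two inner knots it spans 3 columns and
#' risk is always expressed relative to a centering temperature.
#'
#' @param temps numeric vector of daily mean temperatures pooling all study
#'   years for one city.
#' @param probs percentile positions of the inner knots (fractions).
#' @return object of class `exposure_spec`: list with `knots`,
#'   `boundary`, `probs`.
#' @export
exposure_spec <- function(temps, probs = c(0.5, 0.9)) {
  temps <- temps[!is.na(temps)]
  knots <- unname(stats::quantile(temps, probs, type = 7))
  boundary <- range(temps)
  if (any(diff(c(boundary[1], knots, boundary[2])) <= 0)) {
    stopf("exposure knots are not strictly increasing")
  }
  structure(list(knots = knots, boundary = boundary, probs = probs),
            class = "exposure_spec")
}

#' Evaluate the natural cubic exposure basis
#'
#' @param x temperatures at which to evaluate.
#' @param spec an [exposure_spec()].
#' @return n x k basis matrix (k = number of inner knots + 1), linear beyond
#'   the boundary knots, no intercept column.
#' @export
ns_basis <- function(x, spec) {
  b <- splines::ns(x, knots = spec$knots, Boundary.knots = spec$boundary)
  unname(b[, , drop = FALSE])
}

#' Lag basis specification
#'
#' Natural cubic spline over lags `0..max_lag` with an intercept and inner
#' knots equally spaced on the log(lag + 1) scale — the standard choice for
#' distributed-lag models with lags of about ten days.
#'
#' @param max_lag maximum lag in days (default 10).
#' @param n_knots number of inner knots (default 2).
#' @param intercept_only use a constant lag basis (equal weight at every
#'   lag), mainly for algebraic checks.
#' @return object of class `lag_spec`: list with `max_lag`, `knots`, and the
#'   evaluated `(max_lag + 1) x (n_knots + 2)` lag basis matrix `C`
#'   (intercept column first).
#' @export
lag_spec <- function(max_lag = 10L, n_knots = 2L, intercept_only = FALSE) {
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L) stopf("`max_lag` must be non-negative")
  lags <- 0:max_lag
  if (intercept_only) {
    return(structure(list(max_lag = max_lag, knots = numeric(0),
                          C = matrix(1, max_lag + 1L, 1L)),
                     class = "lag_spec"))
  }
  if (max_lag == 0L || n_knots == 0L) {
    C <- if (max_lag == 0L) matrix(1, 1, 1) else {
      cbind(1, splines::ns(lags, df = 1, Boundary.knots = c(0, max_lag)))
    }
    knots <- numeric(0)
  } else {
    u <- log(max_lag + 1) * seq_len(n_knots) / (n_knots + 1)
    knots <- exp(u) - 1
    C <- cbind(1, unname(splines::ns(lags, knots = knots,
                                     Boundary.knots = c(0, max_lag))))
  }
  structure(list(max_lag = max_lag, knots = knots, C = unname(C)),
            class = "lag_spec")
}

#' Distributed-lag cross-basis
#'
#' Tensor combination of the exposure basis and the lag basis:
#' `A[t, (j-1)*nk + k] = sum_l B_j(x[t-l]) C_k(l)` for every modelled
#' (warm-season) day `t`. The input series must include the 10-day
#' pre-season buffer so every output day has a complete lag history; a day
#' whose history crosses a date gap is an error naming the first offending
#' date.
#'
#' @param dates Date vector, strictly increasing (gaps allowed between
#'   seasons, not inside a season/buffer block).
#' @param tmean daily mean temperatures aligned with `dates`.
#' @param espec an [exposure_spec()].
#' @param lspec a [lag_spec()].
#' @param out_dates dates of the rows to return; defaults to the
#'   June-September days among `dates`.
#' @return matrix of class `cross_basis` with `ncol(B) * ncol(C)` columns
#'   and attributes `dates`, `exposure_spec`, `lag_spec`.
#' @export
cross_basis <- function(dates, tmean, espec, lspec,
                        out_dates = dates[is_warm_season(dates)]) {
  if (!inherits(dates, "Date")) dates <- as.Date(dates)
  if (is.unsorted(dates, strictly = TRUE)) stopf("`dates` must be strictly increasing")
  L <- lspec$max_lag
  pos <- match(out_dates, dates)
  if (anyNA(pos)) stopf("output dates missing from the input series")
  # lag history must be contiguous: date at pos - l equals out_date - l
  first_bad <- NULL
  for (l in 0:L) {
    p <- pos - l
    bad <- p < 1L | dates[pmax(p, 1L)] != (out_dates - l)
    if (any(bad)) { first_bad <- min(out_dates[bad]); break }
  }
  if (!is.null(first_bad)) {
    stopf("incomplete %d-day lag history before %s", L, format(first_bad))
  }
  B <- ns_basis(tmean, espec)
  C <- lspec$C
  nb <- ncol(B); nk <- ncol(C)
  A <- matrix(0, length(pos), nb * nk)
  jrep <- rep(seq_len(nb), each = nk)
  for (l in 0:L) {
    Bl <- B[pos - l, jrep, drop = FALSE]
    A <- A + Bl * rep(C[l + 1L, ], times = nb)[col(A)]
  }
  colnames(A) <- paste0("b", jrep, "l", rep(seq_len(nk), nb))
  structure(A, dates = out_dates, exposure_spec = espec, lag_spec = lspec,
            class = c("cross_basis", "matrix"))
}

# Contrast matrix summing a cross-basis coefficient vector over all lags:
# theta = M eta reduces to the cumulative exposure-response coefficients.
lag_sum_matrix <- function(lspec, n_exposure = 3L) {
  cs <- colSums(lspec$C)
  nk <- length(cs)
  M <- matrix(0, n_exposure, n_exposure * nk)
  for (j in seq_len(n_exposure)) M[j, (j - 1L) * nk + seq_len(nk)] <- cs
  M
}
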