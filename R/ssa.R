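#' Singular spectrum analysis trend smoothing
#'
#' Extracts the low-frequency (trend) component of a univariate series by
#' singular spectrum analysis: the series is embedded into a Hankel
#' trajectory matrix with window length `window`, decomposed by SVD, a group
#' of leading low-frequency components is selected, and the trend is
#' reconstructed by diagonal (anti-diagonal) averaging.
#'
#' Component grouping: by default the leading components `1..k` are kept,
#' where `k` is the largest index such that every left singular vector up to
#' `k` is quasi-monotone — its mean periodicity, estimated from the number
#' of mean-crossings, exceeds `window` time steps (at most 2 sign changes of
#' the centred eigenvector across the window). Alternatively a fixed number
#' of components (`n_components`) or a cumulative variance fraction
#' (`var_fraction`) may be requested.
#'
#' @param x numeric series (e.g. monthly global mean surface temperature
#'   anomalies in degrees Celsius).
#' @param window embedding window length, in time steps (months for monthly
#'   series); the series must be at least twice as long.
#' @param grouping `"frequency"` (default, the mean-periodicity rule),
#'   `"n"` (keep `n_components`), or `"var"` (smallest leading group whose
#'   squared singular values reach `var_fraction` of the total).
#' @param n_components,var_fraction parameters of the alternative groupings.
#' @return numeric vector of the same length as `x`: the reconstructed trend.
#' @examples
#' x <- seq(0, 2, length.out = 480) + sin(seq_len(480) / 3) * 0.1
#' trend <- ssa_smooth(x, window = 120)
#' @export
ssa_smooth <- function(x, window = 120L, grouping = c("frequency", "n", "var"),
                       n_components = 2L, var_fraction = 0.9) {
  grouping <- match.arg(grouping)
  x <- as.numeric(x)
  n <- length(x)
  if (window < 2L) stopf("`window` must be at least 2")
  if (n < 2L * window) {
    stopf("series length (%d) must be at least twice the window (%d)", n, window)
  }
  if (anyNA(x)) stopf("series contains missing values")

  L <- as.integer(window)
  K <- n - L + 1L
  # Hankel trajectory matrix: column j holds x[j .. j+L-1].
  idx <- outer(seq_len(L), seq_len(K) - 1L, `+`)
  X <- matrix(x[idx], nrow = L, ncol = K)
  dec <- svd(X)

  keep <- switch(grouping,
    frequency = {
      ok <- vapply(seq_len(ncol(dec$u)), function(j) {
        u <- dec$u[, j]
        u <- u - mean(u)
        sum(diff(sign(u)) != 0) <= 2L
      }, logical(1))
      k <- if (ok[1]) max(which(cumsum(!ok) == 0L)) else 1L
      seq_len(k)
    },
    n = seq_len(min(n_components, length(dec$d))),
    var = {
      frac <- cumsum(dec$d^2) / sum(dec$d^2)
      seq_len(which(frac >= var_fraction)[1])
    }
  )

  # Rank-one sum of the kept eigentriples, then diagonal averaging.
  Xr <- dec$u[, keep, drop = FALSE] %*%
    (dec$d[keep] * t(dec$v[, keep, drop = FALSE]))
  diag_average(Xr)
}

# Average a trajectory matrix over its anti-diagonals to recover a series.
diag_average <- function(M) {
  L <- nrow(M)
  K <- ncol(M)
  n <- L + K - 1L
  groups <- as.vector(row(M) + col(M)) - 1L  # anti-diagonal index 1..n
  as.numeric(tapply(as.vector(M), groups, mean))[seq_len(n)]
}

#' Centred moving-average smoothing of an annual series
#'
#' Sensitivity-analysis alternative to [ssa_smooth()]: a centred moving
#' average with an odd window. At the series edges the window shrinks
#' symmetrically so the output has the same length as the input.
#'
#' @param x numeric annual series.
#' @param window odd window length in years (default 5).
#' @return smoothed series, same length as `x`.
#' @export
moving_average_smooth <- function(x, window = 5L) {
  x <- as.numeric(x)
  window <- as.integer(window)
  if (window %% 2L == 0L) stopf("`window` must be odd")
  if (length(x) < window) stopf("series shorter than window")
  h <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1L, n - i)  # symmetric shrink at edges
    mean(x[(i - k):(i + k)])
  }, numeric(1))
}
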