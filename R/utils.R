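#' @keywords internal
"_PACKAGE"

# Half-vectorisation of a symmetric matrix (lower triangle, column-major).
vech <- function(m) m[lower.tri(m, diag = TRUE)]

# Rebuild a symmetric d x d matrix from its half-vectorisation.
unvech <- function(v, d) {
  m <- matrix(0, d, d)
  m[lower.tri(m, diag = TRUE)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

# Symmetric PSD check with a relative tolerance on the smallest eigenvalue.
is_psd <- function(m, tol = 1e-8) {
  if (!isSymmetric(unname(m), tol = 1e-8)) return(FALSE)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev[length(ev)] >= -tol * max(abs(ev[1]), 1)
}

# Nearest-PSD projection used only to guard Cholesky draws against
# round-off-negative eigenvalues; never applied to reported covariances.
psd_chol <- function(m) {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  # upper-triangular-free square root: t(R) %*% R = m (exact for PSD input)
  sqrt(vals) * t(e$vectors)
}

# Deterministic derived seeds (kept well below .Machine$integer.max).
derive_seed <- function(master, offset) {
  (as.integer(master) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

# Days of the warm season (Jun 1 - Sep 30) and the pre-season lag buffer.
warm_season_months <- 6:9

is_warm_season <- function(dates) {
  as.integer(format(dates, "%m")) %in% warm_season_months
}

# TRUE for dates needed as lag history: May 22 onward through Sep 30.
is_season_or_buffer <- function(dates, buffer_days = 10L) {
  m <- as.integer(format(dates, "%m"))
  d <- as.integer(format(dates, "%d"))
  (m %in% warm_season_months) | (m == 5L & d >= 22L)
}

date_year <- function(dates) as.integer(format(dates, "%Y"))
date_month <- function(dates) as.integer(format(dates, "%m"))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
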