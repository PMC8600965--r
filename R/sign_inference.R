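#' Time-lagged correlation coefficient (TLC)
#'
#' Pearson correlation between `x_i` and `y_{i - tau}` over the valid
#' overlap, with means computed on the overlap. A future-directed effect of
#' `x` on `y` with delay `s` samples therefore appears at `tau = -s`. Works
#' identically for continuous values and for 0/1 binned spike trains.
#'
#' @param x,y numeric vectors of equal length.
#' @param tau integer lag in samples (may be negative).
#' @return Correlation coefficient in `[-1, 1]`.
#' @examples
#' x <- rnorm(200); y <- c(0, 0, 0, x[1:197])
#' tlc(x, y, -3)
#' @export
tlc <- function(x, y, tau) {
  a <- lag_align(x, y, tau)
  if (length(a$x) < 3) stop("overlap after shifting is shorter than 3 samples")
  if (stats::sd(a$x) == 0 || stats::sd(a$y) == 0) {
    stop("undefined correlation: constant segment on the overlap")
  }
  stats::cor(a$x, a$y)
}

# Align x_i with y_{i - tau}; returns the overlapping segments plus the
# index range of i so conditioning channels can be cut identically.
lag_align <- function(x, y, tau) {
  tau <- as.integer(tau)
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  i <- seq_len(n)
  ok <- i - tau >= 1L & i - tau <= n
  i <- i[ok]
  list(x = x[i], y = y[i - tau], i = i)
}

#' Time-lagged partial correlation coefficient (TLPC)
#'
#' Partial correlation between `x^(j)_i` and `x^(k)_{i - tau}` given the
#' conditioning channels taken at lag 0 (aligned with the source index `i`).
#' Computed by the regression-residual route: both series are residualised
#' on the conditioning channels by least squares and the residuals are
#' correlated. This is algebraically identical to the recursive
#' one-variable-at-a-time elimination (see [tlpc_recursive()]) but free of
#' an elimination order.
#'
#' @param series a [ts_set].
#' @param j,k source and target channels (index or name).
#' @param tau integer lag in samples.
#' @param conditioning channels to condition on (excluding `j`, `k`); may be
#'   empty, in which case the TLC is returned.
#' @return Partial correlation coefficient.
#' @export
tlpc <- function(series, j, k, tau, conditioning = integer(0)) {
  stopifnot(inherits(series, "ts_set"))
  j <- resolve_channel(series, j)
  k <- resolve_channel(series, k)
  cset <- if (length(conditioning)) resolve_channel(series, conditioning) else integer(0)
  if (j %in% cset || k %in% cset) stop("conditioning set must exclude j and k")
  x <- series$values[, j]
  y <- series$values[, k]
  a <- lag_align(x, y, tau)
  if (length(a$i) < 3 + length(cset)) stop("overlap too short for conditioning set")
  if (length(cset) == 0) return(tlc(x, y, tau))
  W <- series$values[a$i, cset, drop = FALSE]
  qrW <- qr(cbind(1, W))
  if (qrW$rank < ncol(W) + 1) stop("collinear conditioning channels (rank deficiency)")
  rx <- qr.resid(qrW, a$x)
  ry <- qr.resid(qrW, a$y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: residuals are constant")
  }
  stats::cor(rx, ry)
}

#' Recursive time-lagged partial correlation (cross-check route)
#'
#' Implements the textbook recursion that removes conditioning channels one
#' at a time: the partial correlation given a set equals the partial
#' correlation given the set minus one element, corrected by the lag-0 and
#' lagged partial correlations with that element. Exposed as an independent
#' cross-check of [tlpc()]; the regression-residual route is canonical.
#'
#' @inheritParams tlpc
#' @return Partial correlation coefficient.
#' @export
tlpc_recursive <- function(series, j, k, tau, conditioning = integer(0)) {
  stopifnot(inherits(series, "ts_set"))
  j <- resolve_channel(series, j)
  k <- resolve_channel(series, k)
  cset <- if (length(conditioning)) resolve_channel(series, conditioning) else integer(0)
  # Align all variables on the common overlap first (source and lag-0
  # conditioning channels at index i, target at i - tau); the recursion then
  # runs on plain correlations of the aligned columns, so it agrees with the
  # regression-residual route to machine precision.
  a <- lag_align(series$values[, j], series$values[, k], as.integer(tau))
  cols <- cbind(src = a$x, tgt = a$y, series$values[a$i, cset, drop = FALSE])
  rho <- function(ia, ib, cs) {
    if (length(cs) == 0) return(stats::cor(cols[, ia], cols[, ib]))
    i <- cs[length(cs)]
    rest <- cs[-length(cs)]
    r_ab <- rho(ia, ib, rest)
    r_ai <- rho(ia, i, rest)
    r_ib <- rho(i, ib, rest)
    (r_ab - r_ai * r_ib) / (sqrt(1 - r_ai^2) * sqrt(1 - r_ib^2))
  }
  rho(1L, 2L, 2L + seq_along(cset))
}

#' Excitatory/inhibitory sign of a directed connection
#'
#' Scans a range of strictly negative lags, finds the lag `tau*` maximising
#' the absolute time-lagged partial correlation between source and target
#' (given the conditioning channels at lag 0), and returns the sign of the
#' coefficient there: +1 excitation, -1 inhibition. Ties in absolute value
#' are broken toward the lag closest to zero. Lags whose coefficient is
#' undefined (constant overlap) are skipped; if all are undefined the sign
#' is `NA` (undetermined).
#'
#' @param series a [ts_set].
#' @param j,k source and target channels.
#' @param conditioning channels conditioned on (lag 0); may be empty, which
#'   gives the purely pairwise TLC-based sign.
#' @param lag_range vector of negative integer lags to scan (default
#'   `-1 ... -5 * M` with `M = 3`, i.e. `-15:-1`).
#' @return List with `sign` (+1, -1 or NA), `tau_star` (samples) and the
#'   scanned `coefficients`.
#' @export
infer_sign <- function(series, j, k, conditioning = integer(0),
                       lag_range = -(1:15)) {
  lag_range <- as.integer(lag_range)
  if (length(lag_range) == 0 || any(lag_range >= 0)) {
    stop("'lag_range' must contain strictly negative lags")
  }
  lag_range <- sort(unique(lag_range), decreasing = TRUE)  # closest to zero first
  coef <- vapply(lag_range, function(tau) {
    tryCatch(tlpc(series, j, k, tau, conditioning), error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(coef))) {
    return(list(sign = NA_real_, tau_star = NA_integer_,
                coefficients = stats::setNames(coef, lag_range)))
  }
  best <- which.max(abs(coef))  # first max = tie toward smallest |tau|
  list(sign = unname(sign(coef[best])),
       tau_star = lag_range[best],
       coefficients = stats::setNames(coef, lag_range))
}
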