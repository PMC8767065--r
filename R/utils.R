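#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ordinary least-squares line fit
#'
#' Closed-form univariate OLS used by the tangent and slope estimators.
#'
#' @param t numeric vector of abscissae (time, seconds or minutes).
#' @param v numeric vector of ordinates, same length as `t`.
#' @return list with `slope`, `intercept`, `rmse` and `n`.
#' @keywords internal
ols_fit <- function(t, v) {
  n <- length(t)
  if (n < 2L) stop("ols_fit: need at least 2 points", call. = FALSE)
  mt <- mean(t); mv <- mean(v)
  sxx <- sum((t - mt)^2)
  if (sxx <= 0) stop("ols_fit: degenerate abscissae (zero variance)", call. = FALSE)
  slope <- sum((t - mt) * (v - mv)) / sxx
  intercept <- mv - slope * mt
  res <- v - (intercept + slope * t)
  list(slope = slope, intercept = intercept,
       rmse = sqrt(mean(res^2)), n = n)
}

# Rolling OLS slope over windows [t[i], t[i] + width], vectorised with
# cumulative sums; returns NA where fewer than min_n samples fall in a window.
roll_ols_slope <- function(t, v, width, min_n = 3L) {
  n <- length(t)
  jend <- findInterval(t + width + 1e-9, t)
  ct  <- cumsum(t);   cv  <- cumsum(v)
  ct2 <- cumsum(t^2); ctv <- cumsum(t * v)
  i <- seq_len(n)
  m  <- jend - i + 1L
  sum_rng <- function(cs) cs[jend] - c(0, cs)[i]
  st <- sum_rng(ct); sv <- sum_rng(cv)
  st2 <- sum_rng(ct2); stv <- sum_rng(ctv)
  denom <- m * st2 - st^2
  slope <- (m * stv - st * sv) / denom
  slope[m < min_n | abs(denom) < 1e-300] <- NA_real_
  list(slope = slope, end = jend, n = m)
}

# Trapezoidal integral of y over x on the sample grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Linear interpolation of a trace at a single time point (clamped to range).
interp_at <- function(t, v, x) {
  stats::approx(t, v, xout = x, rule = 2)$y
}

robust_sd <- function(x) stats::mad(x, constant = 1.4826)

# Theil-Sen robust line: median of pairwise slopes, median-based intercept.
# Used for the plateau trend, where a fraction of samples may already lie
# on the secondary rise; exact on clean linear data.
theil_sen_fit <- function(t, v) {
  n <- length(t)
  if (n < 2L) stop("theil_sen_fit: need at least 2 points", call. = FALSE)
  ij <- utils::combn(n, 2)
  slopes <- (v[ij[2, ]] - v[ij[1, ]]) / (t[ij[2, ]] - t[ij[1, ]])
  slope <- stats::median(slopes)
  intercept <- stats::median(v - slope * t)
  list(slope = slope, intercept = intercept)
}
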