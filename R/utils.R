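# Internal helpers shared across modules.

# Map time differences to the half-open interval (-T/2, T/2].
wrap_half <- function(x, T) {
  y <- x - T * round(x / T)
  y[y <= -T / 2] <- y[y <= -T / 2] + T
  y
}

# Circular mean (and sd) of time lags on a cycle of period T.
circ_mean_lag <- function(lags, T) {
  a <- 2 * pi * lags / T
  s <- mean(sin(a)); c <- mean(cos(a))
  m <- atan2(s, c) * T / (2 * pi)
  R <- sqrt(s^2 + c^2)
  csd <- if (R >= 1) 0 else sqrt(-2 * log(R)) * T / (2 * pi)
  list(mean = wrap_half(m, T), sd = csd)
}

# Local maxima of a sampled trace.  Peak times are refined by a quadratic
# fit through the three samples around each maximum.  Only peaks above
# min + height_frac * (max - min) are kept.
find_peaks <- function(t, y, height_frac = 0.25) {
  n <- length(y)
  if (n < 3L) return(numeric(0))
  thr <- min(y) + height_frac * (max(y) - min(y))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  idx <- idx[y[idx] > thr]
  if (length(idx) == 0L) return(numeric(0))
  # quadratic refinement on uniform grid
  h <- t[2] - t[1]
  ym <- y[idx - 1L]; y0 <- y[idx]; yp <- y[idx + 1L]
  den <- ym - 2 * y0 + yp
  off <- ifelse(abs(den) > 0, 0.5 * (ym - yp) / den, 0)
  off[abs(off) > 1] <- 0
  t[idx] + off * h
}

# Periodic cubic-spline interpolant of samples y on the uniform grid
# t = 0, T/M, ..., T(1 - 1/M).  Returns a function of time, evaluated with
# circular wrapping.
periodic_interp <- function(y, T) {
  M <- length(y)
  tg <- seq(0, T, length.out = M + 1)
  f <- stats::splinefun(tg, c(y, y[1]), method = "periodic")
  function(t) f(t %% T)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
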