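#' Interaction function H of two weakly coupled circuits
#'
#' Cycle-averaged effect of one circuit's pyramidal output on the phase of
#' the other, computed from the adjoint PRC and the limit cycle:
#' \deqn{H(\theta) = \frac{G_{ee}}{T}\int_0^T Z_{s_{ee}}(s)\,
#'   r_e(s-\theta)\,ds + \frac{G_{ie}}{T}\int_0^T Z_{s_{ie}}(s)\,
#'   r_e(s-\theta)\,ds,}
#' by trapezoid quadrature on the shared uniform phase grid (on which the
#' circular shift is exact).  Because the cross projections originate from
#' the pyramidal cells only, H involves solely the synaptic adjoint
#' components \eqn{Z_{s_{ee}}}, \eqn{Z_{s_{ie}}} and the E-rate; it is
#' linear in \eqn{(G_{ee}, G_{ie})} and the unit-strength components are
#' kept so scans over the couplings need no recomputation.
#'
#' @param adjoint An [adjoint_iprc()] result.
#' @param cycle The [find_limit_cycle()] the adjoint was computed on
#'   (defaults to the one stored in `adjoint`); must share grid and
#'   period.
#' @param cross A [cross_coupling()] (its delay is used later by
#'   [coupling_function()]).
#' @param rescale_tau_s If `TRUE`, divide H by \eqn{\tau_s}, matching the
#'   standard averaging of a perturbation entering through the synapse
#'   equation; default `FALSE`, the convention used throughout (identical
#'   at the canonical \eqn{\tau_s = 1}).
#'
#' @return An object of class `coupling_functions` with fields `theta`
#'   (time-lag grid over one period), `H`, the unit components `H_ee`,
#'   `H_ie`, `period`, `cross`, and later `G`/`delay` once
#'   [coupling_function()] is applied.
#' @export
interaction_function <- function(adjoint, cycle = NULL, cross,
                                 rescale_tau_s = FALSE) {
  stopifnot(inherits(adjoint, "adjoint_prc"), inherits(cross, "cross_coupling"))
  cycle <- cycle %||% adjoint$cycle
  if (length(adjoint$t) != nrow(cycle$states) ||
      abs(adjoint$period - cycle$period) > 1e-9 * cycle$period)
    stop("grid-mismatch: adjoint and limit cycle must share grid and period")
  M <- length(adjoint$t)
  re <- cycle$states[, "r_e"]
  zsee <- adjoint$Z[, "Z_see"]
  zsie <- adjoint$Z[, "Z_sie"]
  # H_j = (1/T) * sum_k Z(t_k) re(t_k - theta_j) * h ; h = T/M
  shift_corr <- function(z) {
    out <- numeric(M)
    idx0 <- seq_len(M)
    for (j in 0:(M - 1)) {
      k <- ((idx0 - 1 - j) %% M) + 1
      out[j + 1] <- sum(z * re[k]) / M
    }
    out
  }
  scale <- if (rescale_tau_s) 1 / cycle$couplings$tau_s else 1
  H_ee <- shift_corr(zsee) * scale
  H_ie <- shift_corr(zsie) * scale
  structure(list(theta = adjoint$t, period = cycle$period,
                 H = cross$g_ee * H_ee + cross$g_ie * H_ie,
                 H_ee = H_ee, H_ie = H_ie, cross = cross,
                 G = NULL, delay = NULL),
            class = "coupling_functions")
}

#' Coupling function G: odd part of the delay-shifted H
#'
#' The phase-difference equation of the two delay-coupled circuits is
#' \eqn{\dot\theta \propto G(\theta)} with
#' \deqn{G(\theta) = H(\theta + d) - H(-\theta + d),}
#' the odd part of the delay-shifted interaction function (d the
#' conduction delay, \eqn{\theta} the phase of circuit 1 minus circuit
#' 2 in time units).  The orientation of the delay shift is fixed by
#' requiring consistency with the coupled sixteen-dimensional delay
#' system itself: the drift of the simulated phase lag matches
#' \eqn{(T/2\pi)\,G} pointwise (see the methods vignette).  G is
#' evaluated through a periodic cubic-spline interpolant of H, which
#' makes the exact identities \eqn{G(0) = 0}, \eqn{G(T/2) = 0} and the
#' antisymmetry \eqn{G(-\theta) = -G(\theta)} hold at machine precision
#' for every delay.
#'
#' @param cf A `coupling_functions` object from [interaction_function()].
#' @param delay Conduction delay d (ms); defaults to the delay carried by
#'   the object's `cross`.
#'
#' @return The `coupling_functions` object with `G` (samples on the
#'   `theta` grid), `delay`, and an interpolator usable by
#'   [locking_modes()].
#' @export
coupling_function <- function(cf, delay = NULL) {
  stopifnot(inherits(cf, "coupling_functions"))
  delay <- delay %||% cf$cross$delay
  if (!is.finite(delay) || delay < 0) stop("'delay' must be >= 0")
  Hfun <- periodic_interp(cf$H, cf$period)
  cf$G <- Hfun(cf$theta + delay) - Hfun(-cf$theta + delay)
  cf$delay <- delay
  cf$G_fun <- function(theta) Hfun(theta + delay) - Hfun(-theta + delay)
  cf
}

#' Phase-locking modes: zeros of the G-function
#'
#' The zeros of G are the steady-state phase lags of the two coupled
#' circuits; a zero is a stable locking mode when the slope there is
#' negative.  Zeros are located from sign changes on the sample grid and
#' refined by bisection to `|G| < 1e-10`; the in-phase (0) and anti-phase
#' (T/2) lags, exact zeros by construction, are always reported.  Zeros
#' with `|slope| < 1e-8` are flagged marginal rather than classified.
#'
#' @param cf A `coupling_functions` object with `G` (see
#'   [coupling_function()]).
#'
#' @return A data.frame with one row per mode: `theta_star` (in `[0, T)`,
#'   ms), `stable`, `slope`, `marginal`.
#' @export
locking_modes <- function(cf) {
  stopifnot(inherits(cf, "coupling_functions"))
  if (is.null(cf$G)) stop("apply coupling_function() first")
  T <- cf$period
  G <- cf$G_fun
  M <- length(cf$theta)
  if (M < 512L) stop("G must be sampled on at least 512 points")

  zeros <- c(0, T / 2)
  g <- cf$G
  th <- cf$theta
  sgn <- sign(g)
  for (j in seq_len(M)) {
    k <- if (j == M) 1L else j + 1L
    if (sgn[j] == 0) next
    if (sgn[j] * sgn[k] < 0) {
      lo <- th[j]; hi <- th[j] + T / M
      for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (G(lo) * G(mid) <= 0) hi <- mid else lo <- mid
        if (abs(G(mid)) < 1e-10 && (hi - lo) < 1e-12 * T) break
      }
      zeros <- c(zeros, ((lo + hi) / 2) %% T)
    }
  }
  zeros <- sort(unique(round(zeros / T, 9)) * T)
  # merge zeros closer than grid resolution
  keep <- c(TRUE, diff(zeros) > T / (4 * M))
  if (length(zeros) > 1 &&
      (T - zeros[length(zeros)] + zeros[1]) < T / (4 * M)) keep[length(zeros)] <- FALSE
  zeros <- zeros[keep]

  eps <- T / 4096
  slope <- vapply(zeros, function(z) (G(z + eps) - G(z - eps)) / (2 * eps),
                  numeric(1))
  data.frame(theta_star = zeros,
             stable = slope < 0,
             slope = slope,
             marginal = abs(slope) < 1e-8)
}

#' Bifurcation diagram of the locking modes
#'
#' Tracks the zeros of the G-function and their stability while one of
#' the cross-coupling parameters (the delay d, or the strengths G_ee,
#' G_ie) is scanned.  H is linear in the coupling strengths, so only its
#' precomputed unit components are recombined; scanning the delay merely
#' re-shifts H.  The resulting diagram shows the in-phase/anti-phase
#' stability exchange with delay and the window of intermediate,
#' symmetry-broken lags.
#'
#' @param cf A `coupling_functions` object (from
#'   [interaction_function()]).
#' @param scan One of `"d"`, `"g_ee"`, `"g_ie"`.
#' @param values Sorted grid of scan values.
#'
#' @return A data.frame with columns `value`, `theta_star`, `stable`,
#'   `slope`, `marginal` (one row per mode per grid value).
#' @export
locking_bifurcation <- function(cf, scan = c("d", "g_ee", "g_ie"), values) {
  stopifnot(inherits(cf, "coupling_functions"))
  scan <- match.arg(scan)
  if (is.unsorted(values)) stop("'values' grid must be sorted")
  rows <- lapply(values, function(v) {
    cfi <- cf
    if (scan == "g_ee") {
      cfi$H <- v * cf$H_ee + cf$cross$g_ie * cf$H_ie
    } else if (scan == "g_ie") {
      cfi$H <- cf$cross$g_ee * cf$H_ee + v * cf$H_ie
    }
    d <- if (scan == "d") v else (cf$delay %||% cf$cross$delay)
    cfi <- coupling_function(cfi, delay = d)
    lm <- locking_modes(cfi)
    cbind(value = v, lm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scan") <- scan
  out
}

#' @export
print.coupling_functions <- function(x, ...) {
  cat(sprintf("Coupling functions on %d phase samples, T = %.4f ms; G_ee = %g, G_ie = %g%s\n",
              length(x$theta), x$period, x$cross$g_ee, x$cross$g_ie,
              if (!is.null(x$delay)) sprintf(", delay = %g ms", x$delay)
              else " (no delay applied yet)"))
  invisible(x)
}
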