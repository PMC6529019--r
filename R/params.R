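#' Physical constants of one neural population
#'
#' Bundles the parameters of a population of quadratic integrate-and-fire
#' (QIF) neurons, \eqn{\tau \dot v_j = \eta_j + v_j^2 + I}, whose
#' excitabilities \eqn{\eta_j} follow a Lorentzian distribution with centre
#' \eqn{\bar\eta} and half-width \eqn{\Delta}.  Time is measured in
#' milliseconds throughout the package, so a membrane time constant of 10
#' places the emergent network rhythms in the gamma band when frequencies
#' are read as \eqn{f = 1000/T} Hz.
#'
#' @param tau Membrane time constant (ms, > 0).
#' @param eta_bar Centre of the Lorentzian excitability distribution
#'   (dimensionless current units).
#' @param delta Half-width of the excitability distribution (>= 0).
#' @param n Number of neurons (integer >= 1); used by the finite-size
#'   spiking simulators, irrelevant to the mean-field reduction.
#' @param v_th Spike cut-off voltage (spiking simulations only).
#' @param v_r Reset voltage, must be below `v_th`.
#'
#' @return An object of class `population_params`.
#' @examples
#' population_params(tau = 10, eta_bar = -5, delta = 1, n = 5000)
#' @export
population_params <- function(tau, eta_bar, delta, n = 1L,
                              v_th = 500, v_r = -500) {
  stopifnot(is.numeric(tau), length(tau) == 1L)
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be a positive number")
  if (!is.finite(eta_bar)) stop("'eta_bar' must be finite")
  if (!is.finite(delta) || delta < 0) stop("'delta' must be >= 0")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be an integer >= 1")
  if (!is.finite(v_th) || !is.finite(v_r) || v_r >= v_th)
    stop("'v_r' must be below 'v_th'")
  structure(list(tau = tau, eta_bar = eta_bar, delta = delta, n = n,
                 v_th = v_th, v_r = v_r),
            class = "population_params")
}

#' Within-circuit synaptic coupling strengths
#'
#' Synaptic strengths use the beta-to-alpha convention: `j_ab` is the
#' strength of population *b* projecting onto population *a* (e.g. `j_ei`
#' is the inhibitory synapse onto the E-cells).  Each synapse is a
#' first-order exponential filter of the presynaptic population rate,
#' \eqn{\tau_s \dot s_{\alpha\beta} = -s_{\alpha\beta} +
#' J_{\alpha\beta} r_\beta}.
#'
#' @param j_ee,j_ei,j_ie,j_ii Synaptic strengths (finite; `j_ei`, `j_ii`
#'   are magnitudes of inhibition, entering the currents with a minus sign).
#' @param tau_s Synaptic time constant (ms, > 0), shared by all synapses.
#'
#' @return An object of class `synaptic_couplings`.
#' @examples
#' synaptic_couplings(j_ee = 0, j_ei = 15, j_ie = 15, j_ii = 0)
#' @export
synaptic_couplings <- function(j_ee, j_ei, j_ie, j_ii, tau_s = 1) {
  vals <- c(j_ee, j_ei, j_ie, j_ii)
  if (length(vals) != 4L || !all(is.finite(vals)))
    stop("synaptic strengths must be single finite numbers")
  if (!is.finite(tau_s) || tau_s <= 0) stop("'tau_s' must be > 0")
  structure(list(j_ee = j_ee, j_ei = j_ei, j_ie = j_ie, j_ii = j_ii,
                 tau_s = tau_s),
            class = "synaptic_couplings")
}

#' Piecewise-constant external drive protocol
#'
#' External currents injected into the E and I populations as step
#' functions of time.  Segment `k` starts at `start[k]` and lasts until the
#' next segment (the final segment extends to the end of any simulation).
#'
#' @param start Numeric vector of segment start times (ms), strictly
#'   increasing; the first must be 0.
#' @param i_ext_e,i_ext_i External current on the E (resp. I) cells during
#'   each segment; recycled to the length of `start` if scalar.
#'
#' @return An object of class `drive_protocol`.
#' @examples
#' drive_protocol(start = c(0, 100, 200), i_ext_e = c(0, 10, 0), i_ext_i = 0)
#' @export
drive_protocol <- function(start = 0, i_ext_e = 0, i_ext_i = 0) {
  start <- as.numeric(start)
  if (length(start) < 1L || start[1] != 0 || is.unsorted(start, strictly = TRUE))
    stop("'start' must be strictly increasing and begin at 0")
  i_ext_e <- rep_len(as.numeric(i_ext_e), length(start))
  i_ext_i <- rep_len(as.numeric(i_ext_i), length(start))
  if (!all(is.finite(c(i_ext_e, i_ext_i)))) stop("drive values must be finite")
  structure(list(start = start, i_ext_e = i_ext_e, i_ext_i = i_ext_i),
            class = "drive_protocol")
}

#' Constant drive helper
#'
#' @param i_ext_e,i_ext_i Constant external currents on the two populations.
#' @return A single-segment [drive_protocol()].
#' @export
constant_drive <- function(i_ext_e = 0, i_ext_i = 0) {
  drive_protocol(0, i_ext_e, i_ext_i)
}

#' Evaluate a drive protocol at given times
#'
#' @param drive A [drive_protocol()].
#' @param t Times (ms).
#' @return A two-column matrix with columns `i_ext_e`, `i_ext_i`.
#' @export
drive_value <- function(drive, t) {
  stopifnot(inherits(drive, "drive_protocol"))
  idx <- findInterval(t, drive$start, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  cbind(i_ext_e = drive$i_ext_e[idx], i_ext_i = drive$i_ext_i[idx])
}

#' Cross-circuit coupling and conduction delay
#'
#' Projections between the two circuits originate from the pyramidal cells
#' only: `g_ee` targets the partner's E-cells, `g_ie` its I-cells.  The
#' phase-reduction machinery assumes these are weak relative to the
#' within-circuit synapses; when `max(g_ee, g_ie)` exceeds
#' `weak_threshold` the object carries a raised `extrapolated` flag and
#' analyses proceed with results marked as outside the weak-coupling
#' regime.
#'
#' @param g_ee,g_ie Cross-circuit strengths (>= 0).
#' @param delay Conduction delay `d` between the circuits (ms, >= 0).
#' @param weak_threshold Strength above which the weak-coupling assumption
#'   is considered violated (default 0.5).
#'
#' @return An object of class `cross_coupling` with logical field
#'   `extrapolated`.
#' @examples
#' cross_coupling(g_ee = 0.1, g_ie = 0.5, delay = 10)
#' @export
cross_coupling <- function(g_ee = 0, g_ie = 0, delay = 0,
                           weak_threshold = 0.5) {
  if (!all(is.finite(c(g_ee, g_ie))) || g_ee < 0 || g_ie < 0)
    stop("cross-coupling strengths must be finite and >= 0")
  if (!is.finite(delay) || delay < 0) stop("'delay' must be >= 0")
  structure(list(g_ee = g_ee, g_ie = g_ie, delay = delay,
                 weak_threshold = weak_threshold,
                 extrapolated = max(g_ee, g_ie) > weak_threshold),
            class = "cross_coupling")
}

# parameter vector handed to the compiled cores
pack_params <- function(e_params, i_params, couplings) {
  stopifnot(inherits(e_params, "population_params"),
            inherits(i_params, "population_params"),
            inherits(couplings, "synaptic_couplings"))
  c(e_params$tau, e_params$eta_bar, e_params$delta,
    i_params$tau, i_params$eta_bar, i_params$delta,
    couplings$tau_s,
    couplings$j_ee, couplings$j_ei, couplings$j_ie, couplings$j_ii)
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf(
    "QIF population: N = %d, tau = %g ms, eta_bar = %g, delta = %g, reset/cutoff = %g/%g\n",
    x$n, x$tau, x$eta_bar, x$delta, x$v_r, x$v_th))
  invisible(x)
}

#' @export
print.cross_coupling <- function(x, ...) {
  cat(sprintf("Cross coupling: G_ee = %g, G_ie = %g, delay = %g ms%s\n",
              x$g_ee, x$g_ie, x$delay,
              if (x$extrapolated) " [beyond weak-coupling regime]" else ""))
  invisible(x)
}
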