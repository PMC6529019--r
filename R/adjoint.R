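#' Jacobian of the reduced E-I system
#'
#' The 8x8 linearization M of the mean-field vector field at a given
#' state, in the ordering `(r_e, V_e, s_ee, s_ei, r_i, V_i, s_ie, s_ii)`.
#' Row 1 is \eqn{(2V_e/\tau_e,\ 2r_e/\tau_e,\ 0, \dots)}; row 2 is
#' \eqn{(-2\tau_e\pi^2 r_e,\ 2V_e/\tau_e,\ 1,\ -1,\ 0,\dots)}; each
#' synapse row carries \eqn{-1/\tau_s} on the diagonal and
#' \eqn{J_{\alpha\beta}/\tau_s} in the presynaptic-rate column.  Evaluated
#' along a limit cycle this is the periodic matrix M(t) whose transpose
#' drives the adjoint (iPRC) equation.
#'
#' @inheritParams mf_vector_field
#' @return An 8x8 numeric matrix.
#' @export
linearization_matrix <- function(state, e_params, i_params, couplings) {
  stopifnot(length(state) == 8L)
  te <- e_params$tau; ti <- i_params$tau; ts <- couplings$tau_s
  re <- state[1]; Ve <- state[2]; ri <- state[5]; Vi <- state[6]
  M <- matrix(0, 8, 8, dimnames = list(mf_state_names, mf_state_names))
  M[1, 1] <- 2 * Ve / te;            M[1, 2] <- 2 * re / te
  M[2, 1] <- -2 * te * pi^2 * re;    M[2, 2] <- 2 * Ve / te
  M[2, 3] <- 1;                      M[2, 4] <- -1
  M[3, 1] <- couplings$j_ee / ts;    M[3, 3] <- -1 / ts
  M[4, 5] <- couplings$j_ei / ts;    M[4, 4] <- -1 / ts
  M[5, 5] <- 2 * Vi / ti;            M[5, 6] <- 2 * ri / ti
  M[6, 5] <- -2 * ti * pi^2 * ri;    M[6, 6] <- 2 * Vi / ti
  M[6, 7] <- 1;                      M[6, 8] <- -1
  M[7, 1] <- couplings$j_ie / ts;    M[7, 7] <- -1 / ts
  M[8, 5] <- couplings$j_ii / ts;    M[8, 8] <- -1 / ts
  M
}

#' Macroscopic infinitesimal phase-resetting curve via the adjoint method
#'
#' Solves the adjoint equation \eqn{-\dot Z = M(t)^T Z} for the periodic
#' eight-component vector Z(t) along a limit cycle of the reduced E-I
#' system.  Backward integration with per-period renormalisation extracts
#' the unique periodic solution (backward time turns the cycle's
#' attracting Floquet directions into decaying ones); iteration stops when
#' the per-period relative change falls below `tol`, and the result is
#' rescaled once so that the cycle average of \eqn{Z\cdot\dot O} equals
#' \eqn{2\pi/T}.  The pointwise constancy of \eqn{Z\cdot\dot O} is a
#' structural property of the adjoint flow and is reported as an
#' integration-quality residual.
#'
#' @param cycle A [find_limit_cycle()] result.
#' @param tol Per-period relative change declaring convergence (default
#'   1e-8).
#' @param max_periods Cap on backward periods before an
#'   adjoint-divergence error (default 200).
#'
#' @return An object of class `adjoint_prc`: `period`, `t` (the cycle's
#'   phase-time grid), `Z` (`n_samples` x 8, columns `Z_re ... Z_sii`),
#'   `normalization_residual` (max pointwise relative deviation of
#'   \eqn{Z\cdot\dot O} from \eqn{2\pi/T}), `periodicity_residual`
#'   (relative `||Z(0) - Z(T)||`), and `periods_used`.
#' @export
adjoint_iprc <- function(cycle, tol = 1e-8, max_periods = 200L) {
  stopifnot(inherits(cycle, "limit_cycle"))
  par <- pack_params(cycle$e_params, cycle$i_params, cycle$couplings)
  cyc4 <- cycle$states[, c("r_e", "V_e", "r_i", "V_i")]
  res <- tryCatch(
    adjoint_backward_cpp(cyc4, par, cycle$period, tol, as.integer(max_periods)),
    error = function(e) {
      if (grepl("did not converge|lost the solution", conditionMessage(e)))
        stop("adjoint-divergence: ", conditionMessage(e),
             " (unstable or marginal cycle?)", call. = FALSE)
      stop(e)
    })
  Z <- res$Z
  # scale so that mean(Z . Odot) = 2*pi/T
  Odot <- t(apply(cycle$states, 1, mf_vector_field,
                  e_params = cycle$e_params, i_params = cycle$i_params,
                  couplings = cycle$couplings,
                  drive_values = cycle$drive_values))
  dots <- rowSums(Z * Odot)
  target <- 2 * pi / cycle$period
  alpha <- target / mean(dots)
  Z <- Z * alpha
  dots <- dots * alpha
  per_res <- sqrt(sum((res$z_final - res$Z[1, ])^2)) /
    sqrt(sum(res$Z[1, ]^2))
  colnames(Z) <- paste0("Z_", c("re", "ve", "see", "sei", "ri", "vi", "sie", "sii"))
  structure(list(period = cycle$period, t = cycle$t, Z = Z,
                 normalization_residual = max(abs(dots - target)) / target,
                 periodicity_residual = per_res,
                 periods_used = res$periods,
                 cycle = cycle),
            class = "adjoint_prc")
}

#' @export
print.adjoint_prc <- function(x, ...) {
  cat(sprintf(
    "Adjoint iPRC: T = %.4f ms, %d samples, normalization residual %.2e, periodicity residual %.2e (%d backward periods)\n",
    x$period, length(x$t), x$normalization_residual,
    x$periodicity_residual, x$periods_used))
  invisible(x)
}

#' Phase-resetting curve by direct pulse perturbation
#'
#' Measures the macroscopic PRC the way an experimenter would: for each
#' onset phase a square current pulse is applied to the chosen population,
#' the system is integrated for many cycles, and the asymptotic shift of
#' the `r_e` peak times relative to an unperturbed reference is read out,
#' mapped to \eqn{(-T/2, T/2]} and converted to radians (advance
#' positive).  The `"reduced"` backend perturbs the mean-field system;
#' the `"spiking"` backend perturbs a finite-size network (noisy by
#' finite-size effects, so large N is recommended).
#'
#' @param cycle A [find_limit_cycle()] result (defines the unperturbed
#'   rhythm, the phase origin at the `r_e` maximum, and the parameters).
#' @param pulse List with `target` (`"E"`/`"I"`), `amplitude` and
#'   `duration` (ms).
#' @param phase_grid Onset phases in radians over `[0, 2*pi)`.
#' @param backend `"reduced"` (default) or `"spiking"`.
#' @param n_periods Cycles integrated after the pulse before the shift is
#'   read out (>= 20; asymptotic shift, default 25).
#' @param n Spiking backend: neurons per population (default 5000).
#' @param seed Spiking backend seed.
#' @param settle_tol Plateau tolerance for the shift across the last five
#'   cycles, as a fraction of T (default 1/100); exceeded values raise an
#'   unsettled-shift error.
#'
#' @return A data.frame with columns `phase` (onset, radians),
#'   `shift_rad`, `shift_ms`.
#' @export
direct_prc <- function(cycle, pulse, phase_grid = seq(0, 2 * pi, length.out = 33)[-33],
                       backend = c("reduced", "spiking"), n_periods = 25L,
                       n = 5000L, seed = 1L, settle_tol = 0.01) {
  stopifnot(inherits(cycle, "limit_cycle"))
  backend <- match.arg(backend)
  T <- cycle$period
  pulse$duration <- pulse$duration %||% 0.1
  if (backend == "reduced")
    direct_prc_reduced(cycle, pulse, phase_grid, n_periods, settle_tol)
  else
    direct_prc_spiking(cycle, pulse, phase_grid, n_periods, n, seed)
}

direct_prc_reduced <- function(cycle, pulse, phase_grid, n_periods, settle_tol) {
  T <- cycle$period
  dur <- (n_periods + 3) * T
  run <- function(pl) {
    tr <- integrate_mf(cycle$states[1, ], cycle$e_params, cycle$i_params,
                       cycle$couplings, cycle$drive_values,
                       duration = dur, step = cycle$step, pulse = pl)
    find_peaks(tr$t, tr$states[, 1])
  }
  ref_peaks <- run(NULL)
  shifts <- vapply(phase_grid, function(ph) {
    pl <- list(target = pulse$target, amplitude = pulse$amplitude,
               duration = pulse$duration, onset = ph / (2 * pi) * T)
    pk <- run(pl)
    peak_shift(ref_peaks, pk, T, n_last = 5, settle_tol = settle_tol)
  }, numeric(1))
  data.frame(phase = phase_grid,
             shift_rad = 2 * pi * shifts / T,
             shift_ms = shifts)
}

direct_prc_spiking <- function(cycle, pulse, phase_grid, n_periods, n, seed) {
  T <- cycle$period
  ep <- cycle$e_params; ip <- cycle$i_params
  ep$n <- as.integer(n); ip$n <- as.integer(n)
  dv <- cycle$drive_values
  settle <- 20 * T
  dur <- settle + (n_periods + 3) * T
  base <- drive_protocol(0, dv[1], dv[2])
  run <- function(drv) {
    sim <- simulate_spiking_network(ep, ip, cycle$couplings, drv,
                                    duration = dur, step = 0.01, seed = seed)
    tr <- sim$rates
    keep <- tr$t > settle / 2
    find_peaks(tr$t[keep], tr$r_e[keep])
  }
  ref_peaks <- run(base)
  anchor <- ref_peaks[which.min(abs(ref_peaks - settle))]
  shifts <- vapply(phase_grid, function(ph) {
    on <- anchor + ph / (2 * pi) * T
    amp <- pulse$amplitude
    drv <- pulse_drive(base, pulse$target, amp, on, pulse$duration)
    pk <- run(drv)
    peak_shift(ref_peaks, pk, T, n_last = 5, settle_tol = Inf)
  }, numeric(1))
  data.frame(phase = phase_grid,
             shift_rad = 2 * pi * shifts / T,
             shift_ms = shifts)
}

# splice a square pulse into a piecewise-constant protocol
pulse_drive <- function(drive, target, amplitude, onset, duration) {
  tpts <- sort(unique(c(drive$start, onset, onset + duration)))
  vv <- drive_value(drive, tpts)
  sel <- tpts >= onset & tpts < onset + duration
  if (toupper(target) == "E") vv[sel, 1] <- vv[sel, 1] + amplitude
  else vv[sel, 2] <- vv[sel, 2] + amplitude
  drive_protocol(tpts, vv[, 1], vv[, 2])
}

# asymptotic peak-time shift (reference minus perturbed; advance positive)
peak_shift <- function(ref_peaks, pert_peaks, T, n_last = 5, settle_tol = 0.01) {
  if (length(pert_peaks) < n_last + 1 || length(ref_peaks) < n_last + 1)
    stop("unsettled-shift: too few peaks to measure an asymptotic shift")
  last <- utils::tail(pert_peaks, n_last)
  d <- vapply(last, function(tp) {
    wrap_half(ref_peaks[which.min(abs(ref_peaks - tp))] - tp, T)
  }, numeric(1))
  if (is.finite(settle_tol) && stats::sd(d) > settle_tol * T)
    stop(sprintf("unsettled-shift: peak shift varies by %.3g ms over the last %d cycles",
                 stats::sd(d), n_last))
  circ_mean_lag(d, T)$mean
}

#' Classify a phase-resetting curve
#'
#' Labels a sampled PRC as `"null"` (never exceeds the noise floor),
#' `"type II"` (biphasic: both signs exceed the floor) or `"type I"`
#' (monophasic).
#'
#' @param values Sampled PRC over a full period.
#' @param noise_floor Absolute magnitude below which the curve counts as
#'   zero; defaults to 5% of the curve's maximum absolute value.
#'
#' @return One of `"type I"`, `"type II"`, `"null"`.
#' @export
classify_prc <- function(values, noise_floor = NULL) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) return("null")
  noise_floor <- noise_floor %||% (0.05 * max(abs(values)))
  if (max(abs(values)) < noise_floor || all(values == 0)) return("null")
  pos <- max(values) > noise_floor
  neg <- min(values) < -noise_floor
  if (pos && neg) "type II" else "type I"
}
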