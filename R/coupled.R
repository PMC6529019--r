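#' Simulate two delay-coupled reduced circuits
#'
#' Integrates the sixteen-dimensional delay differential system of two
#' identical E-I circuits whose pyramidal populations project onto the
#' partner circuit's E and I cells with strengths \eqn{G_{ee}},
#' \eqn{G_{ie}} and conduction delay d: the delayed terms
#' \eqn{G_{ee} r_e^{(2)}(t-d)} and \eqn{G_{ie} r_e^{(2)}(t-d)} (and
#' symmetrically) enter the \eqn{s_{ee}} and \eqn{s_{ie}} equations.
#' Fixed-step RK4 with a ring-buffer history of the pyramidal rates;
#' delayed stage values are cubic-interpolated on the step grid, so the
#' step must divide the delay.  The initial history is the uncoupled
#' limit cycle, with circuit 2 phase-shifted by `initial_offset` (0 is an
#' invariant manifold of the exchange symmetry, so symmetry-breaking runs
#' need a non-zero offset).
#'
#' @param cycle A [find_limit_cycle()] of the uncoupled circuit (supplies
#'   parameters, drive and the history).
#' @param cross A [cross_coupling()] (strengths and delay d).
#' @param initial_offset Initial phase lead of circuit 2, in ms (default
#'   `0.05 * T`).
#' @param duration Integration time (ms).
#' @param step RK4 step (ms); must divide the delay (default 0.01).
#' @param store_every Keep every `store_every`-th step.
#' @param init Optional snapshot from a previous run (list with `state`,
#'   `hist1`, `hist2`), used to chain runs; overrides `initial_offset`.
#' @param pulse Optional square pulse: list with `circuit` (1 or 2),
#'   `target` (`"E"`/`"I"`), `amplitude`, `onset`, `duration`.
#'
#' @return An object of class `coupled_trajectory`: `t`, `states`
#'   (n x 16, circuit 1 then circuit 2, each in the mean-field ordering),
#'   `delay`, `step`, and the end-of-run history (`hist1`, `hist2`,
#'   covering `[t_end - d, t_end]`) for chaining.
#' @export
simulate_coupled_reduced <- function(cycle, cross, initial_offset = NULL,
                                     duration, step = 0.01, store_every = 1L,
                                     init = NULL, pulse = NULL) {
  stopifnot(inherits(cycle, "limit_cycle"), inherits(cross, "cross_coupling"))
  d <- cross$delay
  nd <- as.integer(round(d / step))
  if (d > 0 && abs(nd * step - d) > 1e-9 * max(1, d))
    stop("configuration error: 'step' must divide the delay")
  if (d > 0 && nd < 2)
    stop("configuration error: the delay must span at least two steps")
  T <- cycle$period

  if (is.null(init)) {
    offset <- initial_offset %||% (0.05 * T)
    re_fun <- periodic_interp(cycle$states[, "r_e"], T)
    state_at <- function(ph) {
      idx <- (round(ph / T * cycle$n_samples) %% cycle$n_samples) + 1
      cycle$states[idx, ]
    }
    y0 <- c(state_at(0), state_at(offset))
    ht <- if (nd > 0) (-nd:0) * step else 0
    hist1 <- re_fun(ht)
    hist2 <- re_fun(ht + offset)
  } else {
    y0 <- init$state
    hist1 <- init$hist1
    hist2 <- init$hist2
    if (nd > 0 && (length(hist1) != nd + 1 || length(hist2) != nd + 1))
      stop("configuration error: snapshot history does not match the delay/step")
  }

  nsteps <- ceiling(duration / step)
  store_every <- max(1L, as.integer(store_every))
  nsteps <- as.integer(ceiling(nsteps / store_every) * store_every)

  pv <- c(0, 0, 0, 0, 0)
  if (!is.null(pulse)) {
    circ <- pulse$circuit %||% 1
    pv <- c(circ, if (toupper(pulse$target %||% "E") == "E") 1 else 2,
            pulse$amplitude %||% 1, pulse$onset %||% 0,
            pulse$duration %||% 0.1)
  }

  m <- dde_integrate_cpp(as.numeric(y0),
                         pack_params(cycle$e_params, cycle$i_params,
                                     cycle$couplings),
                         cycle$drive_values[1], cycle$drive_values[2],
                         cross$g_ee, cross$g_ie, nd,
                         hist1, hist2, 0, nsteps, step, store_every, pv)
  structure(list(t = m[, 1], states = m[, -1, drop = FALSE],
                 delay = d, step = step, period_hint = T,
                 hist1 = attr(m, "re1_tail"), hist2 = attr(m, "re2_tail"),
                 cross = cross),
            class = "coupled_trajectory")
}

#' @export
print.coupled_trajectory <- function(x, ...) {
  cat(sprintf("Coupled reduced trajectory: %d samples over %.1f ms, delay %g ms\n",
              length(x$t), max(x$t) - min(x$t), x$delay))
  invisible(x)
}

#' Simulate two delay-coupled spiking networks
#'
#' Twin finite-size QIF E-I networks with symmetric cross projections
#' from the pyramidal cells only: a spike of an E-cell of one circuit
#' increments, after the conduction delay d, the partner circuit's
#' `s_ee` and `s_ie` by \eqn{G_{ee}/(N_e\tau_s)} and
#' \eqn{G_{ie}/(N_e\tau_s)}.  A ring of per-step E-spike counts carries
#' the in-flight delayed spikes.  Both circuits share the quenched
#' heterogeneity (identical circuits); initial voltages differ by seed,
#' which seeds the symmetry breaking.
#'
#' @param e_params,i_params,couplings As in
#'   [simulate_spiking_network()].
#' @param cross A [cross_coupling()].
#' @param drive_values Constant drive `c(i_ext_e, i_ext_i)` shared by the
#'   circuits.
#' @param duration,step,seed As in [simulate_spiking_network()].
#' @param initial_offset Optional initial phase offset (ms) between the
#'   circuits: each circuit is warm-started from an uncoupled run of the
#'   same network, with circuit 2's snapshot taken `initial_offset` ms
#'   earlier in its rhythm.  `NULL` (default) starts both circuits from
#'   independently jittered rest voltages (near-zero initial lag).
#' @param warmup Length of the uncoupled warm-up run (ms) used when
#'   `initial_offset` is given (default 120).
#' @param cutoff_correction As in [simulate_spiking_network()].
#' @param rate_bin,rate_sigma Rate-estimation controls.
#'
#' @return A list with `raster1`, `raster2` (class `spike_raster`),
#'   `rates1`, `rates2` (class `rate_trace`).
#' @export
simulate_coupled_spiking <- function(e_params, i_params, couplings, cross,
                                     drive_values, duration, step = 0.01,
                                     seed = NULL, initial_offset = NULL,
                                     warmup = 120, cutoff_correction = TRUE,
                                     rate_bin = 0.5, rate_sigma = 1) {
  stopifnot(inherits(cross, "cross_coupling"))
  nd <- as.integer(round(cross$delay / step))
  if (cross$delay > 0 && abs(nd * step - cross$delay) > 1e-9)
    stop("configuration error: 'step' must divide the delay")
  if (!is.null(seed)) set.seed(seed)
  eta_e <- sample_lorentzian(e_params$eta_bar, e_params$delta, e_params$n)
  eta_i <- sample_lorentzian(i_params$eta_bar, i_params$delta, i_params$n)
  jitter <- function(n) stats::runif(n, -1, 1)
  par <- pack_params(e_params, i_params, couplings)
  nre <- n_refractory(e_params, step, cutoff_correction)
  nri <- n_refractory(i_params, step, cutoff_correction)
  s01 <- s02 <- c(0, 0, 0, 0)
  if (is.null(initial_offset)) {
    v0e1 <- rest_voltage(eta_e, drive_values[1]) + jitter(e_params$n)
    v0i1 <- rest_voltage(eta_i, drive_values[2]) + jitter(i_params$n)
    v0e2 <- rest_voltage(eta_e, drive_values[1]) + jitter(e_params$n)
    v0i2 <- rest_voltage(eta_i, drive_values[2]) + jitter(i_params$n)
  } else {
    # uncoupled warm-up; circuit 2 snapshot taken initial_offset earlier
    warm <- function(dur) {
      nst <- as.integer(ceiling(dur / step))
      spiking_net_cpp(eta_e, eta_i,
                      rest_voltage(eta_e, drive_values[1]) + jitter(e_params$n),
                      rest_voltage(eta_i, drive_values[2]) + jitter(i_params$n),
                      par, rep(drive_values[1], nst), rep(drive_values[2], nst),
                      step, c(0, 0, 0, 0), e_params$v_th, e_params$v_r,
                      nre, nri)
    }
    w1 <- warm(warmup + initial_offset)
    w2 <- warm(warmup)
    v0e1 <- w1$v_final_e; v0i1 <- w1$v_final_i; s01 <- w1$s_final
    v0e2 <- w2$v_final_e; v0i2 <- w2$v_final_i; s02 <- w2$s_final
  }
  nsteps <- as.integer(ceiling(duration / step))
  res <- coupled_spiking_cpp(eta_e, eta_i, eta_e, eta_i,
                             v0e1, v0i1, v0e2, v0i2,
                             par, drive_values[1], drive_values[2],
                             cross$g_ee, cross$g_ie, nd, step, nsteps,
                             e_params$v_th, e_params$v_r, s01, s02, nre, nri)
  win <- c(0, nsteps * step)
  mk_raster <- function(te, ide, ti, idi) {
    structure(list(t_e = te, id_e = ide, t_i = ti, id_i = idi,
                   n_e = e_params$n, n_i = i_params$n, window = win),
              class = "spike_raster")
  }
  r1 <- mk_raster(res$t_e1, res$id_e1, res$t_i1, res$id_i1)
  r2 <- mk_raster(res$t_e2, res$id_e2, res$t_i2, res$id_i2)
  list(raster1 = r1, raster2 = r2,
       rates1 = estimate_rate(r1, rate_bin, rate_sigma),
       rates2 = estimate_rate(r2, rate_bin, rate_sigma))
}

#' Phase lag between two oscillating rate traces
#'
#' Circular mean of per-cycle differences between the `r_e` peak times of
#' the two circuits, mapped to \eqn{(-T/2, T/2]}.  Positive lag means
#' circuit 2 peaks after circuit 1 (circuit 1 leads).  The circular
#' standard deviation is attached as a quality measure.
#'
#' @param x Either a `coupled_trajectory`, or a `rate_trace` (then `y`
#'   must be the second circuit's trace).
#' @param y Second `rate_trace` when `x` is one.
#' @param period Oscillation period; estimated from circuit 1's peak
#'   intervals when `NULL`.
#' @param window Analysis window `c(t_min, t_max)`; default the last ten
#'   estimated cycles.
#'
#' @return A list `lag` (ms in `(-T/2, T/2]`), `period`, `circ_sd`,
#'   `n_cycles`.
#' @export
extract_phase_lag <- function(x, y = NULL, period = NULL, window = NULL) {
  if (inherits(x, "coupled_trajectory")) {
    t <- x$t; re1 <- x$states[, 1]; re2 <- x$states[, 9]
  } else {
    stopifnot(inherits(x, "rate_trace"), inherits(y, "rate_trace"))
    t <- x$t; re1 <- x$r_e; re2 <- y$r_e
  }
  p1 <- find_peaks(t, re1)
  p2 <- find_peaks(t, re2)
  if (length(p1) < 3 || length(p2) < 3)
    stop("insufficient-oscillation: too few rate peaks to extract a lag")
  T <- period %||% stats::median(diff(p1))
  if (is.null(window)) window <- c(max(t) - 10 * T, max(t))
  p1 <- p1[p1 >= window[1] & p1 <= window[2]]
  p2full <- p2
  if (length(p1) < 3)
    stop("insufficient-oscillation: fewer than 3 cycles in the window")
  lags <- vapply(p1, function(tp) {
    wrap_half(p2full[which.min(abs(p2full - tp))] - tp, T)
  }, numeric(1))
  cm <- circ_mean_lag(lags, T)
  list(lag = cm$mean, period = T, circ_sd = cm$sd, n_cycles = length(p1))
}

#' Identify leader and follower circuits
#'
#' In a symmetry-broken locked state the two circuits fire in a galloping
#' rhythm: one fires after the long inter-burst silence (the leader) and
#' the other follows shortly after.  In-phase and anti-phase states carry
#' no such roles and are reported as degenerate.  Guard bands of `T/20`
#' around 0 and `T/2` separate the regimes.
#'
#' @inheritParams extract_phase_lag
#' @return A list with `leader`, `follower` (1 or 2, or `NA` when
#'   degenerate), `degenerate` (logical) and the extracted `lag`.
#' @export
identify_leader_follower <- function(x, y = NULL, period = NULL) {
  pl <- extract_phase_lag(x, y, period = period)
  T <- pl$period; lag <- pl$lag
  guard <- T / 20
  if (abs(lag) < guard || abs(lag) > T / 2 - guard)
    return(list(leader = NA_integer_, follower = NA_integer_,
                degenerate = TRUE, lag = lag, period = T))
  # positive lag: circuit 2 peaks shortly after circuit 1, so circuit 1
  # fires after the long silence and leads
  if (lag > 0) list(leader = 1L, follower = 2L, degenerate = FALSE,
                    lag = lag, period = T)
  else list(leader = 2L, follower = 1L, degenerate = FALSE,
            lag = lag, period = T)
}

#' Settle the coupled reduced system into a locked state
#'
#' Runs the delay-coupled reduced system until the phase lag is
#' stationary, returning a snapshot (state + delayed-rate history) from
#' which global-PRC runs can be chained, together with the locked lag,
#' the period and the leader/follower identities.
#'
#' @inheritParams simulate_coupled_reduced
#' @param settle_cycles Cycles to integrate before testing stationarity
#'   (default 300; convergence is slow under weak coupling).
#' @param lag_tol Stationarity tolerance on the lag over the last ten
#'   cycles, as a fraction of T (default 1/100).
#'
#' @return A list of class `locked_state`: `snapshot` (for
#'   `simulate_coupled_reduced(init = )`), `lag`, `period`, `leader`,
#'   `follower`, `degenerate`, `cycle`, `cross`.
#' @export
settle_locked_state <- function(cycle, cross, initial_offset = NULL,
                                settle_cycles = 300, step = 0.01,
                                lag_tol = 0.01) {
  T <- cycle$period
  tr <- simulate_coupled_reduced(cycle, cross, initial_offset,
                                 duration = settle_cycles * T, step = step,
                                 store_every = max(1L, round(0.1 / step)))
  pl <- extract_phase_lag(tr, period = T)
  if (pl$circ_sd > lag_tol * T)
    stop("locked state not reached: lag still drifting after settling")
  lf <- identify_leader_follower(tr, period = T)
  list(snapshot = list(state = tr$states[nrow(tr$states), ],
                       hist1 = tr$hist1, hist2 = tr$hist2),
       lag = pl$lag, period = T, leader = lf$leader, follower = lf$follower,
       degenerate = lf$degenerate, cycle = cycle, cross = cross,
       step = step)
}

#' Global phase-resetting curve of the locked two-circuit system
#'
#' In a phase-locked state the joint spiking rhythm of the two circuits
#' is periodic, so a global phase can be defined and reset.  A square
#' current pulse is applied to one circuit (leader or follower, E- or
#' I-cells) at each onset phase; after `n_cycles_post` cycles the shift
#' of circuit 1's `r_e` peak times against an unperturbed reference is
#' measured (radians, advance positive), and the system is checked to
#' have re-locked to the same lag (within `T/50`); samples that re-lock
#' to a different mode — a strong enough pulse can swap the leader and
#' follower roles — are flagged `mode_switch` and excluded from the
#' curve.  The asymmetry between leader-evoked and follower-evoked
#' curves is the package's footprint of directional signal transfer.
#'
#' @param locked A [settle_locked_state()] result.
#' @param target_circuit `"leader"`, `"follower"`, or a circuit index
#'   (1/2; required when the locked state is degenerate).
#' @param target_population `"E"` or `"I"`.
#' @param pulse List with `amplitude` (default 1) and `duration` (ms,
#'   default 0.1).
#' @param phase_grid Onset phases (radians in `[0, 2*pi)`), relative to a
#'   circuit-1 `r_e` peak.
#' @param n_cycles_post Cycles between pulse and shift measurement
#'   (default 30).
#'
#' @return A data.frame of class `global_prc`: `phase`, `shift_rad`,
#'   `target_circuit`, `target_population`, `mode_switch`; attributes
#'   `lag` (the baseline lag) and `period`.
#' @export
global_prc <- function(locked, target_circuit = "leader",
                       target_population = c("E", "I"),
                       pulse = list(amplitude = 1, duration = 0.1),
                       phase_grid = seq(0, 2 * pi, length.out = 17)[-17],
                       n_cycles_post = 30) {
  target_population <- match.arg(target_population)
  T <- locked$period
  circ <- if (is.numeric(target_circuit)) as.integer(target_circuit)
          else switch(target_circuit,
                      leader = locked$leader, follower = locked$follower,
                      stop("unknown target circuit"))
  if (is.na(circ))
    stop("degenerate locked state: specify target_circuit = 1 or 2")

  dur <- (n_cycles_post + 8) * T
  run <- function(pl) {
    simulate_coupled_reduced(locked$cycle, locked$cross, duration = dur,
                             step = locked$step,
                             store_every = max(1L, round(0.02 / locked$step)),
                             init = locked$snapshot, pulse = pl)
  }
  ref <- run(NULL)
  ref_peaks <- find_peaks(ref$t, ref$states[, 1])
  anchor <- ref_peaks[ref_peaks > 2 * T][1]

  rows <- lapply(phase_grid, function(ph) {
    on <- anchor + ph / (2 * pi) * T
    tr <- run(list(circuit = circ, target = target_population,
                   amplitude = pulse$amplitude %||% 1,
                   duration = pulse$duration %||% 0.1, onset = on))
    pk <- find_peaks(tr$t, tr$states[, 1])
    shift <- tryCatch(peak_shift(ref_peaks, pk, T, n_last = 5,
                                 settle_tol = Inf),
                      error = function(e) NA_real_)
    pl_new <- tryCatch(extract_phase_lag(tr, period = T),
                       error = function(e) NULL)
    switched <- is.null(pl_new) ||
      abs(wrap_half(pl_new$lag - locked$lag, T)) > T / 50
    data.frame(phase = ph,
               shift_rad = if (switched) NA_real_ else 2 * pi * shift / T,
               target_circuit = circ,
               target_population = target_population,
               mode_switch = switched)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "lag") <- locked$lag
  attr(out, "period") <- T
  class(out) <- c("global_prc", class(out))
  out
}
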