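#' Vector field of the exact mean-field reduction
#'
#' Right-hand side of the eight-dimensional reduced E-I system obtained
#' from the Lorentzian ansatz.  For each population,
#' \deqn{\tau \dot r = \Delta/(\pi\tau) + 2 r V, \qquad
#'       \tau \dot V = V^2 + \bar\eta + I - \tau^2\pi^2 r^2,}
#' with total currents \eqn{I_e = I^{ext}_e + \tau_e s_{ee} - \tau_e
#' s_{ei}} and \eqn{I_i = I^{ext}_i + \tau_i s_{ie} - \tau_i s_{ii}}, and
#' first-order synapses \eqn{\tau_s \dot s_{\alpha\beta} =
#' -s_{\alpha\beta} + J_{\alpha\beta} r_\beta}.  The state ordering is
#' `(r_e, V_e, s_ee, s_ei, r_i, V_i, s_ie, s_ii)`.
#'
#' @param state Numeric state vector of length 8.
#' @param e_params,i_params [population_params()].
#' @param couplings [synaptic_couplings()].
#' @param drive_values Length-2 numeric `c(i_ext_e, i_ext_i)`.
#'
#' @return The state derivative (length 8).
#' @export
mf_vector_field <- function(state, e_params, i_params, couplings,
                            drive_values = c(0, 0)) {
  stopifnot(length(state) == 8L, length(drive_values) == 2L)
  te <- e_params$tau; ti <- i_params$tau; ts <- couplings$tau_s
  re <- state[1]; Ve <- state[2]; see <- state[3]; sei <- state[4]
  ri <- state[5]; Vi <- state[6]; sie <- state[7]; sii <- state[8]
  Ie <- drive_values[1] + te * see - te * sei
  Ii <- drive_values[2] + ti * sie - ti * sii
  c((e_params$delta / (pi * te) + 2 * re * Ve) / te,
    (Ve^2 + e_params$eta_bar + Ie - te^2 * pi^2 * re^2) / te,
    (-see + couplings$j_ee * re) / ts,
    (-sei + couplings$j_ei * ri) / ts,
    (i_params$delta / (pi * ti) + 2 * ri * Vi) / ti,
    (Vi^2 + i_params$eta_bar + Ii - ti^2 * pi^2 * ri^2) / ti,
    (-sie + couplings$j_ie * re) / ts,
    (-sii + couplings$j_ii * ri) / ts)
}

mf_state_names <- c("r_e", "V_e", "s_ee", "s_ei", "r_i", "V_i", "s_ie", "s_ii")

#' Integrate the reduced E-I system
#'
#' Fixed-step 4th-order Runge-Kutta integration of the mean-field system,
#' with piecewise-constant external drive and an optional square current
#' pulse on one population (used by the direct phase-resetting method).
#'
#' @inheritParams mf_vector_field
#' @param initial Initial state (length 8); defaults to a low-activity
#'   state consistent with the drive at time 0.
#' @param drive A [drive_protocol()], or a length-2 numeric treated as a
#'   constant drive.
#' @param duration Integration time (ms).
#' @param step Integration step (ms, default 0.01).
#' @param store_every Keep every `store_every`-th step (default 1).
#' @param t0 Initial time (default 0).
#' @param pulse Optional square pulse, a list with `target` (`"E"` or
#'   `"I"`), `amplitude`, `onset` and `duration` (ms).
#'
#' @return A `mf_trajectory`: data.frame-like list with `t` and the eight
#'   state columns.
#' @export
integrate_mf <- function(initial = NULL, e_params, i_params, couplings,
                         drive = c(0, 0), duration, step = 0.01,
                         store_every = 1L, t0 = 0, pulse = NULL) {
  if (is.numeric(drive)) drive <- constant_drive(drive[1],
                                                 if (length(drive) > 1) drive[2] else 0)
  stopifnot(inherits(drive, "drive_protocol"))
  if (!is.finite(step) || step <= 0) stop("'step' must be > 0")
  if (is.null(initial)) {
    dv0 <- drive_value(drive, t0)
    initial <- mf_rest_guess(e_params, i_params, couplings, dv0)
  }
  stopifnot(length(initial) == 8L)
  nsteps <- ceiling(duration / step)
  store_every <- max(1L, as.integer(store_every))
  nsteps <- as.integer(ceiling(nsteps / store_every) * store_every)
  pv <- pulse_vec(pulse)
  m <- mf_integrate_cpp(as.numeric(initial),
                        pack_params(e_params, i_params, couplings),
                        drive$start - t0, drive$i_ext_e, drive$i_ext_i,
                        0, nsteps, step, store_every, pv)
  colnames(m) <- c("t", mf_state_names)
  m[, "t"] <- m[, "t"] + t0
  structure(list(t = m[, 1], states = m[, -1, drop = FALSE], step = step),
            class = "mf_trajectory")
}

pulse_vec <- function(pulse) {
  if (is.null(pulse)) return(c(0, 0, 0, 0))
  target <- match.arg(toupper(pulse$target %||% "E"), c("E", "I"))
  dur <- pulse$duration %||% 0.1
  if (!is.finite(dur) || dur <= 0) stop("pulse duration must be > 0")
  c(if (target == "E") 1 else 2, pulse$amplitude %||% 1,
    pulse$onset %||% 0, dur)
}

# crude low-activity initial state
mf_rest_guess <- function(e_params, i_params, couplings, drive_values) {
  r0 <- 0.01
  c(r0, -e_params$delta / (2 * pi * e_params$tau * r0),
    couplings$j_ee * r0, couplings$j_ei * r0,
    r0, -i_params$delta / (2 * pi * i_params$tau * r0),
    couplings$j_ie * r0, couplings$j_ii * r0)
}

#' Fixed point of the reduced system and its linear stability
#'
#' Finds a root of the mean-field vector field by damped Newton iteration
#' using the analytic Jacobian ([linearization_matrix()]).  At any fixed
#' point the rate equation gives the identity \eqn{V^* =
#' -\Delta/(2\pi\tau r^*)} and the synapse equations give
#' \eqn{s_{\alpha\beta}^* = J_{\alpha\beta} r_\beta^*}, which the
#' multi-start fallback exploits: a grid of rate pairs, plus trajectory
#' endpoints after a transient, seed the iteration when the supplied guess
#' fails.
#'
#' @inheritParams mf_vector_field
#' @param guess Optional initial state (length 8).
#' @param tol Residual tolerance (max-norm, default 1e-12).
#'
#' @return A list of class `mf_fixed_point`: `state`, `eigenvalues`
#'   (complex, length 8), `stable` (all real parts < 0), `marginal`
#'   (leading |Re| below 1e-8), `residual`.
#' @export
find_fixed_point <- function(e_params, i_params, couplings,
                             drive_values = c(0, 0), guess = NULL,
                             tol = 1e-12) {
  F <- function(x) mf_vector_field(x, e_params, i_params, couplings, drive_values)
  J <- function(x) linearization_matrix(x, e_params, i_params, couplings)

  newton <- function(x) {
    for (it in 1:100) {
      fx <- F(x)
      if (max(abs(fx)) < tol) return(x)
      dx <- tryCatch(solve(J(x), fx), error = function(e) NULL)
      if (is.null(dx) || !all(is.finite(dx))) return(NULL)
      lam <- 1
      repeat {
        xn <- x - lam * dx
        if (xn[1] > 0 && xn[5] > 0 &&
            all(is.finite(xn)) && max(abs(F(xn))) < max(abs(fx)) * (1 - 0.25 * lam))
          break
        lam <- lam / 2
        if (lam < 1e-6) { xn <- x - 1e-6 * dx; break }
      }
      if (max(abs(xn - x)) < 1e-15 * max(1, max(abs(x)))) { x <- xn; break }
      x <- xn
    }
    fx <- F(x)
    if (max(abs(fx)) < 1e-10) x else NULL
  }

  starts <- list()
  if (!is.null(guess)) starts <- c(starts, list(as.numeric(guess)))
  for (rr in c(0.002, 0.01, 0.05, 0.2, 1)) {
    st <- c(rr, -e_params$delta / (2 * pi * e_params$tau * rr),
            couplings$j_ee * rr, couplings$j_ei * rr,
            rr, -i_params$delta / (2 * pi * i_params$tau * rr),
            couplings$j_ie * rr, couplings$j_ii * rr)
    starts <- c(starts, list(st))
  }

  root <- NULL
  for (s in starts) {
    root <- newton(s)
    if (!is.null(root)) break
  }
  if (is.null(root)) {
    # fallback: trajectory endpoints after a transient (useful near
    # bistability, where the grid of ansatz states may miss the basin)
    traj <- tryCatch(
      integrate_mf(NULL, e_params, i_params, couplings, drive_values,
                   duration = 200, step = 0.02, store_every = 500),
      error = function(e) NULL)
    if (!is.null(traj)) {
      idx <- unique(round(seq(nrow(traj$states) / 2, nrow(traj$states),
                              length.out = 8)))
      for (i in idx) {
        root <- newton(traj$states[i, ])
        if (!is.null(root)) break
      }
    }
  }
  if (is.null(root))
    stop("root-not-found: Newton iteration failed from the guess and the multi-start grid")

  ev <- eigen(J(root), only.values = TRUE)$values
  remax <- max(Re(ev))
  structure(list(state = stats::setNames(root, mf_state_names),
                 eigenvalues = ev,
                 stable = remax < 0,
                 marginal = abs(remax) < 1e-8,
                 residual = max(abs(F(root))),
                 drive_values = drive_values),
            class = "mf_fixed_point")
}

#' Locate the stable limit cycle of the reduced system
#'
#' Integrates past a transient, then locates the periodic orbit by a
#' Poincare section: upward crossings of `r_e` through its time mean.
#' Crossing times are refined with a cubic Hermite fit inside the
#' integration step, and the period is accepted when successive return
#' times agree to relative `period_tol`.  The orbit is then integrated
#' once more and resampled on `n_samples` uniform phase points, with the
#' phase origin placed at the maximum of `r_e`.
#'
#' @inheritParams mf_vector_field
#' @param n_samples Samples per period (default 1024; the quadrature grid
#'   of the interaction-function machinery).
#' @param step Integration step (ms).
#' @param transient Transient to discard (ms, default 600).
#' @param max_time Give up after this much additional time (ms).
#' @param period_tol Relative agreement of successive return times.
#' @param initial Optional starting state.
#'
#' @return An object of class `limit_cycle`: `period`, `t` (phase-time
#'   grid, length `n_samples`), `states` (`n_samples` x 8 matrix),
#'   `closure_residual` (relative, max-norm), plus the generating
#'   parameters.  Errors with "no-cycle" when the trajectory settles to a
#'   fixed point.
#' @export
find_limit_cycle <- function(e_params, i_params, couplings,
                             drive_values = c(0, 0), n_samples = 1024L,
                             step = 0.01, transient = 600, max_time = 4000,
                             period_tol = 1e-6, initial = NULL) {
  par <- pack_params(e_params, i_params, couplings)
  F <- function(x) mf_vector_field(x, e_params, i_params, couplings, drive_values)

  tr <- integrate_mf(initial, e_params, i_params, couplings, drive_values,
                     duration = transient, step = step)
  y <- tr$states[nrow(tr$states), ]

  # integrate in windows, collecting refined section crossings
  crossings <- numeric(0)
  cross_states <- list()
  t_accum <- 0
  level <- NA_real_
  repeat {
    w <- integrate_mf(y, e_params, i_params, couplings, drive_values,
                      duration = 250, step = step, t0 = t_accum)
    re <- w$states[, 1]
    if (max(re) - min(re) < 1e-8)
      stop("no-cycle: trajectory converged to a fixed point")
    level <- mean(re)
    up <- which(re[-length(re)] < level & re[-1] >= level)
    for (k in up) {
      t1 <- w$t[k]; y1 <- w$states[k, ]; y2 <- w$states[k + 1, ]
      tc <- hermite_crossing(t1, step, y1[1], y2[1], F(y1)[1], F(y2)[1], level)
      # state at the crossing: one partial RK4 step from y1
      ys <- rk4_partial(y1, tc - t1, e_params, i_params, couplings, drive_values)
      crossings <- c(crossings, tc)
      cross_states <- c(cross_states, list(ys))
    }
    y <- w$states[nrow(w$states), ]
    t_accum <- t_accum + 250
    nc <- length(crossings)
    if (nc >= 4) {
      per <- diff(crossings)
      m <- length(per)
      if (abs(per[m] - per[m - 1]) < period_tol * per[m]) break
    }
    if (t_accum > max_time)
      stop("no-cycle: section returns did not settle within the time budget")
  }

  T <- crossings[length(crossings)] - crossings[length(crossings) - 1]
  y0 <- cross_states[[length(cross_states)]]

  # one clean period sampled on exactly n_samples points
  n_samples <- as.integer(n_samples)
  hs <- T / n_samples
  m <- mf_integrate_cpp(y0, par, 0, drive_values[1], drive_values[2],
                        0, n_samples, hs, 1L, c(0, 0, 0, 0))
  states <- m[1:n_samples, -1, drop = FALSE]
  yT <- m[n_samples + 1, -1]
  amp <- apply(states, 2, function(col) max(col) - min(col))
  closure <- max(abs(yT - states[1, ]) / pmax(amp, 1e-12))

  # phase origin at the r_e maximum
  imax <- which.max(states[, 1])
  if (imax > 1L) states <- states[c(imax:n_samples, 1:(imax - 1L)), , drop = FALSE]
  colnames(states) <- mf_state_names

  structure(list(period = T, t = (0:(n_samples - 1)) * hs, states = states,
                 closure_residual = closure, n_samples = n_samples,
                 e_params = e_params, i_params = i_params,
                 couplings = couplings, drive_values = drive_values,
                 step = step),
            class = "limit_cycle")
}

# cubic Hermite root for the section crossing inside one step
hermite_crossing <- function(t1, h, y1, y2, d1, d2, level) {
  g <- function(u) {
    h00 <- (1 + 2 * u) * (1 - u)^2; h10 <- u * (1 - u)^2
    h01 <- u^2 * (3 - 2 * u); h11 <- u^2 * (u - 1)
    h00 * y1 + h10 * h * d1 + h01 * y2 + h11 * h * d2 - level
  }
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
  }
  t1 + h * (lo + hi) / 2
}

rk4_partial <- function(y, h, e_params, i_params, couplings, drive_values) {
  if (h <= 0) return(y)
  F <- function(x) mf_vector_field(x, e_params, i_params, couplings, drive_values)
  k1 <- F(y); k2 <- F(y + h / 2 * k1); k3 <- F(y + h / 2 * k2); k4 <- F(y + h * k3)
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat(sprintf("Limit cycle: T = %.4f ms (f = %.2f Hz), %d samples, closure residual %.2e\n",
              x$period, 1000 / x$period, x$n_samples, x$closure_residual))
  invisible(x)
}

#' One-parameter bifurcation scan of the reduced system
#'
#' For each value of the scan parameter the fixed point is tracked (warm
#' starting from the previous root), its eigenvalues computed, and, where
#' the fixed point is unstable through a complex pair, the attracting
#' limit cycle's `r_e`/`r_i` extrema are measured from a settled
#' trajectory.  This reproduces the standard Hopf diagrams of the
#' PING/ING rhythms: a steady branch losing stability as the drive is
#' raised, or the rhythm dying as the heterogeneity grows.
#'
#' @inheritParams mf_vector_field
#' @param scan One of `"i_ext_e"`, `"i_ext_i"`, `"i_ext_both"`, `"delta"`
#'   (sets both populations' half-widths).
#' @param values Sorted numeric grid of scan values.
#' @param drive_values Baseline drive, overridden on the scanned entries.
#'
#' @return A data.frame with one row per grid value: `value`, the
#'   fixed-point state columns, `re_lambda`, `im_lambda` (leading pair),
#'   `stable`, `marginal`, `oscillatory` (complex unstable pair), cycle
#'   extrema `rmin_e`, `rmax_e`, `rmin_i`, `rmax_i` (NA on stable rows)
#'   and `ok` (root solve succeeded).
#' @export
bifurcation_scan_1d <- function(e_params, i_params, couplings,
                                drive_values = c(0, 0),
                                scan = c("i_ext_e", "i_ext_i", "i_ext_both",
                                         "delta"),
                                values) {
  scan <- match.arg(scan)
  if (is.unsorted(values)) stop("'values' grid must be sorted")
  rows <- vector("list", length(values))
  guess <- NULL
  for (k in seq_along(values)) {
    v <- values[k]
    ep <- e_params; ip <- i_params; dv <- drive_values
    switch(scan,
           i_ext_e = { dv[1] <- v },
           i_ext_i = { dv[2] <- v },
           i_ext_both = { dv[1] <- v; dv[2] <- v },
           delta = { ep$delta <- v; ip$delta <- v })
    fp <- tryCatch(find_fixed_point(ep, ip, couplings, dv, guess = guess),
                   error = function(e) NULL)
    if (is.null(fp)) {
      rows[[k]] <- data.frame(value = v, r_e = NA, V_e = NA, r_i = NA, V_i = NA,
                              re_lambda = NA, im_lambda = NA, stable = NA,
                              marginal = NA, oscillatory = NA,
                              rmin_e = NA, rmax_e = NA, rmin_i = NA, rmax_i = NA,
                              ok = FALSE)
      next
    }
    guess <- fp$state
    lead <- fp$eigenvalues[which.max(Re(fp$eigenvalues))]
    osc <- !fp$stable && abs(Im(lead)) > 1e-8
    ext <- c(NA, NA, NA, NA)
    if (osc) {
      tr <- tryCatch(
        integrate_mf(fp$state + 1e-3, ep, ip, couplings, dv,
                     duration = 700, step = 0.02),
        error = function(e) NULL)
      if (!is.null(tr)) {
        tail_idx <- tr$t > 400
        ext <- c(min(tr$states[tail_idx, 1]), max(tr$states[tail_idx, 1]),
                 min(tr$states[tail_idx, 5]), max(tr$states[tail_idx, 5]))
      }
    }
    rows[[k]] <- data.frame(value = v,
                            r_e = fp$state[1], V_e = fp$state[2],
                            r_i = fp$state[5], V_i = fp$state[6],
                            re_lambda = Re(lead), im_lambda = Im(lead),
                            stable = fp$stable, marginal = fp$marginal,
                            oscillatory = osc,
                            rmin_e = ext[1], rmax_e = ext[2],
                            rmin_i = ext[3], rmax_i = ext[4], ok = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scan") <- scan
  out
}

#' Oscillation map over drive and heterogeneity
#'
#' Classifies every (drive, heterogeneity) grid point as oscillatory
#' (fixed point unstable through a complex eigenvalue pair) or not.
#'
#' @inheritParams bifurcation_scan_1d
#' @param drive_grid Sorted external drive values (applied per
#'   `drive_target`).
#' @param delta_grid Sorted heterogeneity half-widths (both populations).
#' @param drive_target `"e"` (PING convention), `"i"`, or `"both"` (ING
#'   convention).
#'
#' @return A logical matrix `length(drive_grid)` x `length(delta_grid)`
#'   with dimnames giving the grids; `TRUE` marks oscillation.  Grid
#'   points where the root search fails are `NA`.
#' @export
stability_region <- function(e_params, i_params, couplings,
                             drive_grid, delta_grid,
                             drive_target = c("e", "i", "both"),
                             drive_values = c(0, 0)) {
  drive_target <- match.arg(drive_target)
  if (is.unsorted(drive_grid) || is.unsorted(delta_grid))
    stop("grids must be sorted")
  out <- matrix(NA, length(drive_grid), length(delta_grid),
                dimnames = list(signif(drive_grid, 8), signif(delta_grid, 8)))
  for (j in seq_along(delta_grid)) {
    ep <- e_params; ip <- i_params
    ep$delta <- delta_grid[j]; ip$delta <- delta_grid[j]
    guess <- NULL
    for (i in seq_along(drive_grid)) {
      dv <- drive_values
      if (drive_target %in% c("e", "both")) dv[1] <- drive_grid[i]
      if (drive_target %in% c("i", "both")) dv[2] <- drive_grid[i]
      fp <- tryCatch(find_fixed_point(ep, ip, couplings, dv, guess = guess),
                     error = function(e) NULL)
      if (is.null(fp)) next
      guess <- fp$state
      lead <- fp$eigenvalues[which.max(Re(fp$eigenvalues))]
      out[i, j] <- !fp$stable && abs(Im(lead)) > 1e-8
    }
  }
  out
}
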