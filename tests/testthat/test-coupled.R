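test_that("uncoupled pair reproduces the single-circuit trajectory", {
  cyc <- ping_cycle()
  cr <- cross_coupling(0, 0, 0)
  tr <- simulate_coupled_reduced(cyc, cr, initial_offset = 0,
                                 duration = 30, step = 0.01)
  single <- integrate_mf(cyc$states[1, ], cyc$e_params, cyc$i_params,
                         cyc$couplings, cyc$drive_values,
                         duration = 30, step = 0.01)
  n <- min(length(tr$t), length(single$t))
  expect_lt(max(abs(tr$states[1:n, 1:8] - single$states[1:n, ])), 1e-12)
  # circuits 1 and 2 identical when started identically (exchange symmetry)
  expect_lt(max(abs(tr$states[, 1:8] - tr$states[, 9:16])), 1e-12)
})

test_that("zero lag is invariant under coupling at zero delay", {
  cyc <- ping_cycle()
  cr <- cross_coupling(0.1, 0.5, 0)
  tr <- simulate_coupled_reduced(cyc, cr, initial_offset = 0,
                                 duration = 20 * cyc$period, step = 0.01,
                                 store_every = 10)
  expect_lt(max(abs(tr$states[, 1] - tr$states[, 9])), 1e-10)
})

test_that("relabelling the circuits negates the lag and swaps roles", {
  cyc <- ping_cycle()
  T <- cyc$period
  cr <- cross_coupling(0.1, 0.5, 6.5)
  tr <- simulate_coupled_reduced(cyc, cr, initial_offset = 0.2 * T,
                                 duration = 150 * T, step = 0.01,
                                 store_every = 10)
  lag12 <- extract_phase_lag(tr, period = T)$lag
  # swapped construction: give circuit 1 the offset instead
  tr2 <- simulate_coupled_reduced(cyc, cr, initial_offset = -0.2 * T,
                                  duration = 150 * T, step = 0.01,
                                  store_every = 10)
  lag21 <- extract_phase_lag(tr2, period = T)$lag
  expect_equal(lag12, -lag21, tolerance = 0.02 * T)
})

test_that("phase-lag extraction is exact on synthetic traces", {
  t <- seq(0.25, 400, by = 0.5)
  T <- 20
  base <- 1 + 0.8 * sin(2 * pi * t / T)
  same <- extract_phase_lag(synthetic_trace(t, base),
                            synthetic_trace(t, base), period = T)
  expect_equal(same$lag, 0, tolerance = 1e-6)
  anti <- extract_phase_lag(synthetic_trace(t, base),
                            synthetic_trace(t, 1 + 0.8 * sin(2 * pi * (t - T / 2) / T)),
                            period = T)
  expect_equal(abs(anti$lag), T / 2, tolerance = 1e-6)
  quarter <- extract_phase_lag(synthetic_trace(t, base),
                               synthetic_trace(t, 1 + 0.8 * sin(2 * pi * (t - 5) / T)),
                               period = T)
  expect_equal(quarter$lag, 5, tolerance = 1e-6)
  expect_error(extract_phase_lag(synthetic_trace(t, rep(1, length(t))),
                                 synthetic_trace(t, base), period = T),
               "insufficient-oscillation")
})

test_that("leader/follower labels follow the long silence and swap with inputs", {
  t <- seq(0.25, 400, by = 0.5)
  T <- 20
  a <- synthetic_trace(t, 1 + 0.8 * sin(2 * pi * t / T))
  b <- synthetic_trace(t, 1 + 0.8 * sin(2 * pi * (t - 5) / T))  # peaks 5 ms later
  lf <- identify_leader_follower(a, b, period = T)
  expect_false(lf$degenerate)
  expect_identical(lf$leader, 1L)
  sw <- identify_leader_follower(b, a, period = T)
  expect_identical(sw$leader, 2L)
  expect_identical(sw$follower, 1L)
  # in-phase state carries no roles
  dg <- identify_leader_follower(a, a, period = T)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$leader))
})

test_that("delay configuration errors are caught", {
  cyc <- ping_cycle()
  expect_error(simulate_coupled_reduced(cyc, cross_coupling(0.1, 0.5, 6.005),
                                        duration = 10, step = 0.01),
               "divide the delay")
  expect_error(cross_coupling(0.1, 0.5, -1), "delay")
})

test_that("strong cross-coupling raises the extrapolation flag", {
  expect_false(cross_coupling(0.1, 0.5, 0)$extrapolated)
  expect_true(cross_coupling(0.1, 0.9, 0)$extrapolated)
})
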