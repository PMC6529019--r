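test_that("linearization matrix matches its closed-form entries", {
  pp <- figure_preset("fig2_ping")
  # at the origin only the synapse rows are populated
  M0 <- linearization_matrix(rep(0, 8), pp$e_params, pp$i_params, pp$couplings)
  ts <- pp$couplings$tau_s
  expect_equal(diag(M0)[c(3, 4, 7, 8)], rep(-1 / ts, 4),
               ignore_attr = TRUE)
  expect_equal(unname(M0[3, 1]), pp$couplings$j_ee / ts)
  expect_equal(unname(M0[4, 5]), pp$couplings$j_ei / ts)
  expect_equal(unname(M0[7, 1]), pp$couplings$j_ie / ts)
  expect_equal(unname(M0[8, 5]), pp$couplings$j_ii / ts)
  # direct substitution: row 2, column 1 is -2 tau pi^2 r_e
  st <- c(0.1, -0.4, 0, 0, 0.05, -0.6, 0, 0)
  M <- linearization_matrix(st, pp$e_params, pp$i_params, pp$couplings)
  expect_equal(unname(M[2, 1]), -2 * 10 * pi^2 * 0.1, tolerance = 1e-12)
  expect_equal(unname(M[2, 1]), -19.7392088, tolerance = 1e-6)
})

test_that("linearization matrix equals the finite-difference Jacobian", {
  pp <- figure_preset("fig2_ping")
  st <- c(0.12, -0.35, 0.3, 1.1, 0.07, -0.5, 1.4, 0.2)
  M <- linearization_matrix(st, pp$e_params, pp$i_params, pp$couplings)
  eps <- 1e-6
  J <- matrix(0, 8, 8)
  for (k in 1:8) {
    up <- st; up[k] <- up[k] + eps
    dn <- st; dn[k] <- dn[k] - eps
    J[, k] <- (mf_vector_field(up, pp$e_params, pp$i_params, pp$couplings, c(10, 0)) -
               mf_vector_field(dn, pp$e_params, pp$i_params, pp$couplings, c(10, 0))) /
      (2 * eps)
  }
  expect_lt(max(abs(M - J)), 1e-6)
})

test_that("adjoint solution is periodic and normalized along the cycle", {
  for (adj in list(ping_adjoint(), ing_adjoint())) {
    expect_lt(adj$periodicity_residual, 1e-6)
    expect_lt(adj$normalization_residual, 1e-3)
    # Z . Odot must be constant along the cycle (CoV below 1e-3)
    cyc <- adj$cycle
    Odot <- t(apply(cyc$states, 1, mf_vector_field, e_params = cyc$e_params,
                    i_params = cyc$i_params, couplings = cyc$couplings,
                    drive_values = cyc$drive_values))
    dots <- rowSums(adj$Z * Odot)
    expect_lt(stats::sd(dots) / mean(dots), 1e-3)
    expect_equal(mean(dots), 2 * pi / cyc$period, tolerance = 1e-10)
  }
})

test_that("interneuron-generated rhythm ignores pyramidal perturbations", {
  adj <- ing_adjoint()
  # with J_ee = J_ie = 0 the E-subsystem is a slave: its adjoint
  # components vanish
  e_cols <- c("Z_re", "Z_ve", "Z_see", "Z_sei")
  expect_lt(max(abs(adj$Z[, e_cols])), 1e-6 * max(abs(adj$Z[, "Z_vi"])))
})

test_that("PRC classification separates monophasic, biphasic and null curves", {
  expect_identical(classify_prc(c(0.1, 0.5, 0.2)), "type I")
  expect_identical(classify_prc(c(-0.1, 0.5, 0.2)), "type II")
  expect_identical(classify_prc(c(1e-9, -1e-9), noise_floor = 1e-6), "null")
})

test_that("zero-amplitude pulses shift nothing; shifts scale linearly", {
  cyc <- ping_cycle()
  grid <- c(0, pi / 2, pi, 3 * pi / 2)
  z <- direct_prc(cyc, list(target = "E", amplitude = 0, duration = 0.5),
                  phase_grid = grid, n_periods = 21)
  expect_lt(max(abs(z$shift_rad)), 1e-6)
  p1 <- direct_prc(cyc, list(target = "I", amplitude = 1, duration = 0.1),
                   phase_grid = grid, n_periods = 21)
  p05 <- direct_prc(cyc, list(target = "I", amplitude = 0.5, duration = 0.1),
                    phase_grid = grid, n_periods = 21)
  big <- abs(p1$shift_rad) > 1e-4
  expect_true(any(big))
  expect_lt(max(abs(p05$shift_rad[big] * 2 - p1$shift_rad[big]) /
                abs(p1$shift_rad[big])), 0.1)
})

test_that("direct shifts follow the adjoint voltage components", {
  cyc <- ping_cycle()
  adj <- ping_adjoint()
  grid <- seq(0, 2 * pi, length.out = 9)[-9]
  dp <- direct_prc(cyc, list(target = "E", amplitude = 1, duration = 0.1),
                   phase_grid = grid, n_periods = 22)
  zfun <- periodic_fun <- stats::approxfun(c(adj$t, adj$period),
                                           c(adj$Z[, "Z_ve"], adj$Z[1, "Z_ve"]))
  pred <- zfun(grid / (2 * pi) * adj$period) * 1 * 0.1 / cyc$e_params$tau
  expect_gt(stats::cor(dp$shift_rad, pred), 0.98)
})
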