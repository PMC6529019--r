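test_that("interaction function vanishes without coupling and is linear in it", {
  adj <- ping_adjoint(); cyc <- ping_cycle()
  h0 <- interaction_function(adj, cyc, cross = cross_coupling(0, 0, 0))
  expect_true(all(h0$H == 0))
  hee <- interaction_function(adj, cyc, cross = cross_coupling(1, 0, 0))
  hie <- interaction_function(adj, cyc, cross = cross_coupling(0, 1, 0))
  hmix <- interaction_function(adj, cyc, cross = cross_coupling(0.3, 0.7, 0))
  expect_equal(hmix$H, 0.3 * hee$H + 0.7 * hie$H, tolerance = 1e-12)
})

test_that("interaction function is converged at the working grid density", {
  pp <- figure_preset("fig2_ping")
  cyc512 <- find_limit_cycle(pp$e_params, pp$i_params, pp$couplings,
                             c(10, 0), n_samples = 512L)
  adj512 <- adjoint_iprc(cyc512)
  h512 <- interaction_function(adj512, cyc512,
                               cross = cross_coupling(0.1, 0.5, 0))
  h1024 <- ping_coupling()
  # compare on the coarse grid via the periodic interpolant of the fine H
  f <- gammalock:::periodic_interp(h1024$H, h1024$period)
  expect_lt(max(abs(h512$H - f(h512$theta))) / max(abs(h1024$H)), 1e-5)
})

test_that("grid mismatch between adjoint and cycle is rejected", {
  pp <- figure_preset("fig2_ping")
  cyc512 <- find_limit_cycle(pp$e_params, pp$i_params, pp$couplings,
                             c(10, 0), n_samples = 512L)
  expect_error(interaction_function(ping_adjoint(), cyc512,
                                    cross = cross_coupling(0.1, 0.5, 0)),
               "grid-mismatch")
})

test_that("coupling function identities hold at machine precision for all delays", {
  cf <- ping_coupling()
  T <- cf$period
  th <- seq(0, T / 2, length.out = 201)
  for (d in c(0, 2, 6, 7, 10)) {
    cfd <- coupling_function(cf, d)
    expect_lt(abs(cfd$G_fun(0)), 1e-10)
    expect_lt(abs(cfd$G_fun(T / 2)), 1e-10)
    # G is odd for every delay (not only d = 0)
    expect_lt(max(abs(cfd$G_fun(th) + cfd$G_fun(-th))) / max(abs(cfd$G)),
              1e-10)
  }
})

test_that("stable and unstable locking modes swap between zero and long delay", {
  cf <- ping_coupling()
  T <- cf$period
  lm0 <- locking_modes(coupling_function(cf, 0))
  z0 <- lm0[abs(lm0$theta_star) < 1e-6, ]
  zh0 <- lm0[abs(lm0$theta_star - T / 2) < 1e-6, ]
  expect_true(z0$stable)     # in-phase stable without delay
  expect_false(zh0$stable)   # anti-phase unstable without delay
  lm10 <- locking_modes(coupling_function(cf, 10))
  z10 <- lm10[abs(lm10$theta_star) < 1e-6, ]
  zh10 <- lm10[abs(lm10$theta_star - T / 2) < 1e-6, ]
  expect_false(z10$stable)
  expect_true(zh10$stable)
  # stabilities alternate around the circle
  for (lm in list(lm0, lm10)) {
    s <- lm$stable[order(lm$theta_star)]
    expect_true(all(s[-1] != s[-length(s)]))
  }
})

test_that("interneuron-rhythm locking modes are insensitive to coupling strengths", {
  adj <- ing_adjoint(); cyc <- ing_cycle()
  d <- 0.2
  z <- lapply(list(c(0, 0.3), c(0.2, 0.6), c(0.05, 0.1)), function(g) {
    cf <- coupling_function(
      interaction_function(adj, cyc, cross = cross_coupling(g[1], g[2], 0)), d)
    sort(locking_modes(cf)$theta_star)
  })
  expect_equal(z[[1]], z[[2]], tolerance = 1e-4)
  expect_equal(z[[1]], z[[3]], tolerance = 1e-4)
})

test_that("locking diagram has a symmetry-broken window and is delay-periodic", {
  cf <- ping_coupling()
  T <- cf$period
  bd <- locking_bifurcation(cf, "d", seq(0, 12, by = 0.25))
  st <- bd[bd$stable & !bd$marginal, ]
  inter <- st$value[st$theta_star > T / 20 & st$theta_star < T / 2 - T / 20]
  expect_gt(length(unique(inter)), 2)          # intermediate lags exist
  expect_true(all(diff(sort(unique(inter))) <= 0.25 + 1e-9))  # contiguous
  # one-value grid gives that value's modes only
  one <- locking_bifurcation(cf, "d", 6.5)
  expect_true(all(one$value == 6.5))
  # the diagram repeats with period T in the delay
  lm_a <- locking_modes(coupling_function(cf, 1))
  lm_b <- locking_modes(coupling_function(cf, 1 + T))
  expect_equal(sort(lm_a$theta_star), sort(lm_b$theta_star), tolerance = 1e-6)
  expect_identical(lm_a$stable[order(lm_a$theta_star)],
                   lm_b$stable[order(lm_b$theta_star)])
})
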