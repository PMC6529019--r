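quiet_pop <- function(n = 1L, eta = -5, delta = 0) {
  population_params(tau = 10, eta_bar = eta, delta = delta, n = n)
}
no_coupling <- synaptic_couplings(0, 0, 0, 0)

test_that("single QIF period matches the closed form pi*tau/sqrt(eta)", {
  # oracle: the infinite-cutoff QIF with eta = 1, tau = 10 fires every
  # pi * 10 / sqrt(1) ms
  sim <- simulate_spiking_network(quiet_pop(1, eta = 1), quiet_pop(1),
                                  no_coupling, constant_drive(0, 0),
                                  duration = 200, step = 1e-3)
  isi <- diff(sim$raster$t_e)
  expect_gt(length(isi), 3)
  expect_lt(max(abs(isi - pi * 10)) / (pi * 10), 0.01)
})

test_that("a fully sub-threshold network is silent", {
  sim <- simulate_spiking_network(quiet_pop(50), quiet_pop(50),
                                  no_coupling, constant_drive(0, 0),
                                  duration = 100, step = 0.01)
  expect_identical(length(sim$raster$t_e), 0L)
  expect_identical(length(sim$raster$t_i), 0L)
  expect_true(all(sim$rates$r_e == 0))
})

test_that("rate estimation conserves spike counts exactly", {
  mk_raster <- function(te, ti, ne, ni, win) {
    structure(list(t_e = te, id_e = seq_along(te), t_i = ti,
                   id_i = seq_along(ti), n_e = ne, n_i = ni, window = win),
              class = "spike_raster")
  }
  # empty raster -> all-zero trace
  r0 <- estimate_rate(mk_raster(numeric(0), numeric(0), 10, 10, c(0, 50)))
  expect_true(all(r0$r_e == 0) && all(r0$r_i == 0))
  # a single spike integrates to 1/N, for any bin width and smoothing
  for (bw in c(0.1, 0.5, 2)) {
    r1 <- estimate_rate(mk_raster(17.3, numeric(0), 100, 10, c(0, 50)),
                        bin_width = bw, smoothing_sigma = 1)
    expect_equal(sum(r1$r_e) * bw * 100, 1, tolerance = 1e-10)
  }
  # exact conservation for a large random raster
  set.seed(2)
  te <- sort(stats::runif(5000, 0, 200))
  ti <- sort(stats::runif(1500, 0, 200))
  rr <- estimate_rate(mk_raster(te, ti, 400, 100, c(0, 200)))
  expect_equal(sum(rr$r_e) * rr$bin_width * 400, 5000, tolerance = 1e-8)
  expect_equal(sum(rr$r_i) * rr$bin_width * 100, 1500, tolerance = 1e-8)
  expect_true(all(rr$r_e >= 0) && all(rr$r_i >= 0))
})

test_that("homogeneous spiking at a known rate is estimated unbiasedly", {
  # binomial counting oracle: N neurons firing as independent Poisson
  # processes at rho spikes/neuron/ms
  set.seed(5)
  rho <- 0.02; N <- 200; Tw <- 500
  nspk <- stats::rpois(1, rho * N * Tw)
  te <- sort(stats::runif(nspk, 0, Tw))
  raster <- structure(list(t_e = te, id_e = sample(N, nspk, TRUE),
                           t_i = numeric(0), id_i = integer(0),
                           n_e = N, n_i = 1, window = c(0, Tw)),
                      class = "spike_raster")
  est <- mean(estimate_rate(raster)$r_e)
  se <- sqrt(rho / (N * Tw))
  expect_lt(abs(est - rho), 3 * se)
})

test_that("spectral frequency estimate identifies a rhythm or reports none", {
  t <- seq(0.25, 500, by = 0.5)
  osc <- synthetic_trace(t, 1 + 0.5 * sin(2 * pi * t / 25))
  expect_equal(oscillation_frequency(osc), 40, tolerance = 0.01)
  flat <- synthetic_trace(t, rep(1, length(t)))
  expect_true(is.na(oscillation_frequency(flat)))
  short <- synthetic_trace(t[t < 60], 1 + 0.5 * sin(2 * pi * t[t < 60] / 30))
  expect_error(oscillation_frequency(short), "insufficient")
})

test_that("simulated rates are non-negative and seed-reproducible", {
  pp <- figure_preset("fig2_ping")
  ep <- pp$e_params; ip <- pp$i_params
  ep$n <- 300L; ip$n <- 300L
  s1 <- simulate_spiking_network(ep, ip, pp$couplings, pp$drive,
                                 duration = 150, step = 0.01, seed = 3)
  s2 <- simulate_spiking_network(ep, ip, pp$couplings, pp$drive,
                                 duration = 150, step = 0.01, seed = 3)
  expect_true(all(s1$rates$r_e >= 0) && all(s1$rates$r_i >= 0))
  expect_identical(s1$raster$t_e, s2$raster$t_e)
  expect_identical(s1$raster$t_i, s2$raster$t_i)
  expect_gt(length(s1$raster$t_e), 0)
})
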