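ping_args <- function() {
  pp <- figure_preset("fig2_ping")
  list(e = pp$e_params, i = pp$i_params, c = pp$couplings)
}

test_that("vector field structure: rate drift at r = 0 and fixed-point identity", {
  a <- ping_args()
  st <- c(0, -1, 0.1, 0.2, 0, -1, 0.1, 0.2)
  f <- mf_vector_field(st, a$e, a$i, a$c, c(10, 0))
  expect_equal(f[1], a$e$delta / (pi * a$e$tau^2))
  expect_gt(f[1], 0)
  fp <- find_fixed_point(a$e, a$i, a$c, c(10, 0))
  expect_lt(fp$residual, 1e-10)
  expect_equal(unname(fp$state[2]),
               unname(-a$e$delta / (2 * pi * a$e$tau * fp$state[1])),
               tolerance = 1e-8)
  expect_equal(unname(fp$state[6]),
               unname(-a$i$delta / (2 * pi * a$i$tau * fp$state[5])),
               tolerance = 1e-8)
  # synapse fixed points are J * r
  expect_equal(unname(fp$state[4]), a$c$j_ei * unname(fp$state[5]),
               tolerance = 1e-8)
})

test_that("trajectory finite differences reproduce the vector field", {
  a <- ping_args()
  y0 <- c(0.05, -0.3, 0.1, 0.5, 0.08, -0.2, 0.6, 0.1)
  h <- 1e-3
  tr <- integrate_mf(y0, a$e, a$i, a$c, c(10, 0), duration = 10 * h, step = h)
  mid <- 6
  fd <- (tr$states[mid + 1, ] - tr$states[mid - 1, ]) / (2 * h)
  f <- mf_vector_field(tr$states[mid, ], a$e, a$i, a$c, c(10, 0))
  expect_lt(max(abs(fd - f)) / max(abs(f)), 1e-4)
})

test_that("RK4 self-converges under step halving", {
  a <- ping_args()
  y0 <- c(0.05, -0.3, 0.1, 0.5, 0.08, -0.2, 0.6, 0.1)
  e1 <- integrate_mf(y0, a$e, a$i, a$c, c(10, 0), 50, step = 0.01)
  e2 <- integrate_mf(y0, a$e, a$i, a$c, c(10, 0), 50, step = 0.005)
  y1 <- e1$states[nrow(e1$states), ]
  y2 <- e2$states[nrow(e2$states), ]
  expect_lt(max(abs(y1 - y2)) / max(abs(y2)), 1e-6)
})

test_that("homogeneous sub-threshold system is stationary at its rest state", {
  e <- population_params(10, -5, 0)
  i <- population_params(10, -5, 0)
  cc <- synaptic_couplings(0, 15, 15, 0)
  rest <- c(0, -sqrt(5), 0, 0, 0, -sqrt(5), 0, 0)
  tr <- integrate_mf(rest, e, i, cc, c(0, 0), duration = 100, step = 0.01,
                     store_every = 100)
  expect_lt(max(abs(sweep(tr$states, 2, rest))), 1e-10)
})

test_that("PING fixed point loses stability through a complex pair", {
  a <- ping_args()
  fp <- find_fixed_point(a$e, a$i, a$c, c(10, 0))
  lead <- fp$eigenvalues[which.max(Re(fp$eigenvalues))]
  expect_false(fp$stable)
  expect_gt(Re(lead), 0)
  expect_gt(abs(Im(lead)), 0)
  # widening the heterogeneity restores stability
  e10 <- a$e; e10$delta <- 10
  i10 <- a$i; i10$delta <- 10
  fp10 <- find_fixed_point(e10, i10, a$c, c(10, 0))
  expect_true(fp10$stable)
  # eigenvalues agree with the linearization at the root
  ev <- eigen(linearization_matrix(fp$state, a$e, a$i, a$c),
              only.values = TRUE)$values
  expect_equal(sort(Re(ev)), sort(Re(fp$eigenvalues)), tolerance = 1e-8)
})

test_that("limit cycle detection finds the PING orbit and rejects rest", {
  cyc <- ping_cycle()
  expect_gt(cyc$period, 0)
  expect_lt(cyc$closure_residual, 1e-6)
  expect_identical(nrow(cyc$states), cyc$n_samples)
  expect_true(all(cyc$states[, "r_e"] > 0) && all(cyc$states[, "r_i"] > 0))
  # phase origin at the r_e maximum
  expect_identical(which.max(cyc$states[, "r_e"]), 1L)
  a <- ping_args()
  expect_error(
    find_limit_cycle(a$e, a$i, a$c, c(0, 0), transient = 100, max_time = 300),
    "no-cycle")
})

test_that("positive rates stay positive along oscillatory trajectories", {
  a <- ping_args()
  tr <- integrate_mf(c(0.01, -2, 0, 0, 0.01, -2, 0, 0), a$e, a$i, a$c,
                     c(10, 0), duration = 400, step = 0.01, store_every = 10)
  expect_true(all(tr$states[, 1] > 0))
  expect_true(all(tr$states[, 5] > 0))
})

test_that("one-dimensional scans report fixed points, stability and extrema", {
  a <- ping_args()
  one <- bifurcation_scan_1d(a$e, a$i, a$c, c(0, 0), "i_ext_e", 10)
  expect_identical(nrow(one), 1L)
  expect_true(one$ok)
  sc <- bifurcation_scan_1d(a$e, a$i, a$c, c(0, 0), "i_ext_e",
                            seq(0, 10, by = 2))
  expect_true(all(sc$ok))
  expect_true(sc$stable[1])          # undriven network is quiescent
  expect_false(sc$stable[nrow(sc)])  # driven network oscillates
  osc_rows <- which(sc$oscillatory)
  expect_true(all(sc$rmax_e[osc_rows] > sc$r_e[osc_rows]))
})

test_that("oscillation map: no rhythm without drive", {
  a <- ping_args()
  m <- stability_region(a$e, a$i, a$c, drive_grid = c(0, 10),
                        delta_grid = c(1, 5), drive_target = "e")
  expect_identical(dim(m), c(2L, 2L))
  expect_false(m["0", "1"])   # zero drive, canonical heterogeneity
  expect_true(m["10", "1"])   # driven, canonical heterogeneity
})
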