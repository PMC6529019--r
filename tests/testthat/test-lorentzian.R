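test_that("deterministic quantile grid is symmetric around the centre", {
  eta <- sample_lorentzian(-5, 1, 5001)
  expect_equal(median(eta), -5)
  expect_equal(eta + rev(eta), rep(-10, 5001))  # grid symmetry
  expect_true(all(diff(eta) > 0))
})

test_that("zero half-width degenerates to a point mass", {
  expect_equal(sample_lorentzian(-5, 0, 100), rep(-5, 100))
})

test_that("random draws reproduce the Lorentzian CDF and are seed-stable", {
  x1 <- sample_lorentzian(-5, 1, 1e5, mode = "random", seed = 11)
  x2 <- sample_lorentzian(-5, 1, 1e5, mode = "random", seed = 11)
  expect_identical(x1, x2)
  # fraction below zero vs the closed form (1/pi)(pi/2 - atan(-5/1))
  expect_lt(abs(mean(x1 < 0) - fraction_non_oscillatory(-5, 1)), 0.01)
})

test_that("non-oscillator fraction matches the Lorentzian CDF", {
  expect_equal(fraction_non_oscillatory(0, 1), 0.5)
  # closed form against numerical integration of the density
  for (p in list(c(-5, 1), c(2, 0.5), c(-1, 3))) {
    num <- stats::integrate(function(e) {
      p[2] / pi / ((e - p[1])^2 + p[2]^2)
    }, -Inf, 0, rel.tol = 1e-12)$value
    expect_lt(abs(fraction_non_oscillatory(p[1], p[2]) - num), 1e-10)
  }
  # limit: strongly excitable population has no sub-threshold cells
  expect_lt(fraction_non_oscillatory(1e8, 1), 1e-8)
})

test_that("invalid heterogeneity parameters are rejected", {
  expect_error(sample_lorentzian(-5, -1, 10), "half_width")
  expect_error(sample_lorentzian(-5, 1, 0), "count")
  expect_error(fraction_non_oscillatory(-5, 0), "half_width")
})
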