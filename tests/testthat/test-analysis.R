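test_that("polynomial extrapolation is exact on polynomial inputs", {
  d <- c(100, 200, 400, 800)
  e <- -10 + 2 / d + 5 / d^2
  fit <- extrapolate_vs_inverse_d(d, e, order = 2)
  expect_equal(fit$extrapolated, -10, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients), c(-10, 2, 5), tolerance = 1e-9)
  expect_lt(max(abs(fit$residuals)), 1e-12)

  # constant series: a0 equals the constant, higher coefficients vanish
  fitc <- extrapolate_vs_inverse_d(d, rep(-3.5, 4), order = 2)
  expect_equal(fitc$extrapolated, -3.5, tolerance = 1e-12)
  expect_equal(unname(fitc$coefficients[-1]), c(0, 0), tolerance = 1e-9)

  # contract violations
  expect_error(extrapolate_vs_inverse_d(c(100, 100, 200), e[1:3]), "increasing")
  expect_error(extrapolate_vs_inverse_d(d[1:2], e[1:2], order = 2), "order")
})

test_that("extrapolation tolerates small noise on the energy series", {
  # seeded noise sigma = 1e-5 over 6 points: the intercept stays within 1e-4
  # for the overwhelming majority of noise draws
  d <- c(50, 100, 200, 400, 800, 1600)
  truth <- -10 + 2 / d + 5 / d^2
  set.seed(99)
  errs <- replicate(100, {
    fit <- extrapolate_vs_inverse_d(d, truth + rnorm(6, sd = 1e-5), order = 2)
    abs(fit$extrapolated + 10)
  })
  expect_lt(unname(quantile(errs, 0.95)), 1e-4)
})

test_that("spin gaps convert intercept differences to mHartree with sign", {
  d <- c(10, 20, 40)
  fa <- extrapolate_vs_inverse_d(d, rep(-10.000, 3), order = 1)
  fb <- extrapolate_vs_inverse_d(d, rep(-9.999, 3), order = 1)
  expect_equal(spin_gap(fa, fb), 1, tolerance = 1e-9)
  expect_equal(spin_gap(fa, fa), 0)
  expect_equal(spin_gap(fa, fb), -spin_gap(fb, fa), tolerance = 1e-12)

  # translation invariance: shifting both series leaves the gap unchanged
  shift <- 2.5
  fa2 <- extrapolate_vs_inverse_d(d, rep(-10.000 + shift, 3), order = 1)
  fb2 <- extrapolate_vs_inverse_d(d, rep(-9.999 + shift, 3), order = 1)
  expect_equal(spin_gap(fa2, fb2), spin_gap(fa, fb), tolerance = 1e-9)
})

test_that("scaling-exponent fits recover power laws and respect the window", {
  d <- c(8, 16, 32, 64, 128)
  expect_equal(fit_scaling_exponent(d, 2.5 * d^3)$exponent, 3, tolerance = 1e-12)
  expect_equal(fit_scaling_exponent(d, 7 * d)$exponent, 1, tolerance = 1e-12)

  # rescaling costs by a positive constant changes only the prefactor
  f1 <- fit_scaling_exponent(d, d^2.5)
  f2 <- fit_scaling_exponent(d, 100 * d^2.5)
  expect_equal(f1$exponent, f2$exponent, tolerance = 1e-12)
  expect_equal(f2$prefactor / f1$prefactor, 100, tolerance = 1e-9)

  # window restriction
  mixed <- c(1e3, 8e3, 64e3, 100e3, 110e3)  # cubic then flat
  f <- fit_scaling_exponent(d, mixed, window = c(8, 32))
  expect_equal(f$exponent, 3, tolerance = 1e-9)
  expect_equal(f$n_points, 3L)
  expect_error(fit_scaling_exponent(d, -d), "positive")
  expect_error(fit_scaling_exponent(d, d^3, window = c(200, 300)), "window")
})

test_that("sweep reports flag convergence thresholds like the run log", {
  rec <- data.frame(sweep = 1:5,
                    energy = c(-1, -1.1, -1.10999, -1.1099905, -1.10999051),
                    max_discarded_weight = rep(1e-8, 5),
                    realized_D = rep(10L, 5), realized_D_u1 = rep(16L, 5),
                    davidson_iterations = rep(3L, 5),
                    flops_total = cumsum(rep(100, 5)))
  rep_ <- sweep_report(rec, energy_tol = 1e-8)
  expect_true(is.na(rep_$delta_e[1]))
  expect_equal(rep_$below_1e5, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(rep_$below_tol, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(nrow(sweep_report(rec[1, , drop = FALSE])), 1)

  # strictly decreasing energies give a positive, defined delta column
  rec2 <- rec; rec2$energy <- -(1:5)
  expect_true(all(sweep_report(rec2)$delta_e[-1] == 1))
})
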