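p <- dmf_parameters()

test_that("linear FIC rule is exact at G = 0 and elementwise linear", {
  set.seed(11)
  beta <- runif(15, 0, 10)
  for (a in c(0.3, 0.67, 0.75, 1.2))
    expect_identical(linear_fic(0, beta, a), rep(1, 15))
  expect_equal(linear_fic(2, 10, 0.75), 16)
  # permutation equivariance
  perm <- sample(15)
  expect_equal(linear_fic(1.3, beta[perm], 0.7), linear_fic(1.3, beta, 0.7)[perm])
  expect_error(linear_fic(-1, beta, 0.7))
  expect_error(linear_fic(1, -beta, 0.7))
  expect_error(linear_fic(1, beta, 0))
})

test_that("expected gating matches its closed form and limits", {
  expect_equal(round(expected_gating(3.4, p), 3), 0.179)
  expect_equal(expected_gating(0, p), 0)
  expect_gt(expected_gating(1e9, p), 1 - 1e-6)
  r <- seq(0, 50, by = 0.5)
  expect_true(all(diff(expected_gating(r, p)) > 0))
  expect_true(all(expected_gating(r, p) < 1))
  expect_error(expected_gating(-1, p), "nonnegative")
})

test_that("uncoupled moment system solves to small residuals", {
  m <- solve_uncoupled_moments(p, rate_target = 3.4)
  # each moment is a fixed point of its defining equation
  expect_lt(abs(transfer_rate(m$E_IE, p$gE, p$IthrE, p$dE) - 3.4), 1e-8)
  expect_lt(abs(p$tau_GABA *
                  transfer_rate(m$E_II, p$gI, p$IthrI, p$dI) - m$E_SI), 1e-8)
  expect_equal(m$E_SE, expected_gating(3.4, p))

  # independent oracle for E_SI: damped fixed-point iteration
  base <- p$W_I * p$I0 + p$J_NMDA * m$E_SE
  S <- 0.05
  for (i in 1:2000)
    S <- 0.5 * S + 0.5 * p$tau_GABA *
      transfer_rate(base - S, p$gI, p$IthrI, p$dI)
  expect_equal(m$E_SI, S, tolerance = 1e-8)
  expect_equal(m$E_SI, 0.0403, tolerance = 1e-3)

  # independent oracle for E_IE: plain bisection on F_E
  lo <- 0.3; hi <- 0.403
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (transfer_rate(mid, p$gE, p$IthrE, p$dE) < 3.4) lo <- mid else hi <- mid
  }
  expect_equal(m$E_IE, lo, tolerance = 1e-8)
  expect_equal(m$E_IE, 0.3805, tolerance = 1e-3)
})

test_that("analytic coefficients reproduce alpha = 0.67 and c = 0.97", {
  m <- solve_uncoupled_moments(p)
  ac <- analytic_alpha_c(m, p)
  expect_equal(round(ac$alpha, 2), 0.67)
  expect_equal(round(ac$c, 2), 0.97)
  # direct arithmetic oracle
  expect_equal(ac$alpha, 0.15 * m$E_SE / m$E_SI, tolerance = 1e-12)
  expect_equal(ac$c,
               (0.382 + 1.4 * 0.15 * m$E_SE - m$E_IE) / m$E_SI,
               tolerance = 1e-12)
})

test_that("alpha regression recovers a known slope with zero intercept", {
  set.seed(21)
  beta <- runif(20, 1, 8)
  jbg <- lapply(c(0.5, 1, 2), function(g) list(G = g, J = 0.7 * g * beta + 1))
  expect_equal(fit_alpha(jbg, beta), 0.7, tolerance = 1e-12)
  # a wrong uniform offset biases but the noiseless slope through the origin
  # is still returned without fitting an intercept
  jbg_n <- lapply(c(0.4, 0.8, 1.2, 1.6, 2.0), function(g)
    list(G = g, J = 0.7 * g * beta + 1 + rnorm(20, 0, 0.01)))
  expect_lt(abs(fit_alpha(jbg_n, beta) - 0.7), 0.02)
  # high-G weighting emphasizes the slope there
  jbg_k <- lapply(c(1, 2.5), function(g)
    list(G = g, J = (if (g > 2.1) 0.8 else 0.7) * g * beta + 1))
  expect_gt(fit_alpha(jbg_k, beta, weight_rule = "high_G"),
            fit_alpha(jbg_k, beta, weight_rule = "uniform"))
  expect_error(fit_alpha(jbg[1], beta), "distinct")
  jz <- list(list(G = 0, J = rep(1, 20)), list(G = 0, J = rep(1, 20)))
  expect_error(fit_alpha(jz, beta), "distinct|degenerate")
})

test_that("iterative calibration at G = 0 keeps J at the uncoupled value", {
  fic <- calibrate_fic_iterative(tiny20(), G = 0, seed = 1)
  expect_true(fic$converged)
  expect_true(all(abs(fic$J - 1) < 0.05))
  expect_true(all(abs(fic$rate_mean - 3.4) < 0.2))
})
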