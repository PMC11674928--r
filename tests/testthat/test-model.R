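p <- dmf_parameters()

test_that("transfer function handles the removable singularity and is smooth", {
  # limit at threshold is 1/d
  expect_equal(transfer_rate(p$IthrE, p$gE, p$IthrE, p$dE), 1 / p$dE)
  expect_equal(transfer_rate(p$IthrI, p$gI, p$IthrI, p$dI), 1 / p$dI)
  # C1-continuity across threshold
  for (eps in c(1e-9, -1e-9)) {
    expect_lt(abs(transfer_rate(p$IthrE + eps, p$gE, p$IthrE, p$dE) -
                    1 / p$dE), 1e-4)
  }
  # monotone nondecreasing and nonnegative over a wide current grid
  I <- seq(-0.5, 1.5, by = 1e-3)
  r <- transfer_rate(I, p$gE, p$IthrE, p$dE)
  expect_true(all(r >= 0))
  expect_true(all(diff(r) >= -1e-12))
})

test_that("transfer function matches independent oracles", {
  # bisection oracle: the current at which F_E = 3.4 Hz
  f <- function(I) transfer_rate(I, p$gE, p$IthrE, p$dE) - 3.4
  lo <- 0.3; hi <- 0.403
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(lo, 0.3805, tolerance = 1e-3)
  expect_equal(transfer_rate(lo, p$gE, p$IthrE, p$dE), 3.4, tolerance = 1e-8)
  # asymptotic linear form at high current: exponential term negligible
  expect_equal(transfer_rate(1.0, p$gE, p$IthrE, p$dE),
               p$gE * (1.0 - p$IthrE), tolerance = 1e-9)
  expect_equal(p$gE * (1.0 - p$IthrE), 185.07, tolerance = 1e-4)
})

test_that("transfer function rejects non-finite current", {
  expect_error(transfer_rate(NaN, p$gE, p$IthrE, p$dE), "non-finite")
  expect_error(transfer_rate(Inf, p$gE, p$IthrE, p$dE), "non-finite")
})

test_that("node strength computes (optionally halved) row sums", {
  expect_equal(node_strength(matrix(c(0, 1, 1, 0), 2, 2)), c(1, 1))
  m <- matrix(c(0, 2, 0, 2, 0, 4, 0, 4, 0), 3, 3)
  expect_equal(node_strength(m, halve = TRUE), c(1, 3, 2))
  expect_equal(node_strength(matrix(0, 3, 3)), rep(0, 3))
  expect_error(node_strength(matrix(0, 2, 3)), "square")
})

test_that("synaptic currents evaluate the input-current equations exactly", {
  con1 <- connectome(matrix(0, 1, 1))
  # baseline-only terms
  cur <- synaptic_currents(0, 0, con1, coupling_config(0, 1), p)
  expect_equal(cur$I_E, p$W_E * p$I0)
  expect_equal(cur$I_I, p$W_I * p$I0)
  expect_equal(cur$I_I, 0.2674)
  # at the uncoupled moment point the excitatory current is ~0.3805 nA
  cur <- synaptic_currents(0.17894, 0.0403, con1,
                           coupling_config(0, 0.97), p)
  expect_equal(cur$I_E,
               p$W_E * p$I0 + p$w_plus * p$J_NMDA * 0.17894 - 0.97 * 0.0403)
  expect_equal(cur$I_E, 0.3805, tolerance = 1e-3)
  # two coupled regions
  con2 <- connectome(matrix(c(0, 1, 1, 0), 2, 2))
  cur <- synaptic_currents(c(0.1, 0.2), c(0, 0), con2,
                           coupling_config(2, c(1, 1)), p)
  expect_equal(cur$I_E[1], 0.382 + 1.4 * 0.15 * 0.1 + 2 * 0.15 * 0.2)
  expect_error(synaptic_currents(c(0.1), c(0, 0), con2,
                                 coupling_config(2, c(1, 1)), p),
               "dimension")
})

test_that("uncoupled currents decompose into independent single regions", {
  set.seed(3)
  n <- 6
  w <- matrix(runif(n^2), n, n); w <- (w + t(w)) / 2; diag(w) <- 0
  con <- connectome(w)
  SE <- runif(n); SI <- runif(n); J <- runif(n, 0.5, 2)
  cur <- synaptic_currents(SE, SI, con, coupling_config(0, J), p)
  one <- connectome(matrix(0, 1, 1))
  for (i in seq_len(n)) {
    ci <- synaptic_currents(SE[i], SI[i], one, coupling_config(0, J[i]), p)
    expect_equal(cur$I_E[i], ci$I_E)
    expect_equal(cur$I_I[i], ci$I_I)
  }
  # permutation of region order permutes currents identically
  perm <- sample(n)
  cp <- synaptic_currents(SE[perm], SI[perm], connectome(w[perm, perm]),
                          coupling_config(0, J[perm]), p)
  expect_equal(cp$I_E, cur$I_E[perm])
})

test_that("drift vanishes at its fixed points", {
  expect_equal(drift(0, 0, 0, 0, p)$dS_E, 0)
  # gating fixed point at 3.4 Hz
  SEfix <- p$gamma_kin * p$tau_NMDA * 3.4 / (1 + p$gamma_kin * p$tau_NMDA * 3.4)
  expect_lt(abs(drift(SEfix, 0, 3.4, 0, p)$dS_E), 1e-6)
  expect_equal(drift(0, 0.034, 0, 3.4, p)$dS_I, 0)
  # full drift at the solved uncoupled moment point
  m <- solve_uncoupled_moments(p)
  d <- drift(m$E_SE, m$E_SI, m$E_rE, m$E_rI, p)
  expect_lt(sqrt(d$dS_E^2 + d$dS_I^2), 1e-6)
})

test_that("parameter constructors validate their domains", {
  expect_error(dmf_parameters(I0 = -1), "positive")
  expect_error(dmf_parameters(W_E = -0.1), "nonnegative")
  expect_error(hemodynamic_parameters(rho = 0), "positive")
  expect_silent(hemodynamic_parameters(k3 = -0.43))
  expect_error(integration_config(duration = 5, transient_discard = 10),
               "exceed")
  expect_error(integration_config(duration = 20, dt_dmf = 3e-4), "multiple")
  expect_error(coupling_config(-1, 1), "G")
  expect_error(coupling_config(1, c(-0.5, 1)), "nonnegative")
})

test_that("connectome constructor enforces its invariants", {
  expect_error(connectome(matrix(1:6, 2, 3)), "square")
  expect_error(connectome(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(connectome(matrix(c(0, -1, -1, 0), 2, 2)), "nonnegative")
  expect_error(connectome(matrix(c(1, 0, 0, 1), 2, 2)), "diagonal")
  con <- connectome(matrix(c(0, 1, 1, 0), 2, 2), labels = c("a", "b"))
  expect_equal(con$labels, c("a", "b"))
})
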