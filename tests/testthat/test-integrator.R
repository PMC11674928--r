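test_that("identical seeds give bit-identical simulations", {
  con <- connectome(matrix(c(0, 0.3, 0.3, 0), 2, 2))
  cfg <- integration_config(duration = 16, transient_discard = 2, seed = 9)
  cp <- coupling_config(0.5, c(1, 1))
  a <- run_simulation(con, cp, cfg)
  b <- run_simulation(con, cp, cfg)
  expect_identical(a$bold, b$bold)
  expect_identical(a$rate_mean, b$rate_mean)
  cfg2 <- integration_config(duration = 16, transient_discard = 2, seed = 10)
  expect_false(identical(a$bold, run_simulation(con, cp, cfg2)$bold))
})

test_that("BOLD sample count follows duration, discard and TR", {
  con <- connectome(matrix(0, 1, 1))
  cfg <- integration_config(duration = 130, transient_discard = 10, TR = 2,
                            seed = 1)
  sim <- run_simulation(con, coupling_config(0, 1), cfg)
  expect_equal(ncol(sim$bold), 60)
})

test_that("C++ rate stream matches the pure-R reference integrator", {
  con <- connectome(matrix(c(0, 0.4, 0.4, 0), 2, 2))
  cfg <- integration_config(duration = 3, transient_discard = 1, TR = 1,
                            seed = 5)
  cp <- coupling_config(0.8, c(1.1, 0.9))
  fast <- simulate_rates(con, cp, cfg)
  ref <- dmfsim:::dmf_reference_rates(con, cp, cfg)
  expect_equal(fast$rates, ref, tolerance = 1e-12)
})

test_that("streaming pipeline equals the materialized rate + R consumer path", {
  con <- make_connectome(3, target_mean_strength = 0.5, seed = 4)
  cfg <- integration_config(duration = 24, transient_discard = 4, TR = 2,
                            seed = 7)
  cp <- coupling_config(0.5, rep(1, 3))
  streamed <- run_simulation(con, cp, cfg)
  rates <- simulate_rates(con, cp, cfg)$rates
  mono <- balloon_windkessel(rates, cfg)
  expect_equal(unname(streamed$bold), mono, tolerance = 1e-12)
  expect_equal(ncol(mono), 10)
})

test_that("buffer accounting is flat in duration (bounded-memory contract)", {
  con <- connectome(matrix(c(0, 0.2, 0.2, 0), 2, 2))
  cp <- coupling_config(0.3, c(1, 1))
  cap <- 500L
  s1 <- run_simulation(con, cp, integration_config(
    duration = 12, transient_discard = 2, seed = 1, buffer_capacity = cap))
  s2 <- run_simulation(con, cp, integration_config(
    duration = 24, transient_discard = 2, seed = 1, buffer_capacity = cap))
  expect_equal(s1$max_live_samples, cap * 2)
  expect_equal(s2$max_live_samples, s1$max_live_samples)
  # short run never fills the buffer
  s3 <- run_simulation(con, cp, integration_config(
    duration = 12, transient_discard = 2, seed = 1,
    buffer_capacity = 100000L))
  expect_equal(s3$buffer_high_water, 12000)
})

test_that("noise-free dynamics converge to the deterministic fixed point", {
  p0 <- dmf_parameters(sigma = 1e-300)
  con <- connectome(matrix(0, 1, 1))
  cfg <- integration_config(duration = 60, transient_discard = 50, seed = 1)
  sim <- run_simulation(con, coupling_config(0, 1), cfg, params = p0)
  # independent root-finder on the coupled E/I drift fixed point
  p <- dmf_parameters()
  si_of_se <- function(SE)
    uniroot(function(S) p$tau_GABA *
              transfer_rate(p$W_I * p$I0 + p$J_NMDA * SE - S,
                            p$gI, p$IthrI, p$dI) - S,
            c(0, 1), tol = 1e-14)$root
  g <- function(SE) {
    IE <- p$W_E * p$I0 + p$w_plus * p$J_NMDA * SE - si_of_se(SE)
    r <- transfer_rate(IE, p$gE, p$IthrE, p$dE)
    p$gamma_kin * p$tau_NMDA * r / (1 + p$gamma_kin * p$tau_NMDA * r) - SE
  }
  SEfix <- uniroot(g, c(0, 0.9), tol = 1e-14)$root
  IEfix <- p$W_E * p$I0 + p$w_plus * p$J_NMDA * SEfix - si_of_se(SEfix)
  rfix <- transfer_rate(IEfix, p$gE, p$IthrE, p$dE)
  expect_equal(unname(sim$rate_mean), rfix, tolerance = 1e-6)
  expect_equal(unname(sim$se_mean), SEfix, tolerance = 1e-6)
})

test_that("hemodynamic consumer reaches the predicted steady inflow", {
  h <- hemodynamic_parameters()
  cfg <- integration_config(duration = 600, transient_discard = 10, TR = 2)
  rates <- matrix(3, 1, 600000)
  out <- balloon_windkessel(rates, cfg, h, return_state = TRUE)
  f_star <- 1 + (0.5 * 3 + 3) / h$gamma_BW
  expect_equal(out$state$f, f_star, tolerance = 1e-3)
  expect_equal(out$state$s, 0, tolerance = 1e-3)
  # volume and deoxyhemoglobin settle at their algebraic balance
  expect_equal(out$state$v, f_star^h$alpha_BW, tolerance = 1e-3)
})

test_that("hemodynamic divergence is reported as a typed error", {
  cfg <- integration_config(duration = 30, transient_discard = 2, TR = 2)
  # an extreme constant drive with no autoregulation blows up the inflow
  h <- hemodynamic_parameters(gamma_BW = 1e-6, kappa = 1e-6)
  rates <- matrix(500, 1, 30000)
  expect_error(balloon_windkessel(rates, cfg, h),
               class = "dmf_hemo_error")
})
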