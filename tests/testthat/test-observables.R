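cfg <- observables_config()

test_that("band-pass filter passes the band and rejects DC and high freq", {
  t <- seq(0, by = 2, length.out = 1000)
  x_mid <- sin(2 * pi * 0.05 * t)          # passband center
  x_hi <- sin(2 * pi * 0.2 * t)            # 2x above the upper corner
  x_dc <- rep(3, 1000)
  y_mid <- bandpass(rbind(x_mid), cfg)
  expect_lt(abs(sd(y_mid) / sd(x_mid) - 1), 0.05)
  y_hi <- bandpass(rbind(x_hi), cfg)
  expect_lt(mean(y_hi^2) / mean(x_hi^2), 0.10)
  y_dc <- bandpass(rbind(x_dc), cfg)
  expect_lt(sqrt(mean(y_dc^2)), 1e-6 * 3)
  expect_error(bandpass(rbind(x_mid[1:10]), cfg), "short")
  expect_error(observables_config(band = c(0.01, 0.3)), "Nyquist")
})

test_that("FC matrix matches the direct correlation formula", {
  set.seed(31)
  x <- matrix(rnorm(4 * 50), 4, 50)
  fc <- fc_matrix(x)
  # hand-rolled covariance/stdev oracle
  for (i in 1:4) for (j in 1:4) {
    xi <- x[i, ] - mean(x[i, ]); xj <- x[j, ] - mean(x[j, ])
    expect_equal(fc[i, j], sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2)),
                 tolerance = 1e-12)
  }
  expect_equal(fc, t(fc))
  expect_equal(diag(fc), rep(1, 4), ignore_attr = TRUE)
  # duplicated and negated rows
  y <- rbind(x[1, ], x[1, ], -x[1, ])
  fc2 <- suppressWarnings(fc_matrix(y))
  expect_equal(fc2[1, 2], 1)
  expect_equal(fc2[1, 3], -1)
  # zero-variance region flagged, not silently zeroed
  expect_warning(fcz <- fc_matrix(rbind(x[1, ], rep(2, 50))),
                 "zero-variance")
  expect_true(is.na(fcz[1, 2]))
})

test_that("FCD has the expected window count and degenerate-case behavior", {
  set.seed(32)
  x <- matrix(rnorm(5 * 200), 5, 200)
  s <- fcd_matrix(x, cfg)
  expect_equal(s$window_count, 86)           # floor((200 - 30)/2) + 1
  expect_equal(dim(s$fcd), c(86, 86))
  expect_equal(s$fcd, t(s$fcd))
  expect_equal(diag(s$fcd), rep(1, 86), ignore_attr = TRUE)
  expect_true(all(abs(s$pooled_values) <= 1 + 1e-12))
  expect_equal(length(s$pooled_values), 86 * 85 / 2)
  for (Tn in c(30, 57, 101))
    expect_equal(fcd_matrix(x[, 1:Tn], cfg)$window_count,
                 floor((Tn - 30) / 2) + 1)
  expect_error(fcd_matrix(x[, 1:20], cfg), "shorter")
  # exactly periodic signal with period = stride: all windows identical
  x1 <- (-1)^(1:100)
  per <- rbind(x1, 2 * x1, -x1)
  sp <- fcd_matrix(per, cfg)
  expect_true(all(abs(sp$pooled_values - 1) < 1e-12))
})

test_that("FCD of white noise concentrates near zero off-diagonal", {
  set.seed(33)
  x <- matrix(rnorm(20 * 500), 20, 500)
  s <- fcd_matrix(x, cfg)
  expect_lt(mean(abs(s$pooled_values)), 0.2)
})

test_that("K-S distance matches a brute-force ECDF oracle", {
  expect_equal(ks_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_distance(c(1, 2), c(10, 11, 12)), 1)
  expect_equal(ks_distance(c(1, 2, 3), c(1.5, 2.5, 3.5)), 1 / 3)
  set.seed(34)
  for (i in 1:20) {
    a <- rnorm(sample(3:40, 1))
    b <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1))
    expect_equal(ks_distance(a, b), ks_brute(a, b), tolerance = 1e-12)
    # symmetry and invariance under a common strictly monotone transform
    expect_equal(ks_distance(a, b), ks_distance(b, a))
    expect_equal(ks_distance(exp(a), exp(b)), ks_distance(a, b))
    # agreement with the stats implementation
    expect_equal(ks_distance(a, b),
                 unname(suppressWarnings(stats::ks.test(a, b))$statistic),
                 tolerance = 1e-12)
  }
  expect_error(ks_distance(numeric(0), 1), "nonempty")
  # binned variant approximates the raw statistic on smooth samples
  set.seed(35)
  a <- rnorm(2000); b <- rnorm(2000, 0.5)
  expect_lt(abs(ks_distance(a, b, method = "binned", bins = 200) -
                  ks_distance(a, b)), 0.03)
})

test_that("pooling concatenates upper-triangle samples", {
  set.seed(36)
  s1 <- fcd_matrix(matrix(rnorm(4 * 60), 4, 60), cfg)
  s2 <- fcd_matrix(matrix(rnorm(4 * 80), 4, 80), cfg)
  pool <- pool_fcd(list(s1, s2))
  W1 <- s1$window_count; W2 <- s2$window_count
  expect_equal(length(pool), W1 * (W1 - 1) / 2 + W2 * (W2 - 1) / 2)
  expect_equal(pool_fcd(list(s1)), s1$pooled_values)
  # doubling the sample leaves the ECDF unchanged
  expect_equal(ks_distance(pool_fcd(list(s1, s1)), s1$pooled_values), 0)
  expect_error(pool_fcd(list()), "at least one")
})

test_that("rate range check uses a closed interval and reports offenders", {
  expect_true(rate_in_range(rep(3.4, 5))$pass)
  expect_true(rate_in_range(c(3, 4))$pass)
  r <- rate_in_range(c(3.4, 5.0, 3.3))
  expect_false(r$pass)
  expect_equal(r$offending, 2L)
})
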