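test_that("ACF and PACF agree with brute-force oracles on all short series", {
  set.seed(41)
  for (n in 4:12) {
    for (rep in 1:5) {
      x <- round(stats::rnorm(n, 5, 2), 2)
      if (stats::sd(x) == 0) next
      max_lag <- n - 2
      a <- acf_stats(x, max_lag)
      expect_equal(a$acf[1], 1.0)
      for (k in seq_len(max_lag)) {
        expect_equal(a$acf[k + 1], acf_brute(x, k), tolerance = 1e-10)
      }
      expect_true(all(abs(a$acf) <= 1 + 1e-12))
      p <- pacf_stats(x, max_lag)
      expect_equal(p$pacf[1], a$acf[2], tolerance = 1e-10)
      ref <- pacf_brute(x, max_lag)
      expect_equal(p$pacf, unname(ref), tolerance = 1e-8)
    }
  }
})

test_that("worked ACF example and white-noise band calibration hold", {
  a <- acf_stats(c(1, 2, 3, 4, 5), 1)
  expect_equal(a$acf[2], 0.4) # sum(dev * dev_lag1) / sum(dev^2) = 4/10
  expect_equal(a$upper[1], 1.96 / sqrt(5))
  expect_error(acf_stats(rep(3, 10), 2), "constant")

  # under white noise roughly 5% of lags 1-20 fall outside the 95% band
  set.seed(7)
  outside <- replicate(40, {
    x <- stats::rnorm(500)
    a <- acf_stats(x, 20)
    mean(abs(a$acf[-1]) > a$upper[-1])
  })
  expect_lt(mean(outside), 0.10)
})

test_that("PACF recovers an AR(1) coefficient and nulls out higher lags", {
  set.seed(11)
  x <- as.numeric(stats::arima.sim(list(ar = 0.6), n = 2000))
  p <- pacf_stats(x, 6)
  expect_equal(p$pacf[1], 0.6, tolerance = 0.06)
  expect_true(all(abs(p$pacf[3:6]) < 3 * 1.96 / sqrt(2000)))
})

test_that("persistence residuals follow the chronological evaluation scheme", {
  r <- persistence_residuals(c(3, 5, 2))
  expect_equal(r$residuals, c(2, -3))
  expect_equal(r$summary$mean, -0.5)
  expect_equal(r$summary$count, 2L)

  const <- persistence_residuals(rep(4, 10))
  expect_true(all(const$residuals == 0))
  expect_equal(const$summary$sd, 0)

  # chronological split: first 66% train, residuals over the final 34%
  x <- c(10, 12, 9, 14, 13, 11, 16, 15, 12, 18)
  r2 <- persistence_residuals(x, train_fraction = 0.66)
  expect_equal(r2$summary$count, 10L - 6L) # split after floor(0.66 * 10) = 6
  expect_equal(r2$residuals, diff(x)[6:9])
  expect_equal(r2$summary$min, min(r2$residuals))
  expect_equal(r2$summary$max, max(r2$residuals))
  expect_error(persistence_residuals(c(1, 2)), "at least 3")
})

test_that("Dickey-Fuller test has correct size under a unit root and power under noise", {
  n_rep <- 250
  set.seed(13)
  rej_rw <- rej_noise <- 0
  for (i in seq_len(n_rep)) {
    rw <- cumsum(stats::rnorm(200))
    t1 <- dickey_fuller_test(rw)
    rej_rw <- rej_rw + (t1$statistic < t1$critical_values[["5%"]])
    wn <- stats::rnorm(200)
    t2 <- dickey_fuller_test(wn)
    rej_noise <- rej_noise + (t2$statistic < t2$critical_values[["5%"]])
  }
  # size ~5% under the unit-root null, high power against i.i.d. noise
  expect_lt(rej_rw / n_rep, 0.10)
  expect_gt(rej_noise / n_rep, 0.90)

  # location invariance of the intercept specification
  set.seed(14)
  x <- stats::rnorm(100)
  expect_equal(
    dickey_fuller_test(x)$statistic,
    dickey_fuller_test(x + 100)$statistic,
    tolerance = 1e-9
  )
  expect_error(dickey_fuller_test(1:5), "at least 10")
})

test_that("runs test flags alternation and clumping, and is calibrated under the null", {
  # perfectly alternating above/below the median: runs = n, tiny p
  alt <- rep(c(1, 10), 10)
  r <- runs_test(alt)
  expect_equal(r$runs, 20L)
  expect_lt(r$p_value, 0.01)
  # all-above then all-below: 2 runs, tiny p
  clump <- c(rep(10, 10), rep(1, 10))
  r2 <- runs_test(clump)
  expect_equal(r2$runs, 2L)
  expect_lt(r2$p_value, 0.01)
  # closed-form oracle for the alternating case: z = (R - mu) / sigma
  n1 <- r$n_above; n2 <- r$n_below; n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  sig <- sqrt(2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1)))
  expect_equal(r$p_value, 2 * stats::pnorm(-abs((20 - mu) / sig)), tolerance = 1e-12)

  # calibration under exchangeability
  set.seed(15)
  rej <- mean(replicate(400, runs_test(stats::rnorm(60))$p_value < 0.05))
  expect_lt(abs(rej - 0.05), 0.04)
  expect_error(runs_test(c(1, 1, 1, 10)), "each side")
})

test_that("Ljung-Box statistics are nonnegative and nondecreasing in lag", {
  set.seed(16)
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), n = 120))
  lb <- ljung_box(x, lags = 1:10)
  expect_true(all(lb$statistic >= 0))
  expect_true(all(diff(lb$statistic) >= -1e-12))
  # matches stats::Box.test directly at one lag
  expect_equal(lb$statistic[5],
               unname(stats::Box.test(x, lag = 5, type = "Ljung-Box")$statistic))
})

test_that("cross-correlation identifies constructed shifts and handles missing years", {
  set.seed(17)
  a <- stats::rnorm(40)
  expect_equal(cross_correlation(a, a, 0)$r, 1.0)
  # b leads a by one year: maximal correlation at lag 1 (a follows b)
  b <- c(a[-1], stats::rnorm(1))
  cc <- cross_correlation(a, b, 5)
  best <- cc$lag[which.max(cc$r)]
  expect_equal(best, 1L)
  # brute-force oracle over all lags
  for (k in -3:3) {
    ia <- seq_along(a); ib <- ia - k
    ok <- ib >= 1 & ib <= length(b)
    expect_equal(cc$r[cc$lag == k],
                 stats::cor(a[ia[ok]], b[ib[ok]]), tolerance = 1e-12)
  }
  # pairwise deletion: overlap below 3 flagged undefined
  short <- cross_correlation(c(1, 2, NA, 4), c(2, NA, 1, 5), 3)
  expect_false(short$defined[short$lag == 3])
})

test_that("diagnose_series bundles all statistics coherently", {
  set.seed(18)
  cfg <- small_config(seed = 18L, n_years = 6L)
  d <- simulate_prey_whale_dynamics(cfg)
  x <- d$transects$n_whales[order(d$transects$date)]
  dg <- diagnose_series(x, max_lag = 15)
  expect_s3_class(dg, "gw_diagnostics")
  expect_equal(dg$acf$acf[1], 1)
  expect_equal(nrow(dg$ljung_box), 15)
  expect_equal(dg$residual_summary$count, length(dg$residuals))
  expect_named(dg$stationarity$critical_values, c("1%", "5%", "10%"))
})
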