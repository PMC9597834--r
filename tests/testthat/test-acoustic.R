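test_that("AV schedule samples every fifth full day plus transect hours", {
  # deployment 6-21 May: first full day 7 May, then 12, 17 May
  sch <- av_schedule(
    as.POSIXct("2015-05-06 09:30:00", tz = "UTC"),
    as.POSIXct("2015-05-21 14:00:00", tz = "UTC")
  )
  expect_equal(sch$sampled_days, as.Date(c("2015-05-07", "2015-05-12", "2015-05-17")))
  expect_true(all(sch$windows$type == "full_day"))

  # long deployment with no transects: day coverage about one fifth
  long <- av_schedule(
    as.POSIXct("2015-05-06 09:30:00", tz = "UTC"),
    as.POSIXct("2015-09-14 12:00:00", tz = "UTC")
  )
  expect_equal(long$day_coverage, 1 / 5, tolerance = 0.04)

  # transect-concurrent windows appended
  tt <- as.POSIXct(c("2015-06-01 12:00:00", "2015-06-04 11:00:00"), tz = "UTC")
  with_tr <- av_schedule(
    as.POSIXct("2015-05-06 09:30:00", tz = "UTC"),
    as.POSIXct("2015-09-14 12:00:00", tz = "UTC"),
    transect_times = tt
  )
  expect_equal(sum(with_tr$windows$type == "transect"), 2)

  expect_warning(
    av_schedule(as.POSIXct("2015-05-06 09:00:00", tz = "UTC"),
                as.POSIXct("2015-05-06 23:00:00", tz = "UTC")),
    "shorter"
  )
  expect_error(
    av_schedule(as.POSIXct("2015-05-06", tz = "UTC"),
                as.POSIXct("2015-05-06", tz = "UTC")),
    "empty"
  )
})

test_that("class distribution reports both denominators correctly", {
  # catalogue-scale worked example: 5751 calls of which 4574 are core
  # (non-motherese); class counts 1130 sweeps, 1622 moans, 13 rumbles, the
  # knock count taken as the core remainder
  calls <- calls_at(
    as.POSIXct("2015-07-01 00:00:00", tz = "UTC") + seq_len(5751),
    c(
      rep("class1_knock", 4574 - 1130 - 1622 - 13), rep("class2_sweep", 1130),
      rep("class3_moan", 1622), rep("class4_rumble", 13),
      rep("motherese", 5751 - 4574)
    )
  )
  dist <- class_distribution(calls)
  expect_equal(attr(dist, "n_total"), 5751)
  expect_equal(attr(dist, "n_non_motherese"), 4574)
  expect_equal(
    round(dist$pct_non_motherese[dist$call_class == "class2_sweep"], 1), 24.7
  )
  expect_equal(
    round(dist$pct_all[dist$call_class == "class3_moan"], 1), 28.2
  )
  expect_equal(
    round(dist$pct_all[dist$call_class == "motherese"], 1), 20.5
  )
  expect_true(is.na(dist$pct_non_motherese[dist$call_class == "motherese"]))

  one <- class_distribution(calls_at("2015-07-01 00:00:01", "class1_knock"))
  expect_equal(one$pct_all[one$call_class == "class1_knock"], 100)
  expect_equal(sum(one$pct_all), 100)

  expect_warning(
    class_distribution(calls_at(rep("2015-07-01 00:00:01", 2), c("class1_knock", "squeak"))),
    "unknown"
  )
})

test_that("call rates are calls per hour per whale with motherese excluded", {
  calls <- calls_at(
    as.POSIXct("2015-07-01 12:00:00", tz = "UTC") + 1:8 * 60,
    c(rep("class2_sweep", 6), rep("motherese", 2))
  )
  cr <- call_rate(calls, n_whales = 3, window_hours = 2)
  expect_equal(cr$rate_class2, 1.0) # 6 calls / 2 h / 3 whales
  expect_equal(cr$n_motherese, 2)
  expect_equal(cr$rate_class1, 0)
  zero <- call_rate(calls[0, ], n_whales = 2, window_hours = 1)
  expect_equal(zero$rate_class3, 0)
  none <- call_rate(calls, n_whales = 0, window_hours = 1)
  expect_true(is.na(none$rate_class2))
  expect_equal(none$n_class2, 6) # counts retained
  expect_error(call_rate(calls, 2, -1), "positive")
})

test_that("Monte Carlo detection probability matches the closed-form normal CDF", {
  model <- detection_model(n_draws = 1e5, seed = 99L)
  grid <- expand.grid(r = c(10, 100, 500, 1000, 5000), NL = c(80, 91, 100, 110))
  for (i in seq_len(nrow(grid))) {
    p_mc <- detection_probability(grid$r[i], grid$NL[i], model)
    p_cf <- detection_probability(grid$r[i], grid$NL[i], model, method = "closed_form")
    se <- sqrt(max(p_cf * (1 - p_cf), 1e-12) / model$n_draws)
    expect_lt(abs(p_mc - p_cf), 3 * se + 1e-9)
  }
  # extreme noise: probability essentially zero
  expect_lt(detection_probability(10, model$SL_mean + 50, model), 1e-4)
  # median case: NL exactly at the propagated mean source level
  r <- 500
  nl <- model$SL_mean - 20 * log10(r)
  expect_equal(detection_probability(r, nl, model, method = "closed_form"), 0.5)
  expect_equal(detection_probability(r, nl, model), 0.5, tolerance = 0.01)
  expect_error(detection_probability(0.5, 90, model), "reference")
})

test_that("detection probability is non-increasing in range and noise", {
  model <- detection_model(n_draws = 2e4, seed = 3L)
  rs <- c(1, 10, 100, 1000, 10000)
  p_r <- detection_probability(rs, 95, model)
  expect_true(all(diff(p_r) <= 1e-12))
  nls <- seq(70, 130, by = 10)
  p_n <- vapply(nls, function(nl) detection_probability(300, nl, model), numeric(1))
  expect_true(all(diff(p_n) <= 1e-12))
})

test_that("detection radii follow the closed form and quantile transform", {
  model <- detection_model()
  # worked arithmetic: NL = 96.9 dB gives a 1000 m median-detection radius
  expect_equal(detection_radius(96.9, model), 1000, tolerance = 1e-9)
  # constant noise: all quantiles equal
  const <- detection_radius_series(tibble::tibble(NL = rep(91, 50)), model)
  expect_equal(unname(const$exceedance["q10_exceed_m"]),
               unname(const$exceedance["q90_exceed_m"]))
  # normal noise: empirical exceedance radii match the quantile transform of
  # the closed form within sampling error
  set.seed(44)
  nl <- stats::rnorm(20000, 91, 8)
  rs <- detection_radius_series(tibble::tibble(NL = nl), model)
  r_q10 <- detection_radius(stats::qnorm(0.10, 91, 8), model) # quiet tail
  r_q90 <- detection_radius(stats::qnorm(0.90, 91, 8), model)
  expect_equal(unname(rs$exceedance["q10_exceed_m"]), r_q10, tolerance = 0.03)
  expect_equal(unname(rs$exceedance["q90_exceed_m"]), r_q90, tolerance = 0.03)
  # extreme noise floored at the reference distance and flagged
  fl <- detection_radius_series(tibble::tibble(NL = c(91, 220)), model)
  expect_true(fl$radii$floored[2])
})

test_that("visual-acoustic join counts calls per window exhaustively", {
  t0 <- as.POSIXct("2015-07-01 12:00:00", tz = "UTC")
  snaps <- list(
    snapshot_at(t0, 2, mean_nn = 100),
    snapshot_at(t0 + 7200, 3, mean_nn = 600),
    snapshot_at(t0 + 14400, 1, mean_nn = NA)
  )
  calls <- calls_at(
    t0 + c(60, 120, 3599, 7260, 7261, 14460, 20000),
    c("class1_knock", "class3_moan", "class1_knock", "class2_sweep",
      "class3_moan", "class1_knock", "class3_moan")
  )
  jn <- join_visual_acoustic(snaps, calls)
  expect_equal(jn$joined$n_class1, c(2, 0, 1))
  expect_equal(jn$joined$n_class3, c(1, 1, 0))
  expect_equal(jn$joined$n_class2, c(0, 1, 0))
  # call conservation through the join: in-window calls all assigned
  expect_equal(sum(jn$joined$n_class1 + jn$joined$n_class2 + jn$joined$n_class3), 6)
  # rates divide by whales and hours
  expect_equal(jn$joined$rate_class1[1], 1.0) # 2 calls / 1 h / 2 whales

  # calls strictly outside all windows: empty join counts
  far <- join_visual_acoustic(list(snapshot_at(t0, 2)), calls_at(t0 + 90000, "class1_knock"))
  expect_equal(far$joined$n_class1, 0)
  expect_warning(join_visual_acoustic(list(), calls), "no snapshots")
})

test_that("distance-dependent calling is recovered through the full acoustic chain", {
  # generator truth: knock weight falls and moan weight rises with NN
  # distance; the joined rate-vs-distance rank correlations must recover
  # those signs in nearly all replicates
  n_rep <- 40
  knock_neg <- moan_pos <- 0
  t0 <- as.POSIXct("2016-06-01 12:00:00", tz = "UTC")
  for (s in seq_len(n_rep)) {
    set.seed(s + 500)
    dists <- stats::runif(30, 50, 1500)
    snaps <- lapply(seq_along(dists), function(j) {
      snapshot_at(t0 + j * 86400, n_whales = sample(2:6, 1), mean_nn = dists[j])
    })
    calls <- simulate_call_log(simulation_config(seed = s), snaps)
    jn <- join_visual_acoustic(snaps, calls)
    k <- stats::cor(jn$joined$rate_class1, jn$joined$mean_nn_distance, method = "spearman")
    m <- stats::cor(jn$joined$rate_class3, jn$joined$mean_nn_distance, method = "spearman")
    knock_neg <- knock_neg + (!is.na(k) && k < 0)
    moan_pos <- moan_pos + (!is.na(m) && m > 0)
  }
  expect_gte(knock_neg / n_rep, 0.9)
  expect_gte(moan_pos / n_rep, 0.9)
})

test_that("year comparison wrapper returns a Mann-Whitney U result", {
  set.seed(77)
  a <- stats::rpois(30, 3) / 2
  b <- stats::rpois(30, 3) / 2
  ht <- compare_years_call_rates(a, b)
  expect_s3_class(ht, "htest")
  expect_match(ht$method, "Wilcoxon")
})
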