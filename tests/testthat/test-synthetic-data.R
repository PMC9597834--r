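test_that("generator is deterministic and respects limiting configurations", {
  cfg <- small_config(seed = 7L)
  d1 <- simulate_foraging_data(cfg)
  d2 <- simulate_foraging_data(cfg)
  expect_identical(d1$transects, d2$transects)
  expect_identical(d1$catalogue, d2$catalogue)
  expect_identical(d1$units, d2$units)
  expect_identical(d1$calls, d2$calls)

  # zero attraction intensity: the site draws no whales in any year
  d0 <- simulate_prey_whale_dynamics(small_config(seed = 2L, attraction_intensity = 0))
  expect_true(all(d0$transects$n_whales == 0))

  expect_error(
    simulation_config(loyal_return_prob = 1.2),
    "probability"
  )
  expect_error(simulation_config(prey_recovery_rate = -1), "non-negative")
})

test_that("transect counts are non-negative integers within the season window", {
  cfg <- small_config(seed = 3L)
  d <- simulate_prey_whale_dynamics(cfg)
  expect_true(all(d$transects$n_whales >= 0))
  expect_true(all(d$transects$n_whales == round(d$transects$n_whales)))
  len <- as.integer(as.Date("2001-09-06") - as.Date("2001-05-24"))
  expect_true(all(d$transects$day >= 0 & d$transects$day <= len))
  # latent prey never negative, retained in truth
  expect_true(all(d$prey$prey_start >= 0))
  expect_true(all(d$prey$prey_end >= 0))
})

test_that("prey at capacity is a fixed point when removal is zero", {
  cfg <- small_config(seed = 4L, removal_per_whale_day = 0)
  d <- simulate_prey_whale_dynamics(cfg)
  expect_true(all(abs(d$prey$prey_start - cfg$prey_capacity) < 1e-9))
  expect_true(all(abs(d$prey$prey_end - cfg$prey_capacity) < 1e-9))
})

test_that("strong removal with one-winter rebound yields negative lag-1 dependence of annual means", {
  # removal heavy enough to halve the standing prey excess within a high
  # season, recovery fast enough to rebound by the next spring: successive
  # annual means should then alternate, i.e. negative lag-1 autocorrelation
  # (checked against the direct ACF formula, not stats::acf)
  n_neg <- 0
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    cfg <- simulation_config(
      seed = s, n_years = 12L,
      removal_per_whale_day = 0.3, prey_recovery_rate = 1.0
    )
    d <- simulate_prey_whale_dynamics(cfg)
    m <- as.numeric(tapply(d$transects$n_whales, d$transects$year, mean))
    n_neg <- n_neg + (acf_brute(m, 1) < 0)
  }
  expect_gt(n_neg / n_rep, 0.5)
})

test_that("sighting histories cover every whale and respect pool configurations", {
  cfg <- small_config(seed = 5L)
  dyn <- simulate_prey_whale_dynamics(cfg)
  h <- simulate_sighting_histories(cfg, dyn)
  expect_true(all(table(h$catalogue$whale_id) >= 1))
  # conservation: catalogued individuals = loyal used + singles + calves
  expect_setequal(unique(h$catalogue$whale_id), h$whales$whale_id)
  # all sightings inside their season window
  sd <- season_day(h$catalogue$date)
  len <- as.integer(as.Date("2001-09-06") - as.Date("2001-05-24"))
  expect_true(all(sd >= 0 & sd <= len))

  # deterministic pool: every whale returns every year, none single-visit
  dl <- small_config(seed = 6L, loyal_return_prob = 1, single_visit_rate = 0,
                     calf_fraction = 0)
  hl <- simulate_sighting_histories(dl, simulate_prey_whale_dynamics(dl))
  cls <- classify_catalogue(hl$catalogue)
  expect_true(all(cls$per_whale$category == "return"))

  # no loyal pool: everyone is single-visit
  dn <- small_config(seed = 6L, loyal_pool_size = 0L, calf_fraction = 0)
  hn <- simulate_sighting_histories(dn, simulate_prey_whale_dynamics(dn))
  expect_true(all(classify_catalogue(hn$catalogue)$per_whale$category == "single_visit"))

  expect_error(
    simulate_sighting_histories(cfg, list(transects = dyn$transects[0, ], prey = dyn$prey)),
    "empty"
  )
})

test_that("per-year identified individual-days track transect whale counts", {
  cfg <- small_config(seed = 8L)
  dyn <- simulate_prey_whale_dynamics(cfg)
  h <- simulate_sighting_histories(cfg, dyn)
  rt <- residency_table(h$catalogue)
  len <- as.integer(as.Date("2001-09-06") - as.Date("2001-05-24"))
  whale_days <- tapply(rt$residency_days, rt$year, sum) / len
  mean_counts <- tapply(dyn$transects$n_whales, dyn$transects$year, mean)
  yrs <- intersect(names(whale_days), names(mean_counts))
  ratio <- as.numeric(whale_days[yrs]) / pmax(as.numeric(mean_counts[yrs]), 0.5)
  # identified standing stock within a factor ~2.5 of the counted stock
  expect_true(stats::median(ratio) > 0.4 && stats::median(ratio) < 2.5)
})

test_that("locations drift northward through the season and collapse without drift", {
  # positive drift: regression slope of monthly weighted-mean latitude on
  # month positive in nearly all replicates
  pos <- 0
  n_rep <- 40
  for (s in seq_len(n_rep)) {
    cfg <- small_config(seed = s, n_years = 4L)
    u <- simulate_locations(cfg, simulate_prey_whale_dynamics(cfg)$transects)
    wm <- monthly_weighted_means(u)
    fit <- stats::lm(lat ~ month, data = wm)
    pos <- pos + (stats::coef(fit)[["month"]] > 0)
  }
  expect_gte(pos / n_rep, 0.95)

  # zero drift: monthly means coincide with the base centre up to noise
  cfg0 <- small_config(seed = 9L, n_years = 6L, lat_drift_per_month = 0)
  u0 <- simulate_locations(cfg0, simulate_prey_whale_dynamics(cfg0)$transects)
  wm0 <- monthly_weighted_means(u0)
  expect_true(all(abs(wm0$lat - cfg0$base_lat) < 0.02))
})

test_that("call mixture shifts from knocks to moans as whales spread out", {
  cfg <- small_config(seed = 10L)
  dists <- seq(50, 1500, by = 145)
  frac <- t(vapply(seq_along(dists), function(i) {
    snaps <- lapply(1:60, function(j) {
      snapshot_at(as.POSIXct("2015-07-01 12:00:00", tz = "UTC") + j * 86400,
                  n_whales = 4, mean_nn = dists[i])
    })
    cl <- simulate_call_log(simulation_config(seed = i), snaps)
    core <- cl$call_class[cl$call_class != "motherese"]
    c(knock = mean(core == "class1_knock"), moan = mean(core == "class3_moan"))
  }, numeric(2)))
  # monotone trend on binned output: knock fraction decreasing, moan increasing
  expect_lt(stats::cor(dists, frac[, "knock"], method = "spearman"), -0.8)
  expect_gt(stats::cor(dists, frac[, "moan"], method = "spearman"), 0.8)
})

test_that("call log respects zero-whale, pure-knock and motherese rules", {
  cfg <- small_config(seed = 11L)
  empty <- simulate_call_log(cfg, list(snapshot_at("2015-07-01 12:00:00", 0)))
  expect_equal(nrow(empty), 0)

  # extreme proximity: essentially all non-motherese calls are knocks
  # (moan intensity -> 0 as the logistic crossover saturates)
  snaps <- lapply(1:50, function(j) {
    snapshot_at(as.POSIXct("2015-07-01 12:00:00", tz = "UTC") + j * 86400, 5, mean_nn = 1)
  })
  cfg2 <- simulation_config(seed = 12L, call_rate_base = c(0.6, 0, 0.6, 0),
                            knock_distance_scale = 0.1)
  cl <- simulate_call_log(cfg2, snaps)
  core <- cl$call_class[cl$call_class != "motherese"]
  expect_true(all(core == "class1_knock"))

  # motherese only with cow-calf pairs present
  no_pairs <- simulate_call_log(cfg, lapply(1:30, function(j) {
    snapshot_at(as.POSIXct("2015-07-01 12:00:00", tz = "UTC") + j * 86400, 3, n_pairs = 0)
  }))
  expect_false(any(no_pairs$call_class == "motherese"))

  expect_error(
    simulate_call_log(cfg, list(list(timestamp = NULL, n_whales = 2,
                                     n_pairs = 0, mean_nn_distance = 100))),
    "timestamp"
  )
})
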