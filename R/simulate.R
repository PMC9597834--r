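#' Configuration for the synthetic foraging-site generator
#'
#' Bundles every tunable of the synthetic-data generator with validated
#' defaults. The defaults emulate a 20-season coastal gray whale foraging
#' study: a latent mysid prey biomass that whales draw down within a season
#' and that recovers logistically between seasons (so that a heavy foraging
#' year is followed by one or more light years, with full recovery taking
#' 3-4 seasons), a catalogue split into a loyal multi-year pool and
#' single-visit whales recruited in proportion to excess prey, south-to-north
#' within-season drift of foraging locations, and call streams whose
#' knock/moan mixture depends on inter-individual distance.
#'
#' @param seed master integer seed; all sub-generators derive their own
#'   streams from it, so an identical config yields a bit-identical dataset.
#' @param n_years number of survey seasons.
#' @param season_start,season_end season window as `"mm-dd"` strings.
#' @param transects_per_year integer range (length 2) of completed transects
#'   per season.
#' @param prey_capacity carrying capacity of the latent prey biomass
#'   (arbitrary units).
#' @param prey_recovery_rate logistic between-season recovery rate
#'   (fraction/year). The default 0.5 makes recovery from a halved stock take
#'   3-4 seasons.
#' @param removal_per_whale_day prey biomass removed per whale-day.
#' @param whale_attraction_threshold prey level below which the site no
#'   longer attracts foraging whales.
#' @param attraction_intensity expected whales per transect per unit of prey
#'   above the threshold (Poisson intensity scale).
#' @param loyal_pool_size number of whales in the site-loyal pool.
#' @param loyal_return_prob per-year probability a loyal whale uses the site.
#' @param single_visit_rate expected single-visit whales per season per unit
#'   of mean excess prey.
#' @param calf_fraction probability an observed foraging unit is a cow-calf
#'   pair.
#' @param loyal_residency_mean,single_residency_mean,residency_sd mean
#'   within-season residency (days) of loyal and single-visit whales, and its
#'   spread. The 10-day default gap between the pools is the injected truth
#'   that residency-difference estimators are tested against.
#' @param pair_residency_mean mean residency of mothers with calves (days).
#' @param residency_prey_gain days of residency added per standard deviation
#'   of excess prey (couples residency to foraging intensity).
#' @param capture_prob probability a present whale is photo-identified on a
#'   given transect day.
#' @param calf_return_base,calf_return_gain logistic intercept and per-day
#'   slope for the probability a weaned calf returns in later years as a
#'   function of its weaning-season residency.
#' @param base_lat,base_lon bay centre (WGS84 decimal degrees).
#' @param lat_drift_per_month northward drift of the foraging centre per
#'   month (degrees latitude); the within-season south-to-north movement.
#' @param location_sd spatial scatter of foraging units (degrees).
#' @param pair_offset_deg baseline extra displacement of cow-calf pairs from
#'   the foraging corpus (degrees).
#' @param pair_offset_whale_gain growth of the pair displacement per
#'   additional whale present.
#' @param call_rate_base calls/hour/whale for call classes one to four
#'   (knock, sweep, moan, rumble) at the knock-moan crossover distance.
#' @param motherese_rate motherese calls/hour per cow-calf pair present.
#' @param knock_distance_threshold inter-individual distance (m) at which
#'   the call mixture crosses over from knock- to moan-dominated.
#' @param knock_distance_scale logistic scale (m) of the mixture crossover.
#' @param noise_mean,noise_sd per-minute ambient noise level distribution
#'   (dB re 1 uPa).
#' @param source_level_mean,source_level_sd call source level distribution
#'   (dB re 1 uPa at 1 m).
#' @return an object of class `gw_sim_config` (a validated named list).
#' @export
simulation_config <- function(seed = 1L,
                              n_years = 20L,
                              season_start = "05-24",
                              season_end = "09-06",
                              transects_per_year = c(30L, 45L),
                              prey_capacity = 500,
                              prey_recovery_rate = 0.5,
                              removal_per_whale_day = 0.08,
                              whale_attraction_threshold = 130,
                              attraction_intensity = 0.12,
                              loyal_pool_size = 60L,
                              loyal_return_prob = 0.65,
                              single_visit_rate = 0.06,
                              calf_fraction = 0.10,
                              loyal_residency_mean = 28,
                              single_residency_mean = 18,
                              residency_sd = 8,
                              pair_residency_mean = 44,
                              residency_prey_gain = 6,
                              capture_prob = 0.8,
                              calf_return_base = -2,
                              calf_return_gain = 0.05,
                              base_lat = 49.2563,
                              base_lon = -126.1593,
                              lat_drift_per_month = 0.012,
                              location_sd = 0.012,
                              pair_offset_deg = 0.010,
                              pair_offset_whale_gain = 0.15,
                              call_rate_base = c(0.63, 0.65, 0.64, 0.001),
                              motherese_rate = 2.0,
                              knock_distance_threshold = 500,
                              knock_distance_scale = 200,
                              noise_mean = 91,
                              noise_sd = 8,
                              source_level_mean = 156.9,
                              source_level_sd = 11.4) {
  cfg <- as.list(environment())
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (any(!is.finite(num))) stop("all numeric configuration values must be finite", call. = FALSE)
  assert_prob(loyal_return_prob, "loyal_return_prob")
  assert_prob(calf_fraction, "calf_fraction")
  assert_prob(capture_prob, "capture_prob")
  assert_nonneg(prey_capacity, "prey_capacity")
  assert_nonneg(prey_recovery_rate, "prey_recovery_rate")
  assert_nonneg(removal_per_whale_day, "removal_per_whale_day")
  assert_nonneg(attraction_intensity, "attraction_intensity")
  assert_nonneg(single_visit_rate, "single_visit_rate")
  assert_nonneg(call_rate_base, "call_rate_base")
  assert_nonneg(motherese_rate, "motherese_rate")
  stopifnot(
    length(call_rate_base) == 4,
    length(transects_per_year) == 2,
    transects_per_year[1] >= 1,
    transects_per_year[1] <= transects_per_year[2],
    n_years >= 1,
    loyal_pool_size >= 0,
    noise_sd > 0,
    source_level_sd > 0
  )
  if (as.Date(paste0("2000-", season_start)) >= as.Date(paste0("2000-", season_end))) {
    stop("season_start must precede season_end", call. = FALSE)
  }
  structure(cfg, class = "gw_sim_config")
}

#' @export
print.gw_sim_config <- function(x, ...) {
  cat("<gw_sim_config>\n")
  cat(sprintf(
    "  %d seasons (%s to %s), %d-%d transects/season, seed %d\n",
    x$n_years, x$season_start, x$season_end,
    x$transects_per_year[1], x$transects_per_year[2], x$seed
  ))
  cat(sprintf(
    "  prey: capacity %.0f, recovery %.2f/yr, removal %.3f/whale-day, threshold %.0f\n",
    x$prey_capacity, x$prey_recovery_rate, x$removal_per_whale_day,
    x$whale_attraction_threshold
  ))
  cat(sprintf(
    "  catalogue: loyal pool %d (p return %.2f), single-visit rate %.2f\n",
    x$loyal_pool_size, x$loyal_return_prob, x$single_visit_rate
  ))
  invisible(x)
}

season_length_days <- function(config) {
  as.integer(
    as.Date(paste0("2001-", config$season_end)) -
      as.Date(paste0("2001-", config$season_start))
  )
}

#' Simulate coupled prey-whale transect dynamics
#'
#' The latent prey biomass starts at capacity. Within a season each
#' whale-day removes `removal_per_whale_day` units; between seasons the stock
#' recovers logistically toward capacity at `prey_recovery_rate`. The number
#' of whales counted on a transect is Poisson with intensity
#' `attraction_intensity` times the average of the season-arrival prey
#' excess and the current prey excess over `whale_attraction_threshold`
#' (floored at zero): whales select the site on arrival and partially commit
#' to it, so heavy foraging can draw the stock below the attraction
#' threshold before the site empties, while the current-prey component makes
#' counts decline as the season depletes the bay (foraging pressure peaks
#' early to mid-season). Heavy foraging therefore depresses next-season
#' prey and produces the negative lag-1 dependence of annual mean counts that
#' the time-series diagnostics are designed to detect. Five unrecorded
#' burn-in seasons precede the first recorded year so the series starts at
#' the stochastic steady state rather than at pristine capacity.
#'
#' @param config a [simulation_config()].
#' @return a list with `transects`, a tibble (`transect_id`, `year`, `date`,
#'   `day`, `completed`, `n_whales`, `prey`), and `prey`, a per-season tibble
#'   of start/end biomass (retained as generator truth).
#' @export
simulate_prey_whale_dynamics <- function(config) {
  stopifnot(inherits(config, "gw_sim_config"))
  len <- season_length_days(config)
  burn_in <- 5L
  with_seed(sub_seed(config$seed, 1L), {
    prey <- config$prey_capacity
    years <- seq_len(config$n_years) + 1996L
    all_tr <- vector("list", config$n_years)
    prey_log <- vector("list", config$n_years)
    for (i in seq(-burn_in + 1L, length(years))) {
      yr <- if (i >= 1L) years[i] else years[1] + i - 1L
      n_tr <- sample(seq(config$transects_per_year[1], config$transects_per_year[2]), 1)
      days <- sort(sample(0:len, n_tr))
      open <- as.Date(paste0(yr, "-", config$season_start))
      prey_start <- prey
      excess_start <- max(0, prey_start - config$whale_attraction_threshold)
      counts <- integer(n_tr)
      prey_at <- numeric(n_tr)
      prev_day <- 0L
      prev_count <- 0
      for (j in seq_len(n_tr)) {
        # deplete for the whale-days elapsed since the previous transect,
        # using the previous count as the standing whale number
        prey <- max(0, prey - config$removal_per_whale_day * prev_count * (days[j] - prev_day))
        # arrival commitment + current conditions: whales chosen the site at
        # season start only partially leave as the stock declines
        excess_now <- prey - config$whale_attraction_threshold
        lambda <- config$attraction_intensity * max(0, 0.5 * (excess_start + excess_now))
        counts[j] <- stats::rpois(1, lambda)
        prey_at[j] <- prey
        prev_day <- days[j]
        prev_count <- counts[j]
      }
      prey <- max(0, prey - config$removal_per_whale_day * prev_count * (len - prev_day))
      prey_end <- prey
      # between-season logistic recovery toward capacity
      prey <- prey + config$prey_recovery_rate * prey * (1 - prey / config$prey_capacity)
      if (prey <= 0) prey <- 0.01 * config$prey_capacity # recolonisation floor
      prey <- min(prey, config$prey_capacity)
      if (i < 1L) next # burn-in seasons reach the stochastic steady state
      all_tr[[i]] <- tibble::tibble(
        transect_id = sprintf("T%d_%02d", yr, seq_len(n_tr)),
        year = yr,
        date = open + days,
        day = days,
        completed = TRUE,
        n_whales = counts,
        prey = prey_at
      )
      prey_log[[i]] <- tibble::tibble(
        year = yr, prey_start = prey_start, prey_end = prey_end,
        prey_mean = mean(prey_at),
        excess_mean = mean(pmax(0, prey_at - config$whale_attraction_threshold))
      )
    }
    list(
      transects = dplyr::bind_rows(all_tr),
      prey = dplyr::bind_rows(prey_log)
    )
  })
}

#' Simulate photo-identification sighting histories
#'
#' Whales come from two pools. Loyal whales return each year independently
#' with `loyal_return_prob` and hold longer residencies; single-visit whales
#' are recruited each season as a Poisson draw with mean
#' `single_visit_rate * mean excess prey` and are never seen again. A whale
#' present in a season occupies a contiguous residency window and is
#' photo-captured on each transect day inside the window with
#' `capture_prob`. Calves weaned by loyal mothers inherit the site with a
#' probability increasing in their weaning-season residency.
#'
#' @param config a [simulation_config()].
#' @param dynamics result of [simulate_prey_whale_dynamics()] (or a
#'   compatible list with `transects` and `prey`).
#' @return a list with `catalogue`, a long tibble (`whale_id`, `date`), and
#'   `whales`, per-whale metadata (`whale_id`, `pool`, `first_year`,
#'   `is_weaned_calf_first_year`, `mother_id`).
#' @export
simulate_sighting_histories <- function(config, dynamics) {
  stopifnot(inherits(config, "gw_sim_config"))
  transects <- dynamics$transects
  if (is.null(transects) || nrow(transects) == 0) {
    stop("cannot build sighting histories from an empty transect set", call. = FALSE)
  }
  prey <- dynamics$prey
  len <- season_length_days(config)
  with_seed(sub_seed(config$seed, 2L), {
    years <- sort(unique(transects$year))
    excess <- prey$excess_mean[match(years, prey$year)]
    excess_z <- if (stats::sd(excess) > 0) (excess - mean(excess)) / stats::sd(excess) else rep(0, length(excess))
    sightings <- list()
    meta <- list()
    next_calf <- 1L
    pending_calves <- list() # calves weaned, possibly returning later
    for (i in seq_along(years)) {
      yr <- years[i]
      tr_days <- sort(transects$day[transects$year == yr])
      open <- as.Date(paste0(yr, "-", config$season_start))
      res_shift <- config$residency_prey_gain * excess_z[i]

      present <- character(0)
      res_mean <- numeric(0)
      if (config$loyal_pool_size > 0) {
        back <- stats::runif(config$loyal_pool_size) < config$loyal_return_prob
        ids <- sprintf("L%03d", which(back))
        present <- c(present, ids)
        res_mean <- c(res_mean, rep(config$loyal_residency_mean + res_shift, length(ids)))
      }
      n_single <- stats::rpois(1, config$single_visit_rate * excess[i])
      if (n_single > 0) {
        ids <- sprintf("S%d_%02d", yr, seq_len(n_single))
        present <- c(present, ids)
        res_mean <- c(res_mean, rep(config$single_residency_mean + res_shift, n_single))
        meta[[length(meta) + 1]] <- tibble::tibble(
          whale_id = ids, pool = "single", mother_id = NA_character_,
          is_weaned_calf_first_year = FALSE
        )
      }
      # weaned calves that return this year
      if (length(pending_calves)) {
        due <- vapply(pending_calves, function(cl) cl$return_year <= yr, logical(1))
        for (cl in pending_calves[due]) {
          present <- c(present, cl$id)
          res_mean <- c(res_mean, config$loyal_residency_mean + res_shift)
        }
        pending_calves <- pending_calves[!due]
      }
      if (length(present) == 0 || length(tr_days) == 0) next
      span <- pmax(1, pmin(
        len + 1,
        round(stats::rnorm(length(present), res_mean, config$residency_sd))
      ))
      first <- vapply(span, function(s) sample(0:(len + 1 - s), 1), numeric(1))
      last <- first + span - 1
      for (w in seq_along(present)) {
        in_window <- tr_days[tr_days >= first[w] & tr_days <= last[w]]
        seen <- in_window[stats::runif(length(in_window)) < config$capture_prob]
        # guarantee at least one sighting so every generated whale is
        # catalogued (matching photo-ID effort directed at every whale)
        if (length(seen) == 0 && length(in_window) > 0) seen <- sample(in_window, 1)
        if (length(seen) == 0) seen <- tr_days[which.min(abs(tr_days - first[w]))]
        sightings[[length(sightings) + 1]] <- tibble::tibble(
          whale_id = present[w], date = open + seen
        )
      }
      # calf weaning by loyal mothers present this year
      loyal_here <- grep("^L", present, value = TRUE)
      if (length(loyal_here)) {
        weaning <- loyal_here[stats::runif(length(loyal_here)) < config$calf_fraction]
        for (m in weaning) {
          res_m <- span[match(m, present)]
          p_ret <- stats::plogis(config$calf_return_base + config$calf_return_gain * res_m)
          id <- sprintf("C%03d", next_calf)
          next_calf <- next_calf + 1L
          wean_days <- tr_days[stats::runif(length(tr_days)) < config$capture_prob]
          if (length(wean_days) == 0) wean_days <- sample(tr_days, 1)
          sightings[[length(sightings) + 1]] <- tibble::tibble(
            whale_id = id, date = open + wean_days
          )
          meta[[length(meta) + 1]] <- tibble::tibble(
            whale_id = id, pool = "calf", mother_id = m,
            is_weaned_calf_first_year = TRUE
          )
          if (stats::runif(1) < p_ret && yr < max(years)) {
            pending_calves[[length(pending_calves) + 1]] <-
              list(id = id, return_year = yr + sample(1:2, 1))
          }
        }
      }
    }
    catalogue <- dplyr::distinct(dplyr::bind_rows(sightings))
    meta <- dplyr::bind_rows(c(
      list(tibble::tibble(
        whale_id = sprintf("L%03d", seq_len(config$loyal_pool_size)),
        pool = "loyal", mother_id = NA_character_,
        is_weaned_calf_first_year = FALSE
      )),
      meta
    ))
    meta <- meta[meta$whale_id %in% catalogue$whale_id, ]
    first_yr <- catalogue |>
      dplyr::mutate(year = as.integer(format(date, "%Y"))) |>
      dplyr::summarise(first_year = min(year), .by = "whale_id")
    whales <- dplyr::left_join(meta, first_yr, by = "whale_id")
    list(catalogue = catalogue, whales = whales)
  })
}

# partition a whale count into observation units (individuals, groups,
# cow-calf pairs); pairs contribute 1 to the count like individuals
decompose_units <- function(count, calf_fraction) {
  if (count == 0) {
    return(tibble::tibble(
      unit_type = character(0), group_size = integer(0),
      count_contribution = integer(0)
    ))
  }
  n_pairs <- stats::rbinom(1, count, calf_fraction)
  remaining <- count - n_pairs
  sizes <- integer(0)
  while (remaining > 0) {
    s <- min(remaining, sample(c(1L, 1L, 1L, 2L, 3L), 1))
    sizes <- c(sizes, s)
    remaining <- remaining - s
  }
  tibble::tibble(
    unit_type = c(
      rep("cow_calf", n_pairs),
      ifelse(sizes > 1, "group", "individual")
    ),
    group_size = c(rep(2L, n_pairs), sizes),
    count_contribution = c(rep(1L, n_pairs), sizes)
  )
}

#' Simulate foraging-unit locations for each transect
#'
#' Places observation units around the bay centre with a monthly northward
#' drift of the foraging corpus (`lat_drift_per_month`), so weighted-mean
#' latitude is non-decreasing in month in expectation. Cow-calf pairs are
#' displaced away from the corpus by an offset that grows with the number of
#' whales present.
#'
#' @param config a [simulation_config()].
#' @param transects the transect tibble from [simulate_prey_whale_dynamics()].
#' @return a tibble of observation units: `transect_id`, `year`, `date`,
#'   `timestamp`, `unit_id`, `unit_type`, `group_size`, `count_contribution`,
#'   `lat`, `lon`.
#' @export
simulate_locations <- function(config, transects) {
  stopifnot(inherits(config, "gw_sim_config"))
  with_seed(sub_seed(config$seed, 3L), {
    out <- vector("list", nrow(transects))
    for (i in seq_len(nrow(transects))) {
      tr <- transects[i, ]
      units <- decompose_units(tr$n_whales, config$calf_fraction)
      if (nrow(units) == 0) {
        next
      }
      month <- as.integer(format(tr$date, "%m"))
      centre_lat <- config$base_lat + config$lat_drift_per_month * (month - 5L)
      lat <- stats::rnorm(nrow(units), centre_lat, config$location_sd)
      lon <- stats::rnorm(nrow(units), config$base_lon, config$location_sd)
      pairs <- units$unit_type == "cow_calf"
      if (any(pairs)) {
        off <- config$pair_offset_deg *
          (1 + config$pair_offset_whale_gain * tr$n_whales)
        theta <- stats::runif(sum(pairs), 0, 2 * pi)
        lat[pairs] <- lat[pairs] + off * sin(theta)
        lon[pairs] <- lon[pairs] + off * cos(theta)
      }
      out[[i]] <- tibble::tibble(
        transect_id = tr$transect_id,
        year = tr$year,
        date = tr$date,
        timestamp = as.POSIXct(paste(tr$date, "12:00:00"), tz = "UTC") +
          stats::runif(nrow(units), 0, 3600),
        unit_id = sprintf("%s_U%02d", tr$transect_id, seq_len(nrow(units))),
        unit_type = units$unit_type,
        group_size = units$group_size,
        count_contribution = units$count_contribution,
        lat = lat,
        lon = lon
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate a per-minute ambient noise series
#'
#' Ambient noise level for every minute of the requested windows, drawn
#' i.i.d. normal with the configured mean and spread (dB re 1 uPa).
#'
#' @param config a [simulation_config()].
#' @param windows tibble with `start`/`end` POSIXct columns, one row per
#'   recording window.
#' @return a tibble (`minute` POSIXct, `NL` dB re 1 uPa).
#' @export
simulate_noise_series <- function(config, windows) {
  stopifnot(inherits(config, "gw_sim_config"), nrow(windows) >= 1)
  with_seed(sub_seed(config$seed, 4L), {
    mins <- do.call(c, lapply(seq_len(nrow(windows)), function(i) {
      seq(windows$start[i], windows$end[i] - 60, by = 60)
    }))
    tibble::tibble(minute = mins, NL = stats::rnorm(length(mins), config$noise_mean, config$noise_sd))
  })
}

#' Simulate a call log from social snapshots
#'
#' For each snapshot hour, per-whale Poisson event counts are drawn for the
#' four core call classes. The knock (class one) and moan (class three)
#' intensities are modulated by the snapshot's mean nearest-neighbour
#' distance through a logistic crossover at `knock_distance_threshold`:
#' knocks dominate when whales are close, moans when they are far apart,
#' while sweeps (class two) are distance-independent. Motherese calls are
#' emitted only when cow-calf pairs are present.
#'
#' @param config a [simulation_config()].
#' @param snapshots a list of social snapshots as built by
#'   [social_context()], each carrying `timestamp`, `n_whales`, `n_pairs`
#'   and `mean_nn_distance` (NA when fewer than two units).
#' @param window_hours duration of each snapshot window in hours.
#' @return a tibble of calls: `timestamp`, `call_class` (one of
#'   `class1_knock`, `class2_sweep`, `class3_moan`, `class4_rumble`,
#'   `motherese`), `deployment_id`, `transect_id`.
#' @export
simulate_call_log <- function(config, snapshots, window_hours = 1) {
  stopifnot(inherits(config, "gw_sim_config"))
  classes <- c("class1_knock", "class2_sweep", "class3_moan", "class4_rumble")
  with_seed(sub_seed(config$seed, 5L), {
    out <- list()
    for (snap in snapshots) {
      if (is.null(snap$timestamp) || is.na(snap$timestamp)) {
        stop("snapshot without a timestamp", call. = FALSE)
      }
      n <- snap$n_whales
      if (n == 0) next
      d <- snap$mean_nn_distance
      if (is.na(d)) d <- config$knock_distance_threshold # single unit: neutral mixture
      w_knock <- stats::plogis((config$knock_distance_threshold - d) / config$knock_distance_scale)
      w_moan <- 1 - w_knock
      lambda <- config$call_rate_base * window_hours * n
      lambda[1] <- lambda[1] * 2 * w_knock
      lambda[3] <- lambda[3] * 2 * w_moan
      counts <- stats::rpois(4, lambda)
      n_moth <- if (snap$n_pairs > 0) {
        stats::rpois(1, config$motherese_rate * window_hours * snap$n_pairs)
      } else {
        0L
      }
      total <- sum(counts) + n_moth
      if (total == 0) next
      out[[length(out) + 1]] <- tibble::tibble(
        timestamp = snap$timestamp + stats::runif(total, 0, window_hours * 3600),
        call_class = c(rep(classes, counts), rep("motherese", n_moth)),
        deployment_id = sprintf("AMAR%d", as.integer(format(snap$timestamp, "%Y"))),
        transect_id = snap$transect_id %||% NA_character_
      )
    }
    if (length(out) == 0) {
      return(tibble::tibble(
        timestamp = as.POSIXct(character(0), tz = "UTC"),
        call_class = character(0), deployment_id = character(0),
        transect_id = character(0)
      ))
    }
    dplyr::arrange(dplyr::bind_rows(out), timestamp)
  })
}

#' Generate a complete synthetic foraging-site dataset
#'
#' Runs the prey-whale dynamics, sighting-history, location, noise and call
#' generators from one master seed and assembles the result with the
#' generating truth retained for parameter-recovery tests. Acoustic
#' deployments cover the final two seasons, mirroring a study design in
#' which recordings are made in the last years of a long visual series.
#'
#' @param config a [simulation_config()].
#' @return an object of class `gw_dataset`: a list with `transects`,
#'   `units`, `catalogue`, `whales`, `snapshots`, `calls`, `noise` and
#'   `truth`.
#' @export
simulate_foraging_data <- function(config = simulation_config()) {
  stopifnot(inherits(config, "gw_sim_config"))
  dyn <- simulate_prey_whale_dynamics(config)
  hist <- simulate_sighting_histories(config, dyn)
  units <- simulate_locations(config, dyn$transects)

  acoustic_years <- sort(unique(dyn$transects$year))
  acoustic_years <- utils::tail(acoustic_years, 2)
  ac_tr <- dyn$transects[dyn$transects$year %in% acoustic_years, ]
  snapshots <- lapply(seq_len(nrow(ac_tr)), function(i) {
    tr <- ac_tr[i, ]
    u <- units[units$transect_id == tr$transect_id, ]
    snap <- social_context(u)
    snap$timestamp <- as.POSIXct(paste(tr$date, "12:00:00"), tz = "UTC")
    snap$transect_id <- tr$transect_id
    snap$year <- tr$year
    snap
  })
  windows <- tibble::tibble(
    start = as.POSIXct(paste(ac_tr$date, "12:00:00"), tz = "UTC"),
    end = as.POSIXct(paste(ac_tr$date, "13:00:00"), tz = "UTC")
  )
  noise <- if (nrow(windows)) simulate_noise_series(config, windows) else
    tibble::tibble(minute = as.POSIXct(character(0), tz = "UTC"), NL = numeric(0))
  calls <- simulate_call_log(config, snapshots, window_hours = 1)

  structure(
    list(
      transects = dyn$transects,
      units = units,
      catalogue = hist$catalogue,
      whales = hist$whales,
      snapshots = snapshots,
      calls = calls,
      noise = noise,
      truth = list(
        config = config,
        prey = dyn$prey,
        residency_gap_days = config$loyal_residency_mean - config$single_residency_mean
      )
    ),
    class = "gw_dataset"
  )
}

#' @export
print.gw_dataset <- function(x, ...) {
  cat("<gw_dataset>\n")
  cat(sprintf(
    "  %d transects over %d seasons; %d whale observation units\n",
    nrow(x$transects), length(unique(x$transects$year)), nrow(x$units)
  ))
  cat(sprintf(
    "  catalogue: %d individuals, %d sightings\n",
    length(unique(x$catalogue$whale_id)), nrow(x$catalogue)
  ))
  cat(sprintf(
    "  acoustics: %d calls, %d noise minutes\n",
    nrow(x$calls), nrow(x$noise)
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
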