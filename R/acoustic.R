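#' Aural-visual inspection schedule for a deployment
#'
#' Systematic subsampling of a continuous recording: one full 24-h day every
#' fifth day starting from the first full day of the deployment (giving the
#' nominal 20% day coverage), plus the hours concurrent with transect
#' surveys.
#'
#' @param deployment_start,deployment_end POSIXct deployment bounds.
#' @param transect_times optional POSIXct vector of transect start times;
#'   each contributes a `window_hours`-long concurrent window.
#' @param window_hours length of each transect-concurrent window (default 1).
#' @return list: `windows` tibble (`start`, `end`, `type` full_day/transect),
#'   `sampled_days` (Dates of the full-day samples), `day_coverage`
#'   (fraction of full deployment days sampled as full days).
#' @export
av_schedule <- function(deployment_start, deployment_end, transect_times = NULL,
                        window_hours = 1) {
  if (deployment_start >= deployment_end) stop("empty deployment window", call. = FALSE)
  first_date <- as.Date(deployment_start, tz = "UTC")
  # first full day: the day after deployment start unless it starts at 00:00
  first_full <- if (format(deployment_start, "%H:%M:%S") == "00:00:00") {
    first_date
  } else {
    first_date + 1
  }
  last_date <- as.Date(deployment_end, tz = "UTC")
  last_full <- last_date - 1
  if (first_full > last_full) {
    warning("deployment shorter than one full day; empty schedule")
    return(list(
      windows = tibble::tibble(
        start = as.POSIXct(character(0), tz = "UTC"),
        end = as.POSIXct(character(0), tz = "UTC"), type = character(0)
      ),
      sampled_days = as.Date(character(0)), day_coverage = 0
    ))
  }
  full_days <- seq(first_full, last_full, by = "day")
  sampled <- full_days[seq(1, length(full_days), by = 5)]
  win_day <- tibble::tibble(
    start = as.POSIXct(paste(sampled, "00:00:00"), tz = "UTC"),
    end = as.POSIXct(paste(sampled, "00:00:00"), tz = "UTC") + 86400,
    type = "full_day"
  )
  win_tr <- if (!is.null(transect_times) && length(transect_times)) {
    tt <- transect_times[transect_times >= deployment_start & transect_times <= deployment_end]
    tibble::tibble(start = tt, end = tt + window_hours * 3600, type = "transect")
  } else {
    win_day[0, ]
  }
  list(
    windows = dplyr::arrange(dplyr::bind_rows(win_day, win_tr), .data$start),
    sampled_days = sampled,
    day_coverage = length(sampled) / length(full_days)
  )
}

#' Call-class distribution under both denominators
#'
#' Per-class counts and percentages against two denominators: all calls,
#' and non-motherese calls only. Motherese calls are recorded between
#' mothers and calves and are excluded from analyses of foraging-whale
#' acoustic behaviour, so published shares mix the two denominators; both
#' are always reported here. Rows with unknown class labels are dropped
#' with a warning.
#'
#' @param calls tibble with a `call_class` column.
#' @return tibble: `call_class`, `n`, `pct_all`, `pct_non_motherese` (NA for
#'   motherese), plus attributes `n_total` and `n_non_motherese`.
#' @export
class_distribution <- function(calls) {
  valid <- c("class1_knock", "class2_sweep", "class3_moan", "class4_rumble", "motherese")
  cls <- calls$call_class
  bad <- !(cls %in% valid)
  if (any(bad)) {
    warning(sprintf("dropping %d calls with unknown class labels", sum(bad)))
    cls <- cls[!bad]
  }
  counts <- table(factor(cls, levels = valid))
  n_total <- sum(counts)
  n_core <- n_total - counts[["motherese"]]
  out <- tibble::tibble(
    call_class = valid,
    n = as.integer(counts),
    pct_all = if (n_total > 0) 100 * as.integer(counts) / n_total else NA_real_,
    pct_non_motherese = if (n_core > 0) 100 * as.integer(counts) / n_core else NA_real_
  )
  out$pct_non_motherese[out$call_class == "motherese"] <- NA_real_
  attr(out, "n_total") <- n_total
  attr(out, "n_non_motherese") <- n_core
  out
}

#' Per-window calling rate in social context
#'
#' Calls per hour per whale present for each core call class in one
#' observation window. Motherese calls are tabulated but never enter the
#' per-whale rates of foraging behaviour. Rates are undefined (NA) when no
#' whales are present; the counts are retained.
#'
#' @param calls tibble of calls inside the window (`call_class`).
#' @param n_whales whales present during the window.
#' @param window_hours window length in hours (> 0).
#' @return one-row tibble: `window_hours`, `whales_present`, per-class call
#'   counts `n_class1`..`n_class4`, `n_motherese`, and rates
#'   `rate_class1`..`rate_class4` (calls/hour/whale).
#' @export
call_rate <- function(calls, n_whales, window_hours) {
  if (!is.numeric(window_hours) || window_hours <= 0) {
    stop("window_hours must be positive", call. = FALSE)
  }
  core <- c("class1_knock", "class2_sweep", "class3_moan", "class4_rumble")
  counts <- table(factor(calls$call_class, levels = c(core, "motherese")))
  rate <- function(k) {
    if (n_whales >= 1) unname(counts[[k]]) / window_hours / n_whales else NA_real_
  }
  tibble::tibble(
    window_hours = window_hours,
    whales_present = n_whales,
    n_class1 = unname(counts[["class1_knock"]]),
    n_class2 = unname(counts[["class2_sweep"]]),
    n_class3 = unname(counts[["class3_moan"]]),
    n_class4 = unname(counts[["class4_rumble"]]),
    n_motherese = unname(counts[["motherese"]]),
    rate_class1 = rate("class1_knock"),
    rate_class2 = rate("class2_sweep"),
    rate_class3 = rate("class3_moan"),
    rate_class4 = rate("class4_rumble")
  )
}

#' Sonar-equation detection model
#'
#' Passive detection of a call at range `r` from the receiver under the
#' sonar equation `RL = SL - TL(r)` with spherical spreading
#' `TL(r) = 20 log10(r / 1 m)` and the detection rule `RL > NL`. Source
#' level is normal with the given mean and spread; attenuation beyond
#' geometric spreading is neglected (appropriate for low-frequency calls at
#' bay scale).
#'
#' @param SL_mean,SL_sd source level distribution (dB re 1 uPa at 1 m);
#'   defaults 156.9 +- 11.4, the published moan source level.
#' @param n_draws Monte Carlo sample size (default 1e5).
#' @param seed integer seed for the Monte Carlo draws.
#' @return object of class `gw_detection_model`.
#' @export
detection_model <- function(SL_mean = 156.9, SL_sd = 11.4, n_draws = 1e5, seed = 1L) {
  stopifnot(SL_sd > 0, n_draws >= 1)
  structure(
    list(SL_mean = SL_mean, SL_sd = SL_sd, n_draws = as.integer(n_draws), seed = as.integer(seed)),
    class = "gw_detection_model"
  )
}

#' @export
print.gw_detection_model <- function(x, ...) {
  cat(sprintf(
    "<gw_detection_model> SL ~ N(%.1f, %.1f) dB re 1 uPa @ 1 m; spherical spreading; %d MC draws\n",
    x$SL_mean, x$SL_sd, x$n_draws
  ))
  invisible(x)
}

transmission_loss <- function(r) 20 * log10(r)

#' Probability a call is detected at a given range and noise level
#'
#' Estimates `P(SL - 20 log10(r) > NL)` with source level drawn from the
#' model's normal distribution. The Monte Carlo path mirrors the repeated
#' simulation procedure; the closed form is the normal CDF
#' `pnorm((SL_mean - 20 log10(r) - NL) / SL_sd)` and is available as an
#' independent check.
#'
#' @param r range in metres (>= 1, the source-level reference distance).
#' @param NL ambient noise level (dB re 1 uPa).
#' @param model a [detection_model()].
#' @param method `"monte_carlo"` (default) or `"closed_form"`.
#' @return detection probability in `[0, 1]`; vectorised over `r` and `NL`.
#' @export
detection_probability <- function(r, NL, model = detection_model(),
                                  method = c("monte_carlo", "closed_form")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "gw_detection_model"))
  if (any(r < 1)) stop("range must be at least the 1 m reference distance", call. = FALSE)
  margin <- model$SL_mean - transmission_loss(r) - NL
  if (method == "closed_form") {
    return(stats::pnorm(margin / model$SL_sd))
  }
  with_seed(model$seed, {
    sl <- stats::rnorm(model$n_draws, model$SL_mean, model$SL_sd)
    vapply(
      margin,
      function(m) mean(sl - model$SL_mean > -m),
      numeric(1)
    )
  })
}

#' Detection radius at a given probability for one noise level
#'
#' Closed-form range at which the detection probability equals `p`:
#' `r* = 10^((SL_mean - NL + qnorm(1 - p) * SL_sd) / 20)`, reducing to
#' `10^((SL_mean - NL) / 20)` at the p = 0.5 median criterion.
#'
#' @param NL ambient noise level (dB re 1 uPa); vectorised.
#' @param model a [detection_model()].
#' @param p detection probability defining the radius (default 0.5).
#' @return radius in metres, floored at the 1 m reference distance.
#' @export
detection_radius <- function(NL, model = detection_model(), p = 0.5) {
  stopifnot(inherits(model, "gw_detection_model"), p > 0, p < 1)
  r <- 10^((model$SL_mean - NL + stats::qnorm(1 - p) * model$SL_sd) / 20)
  pmax(r, 1)
}

#' Per-minute detection radii and exceedance quantiles
#'
#' Applies [detection_radius()] to every minute of an ambient-noise series
#' and summarises the distribution of radii by exceedance quantiles: the
#' radius exceeded 10% of the time (quiet conditions, the maximum reach)
#' and the radius exceeded 90% of the time (noisy conditions, the floor).
#' Minutes whose noise exceeds `SL_mean + 4 SL_sd` are floored at the 1 m
#' reference and flagged.
#'
#' @param noise tibble with a `NL` column (and optionally `minute`).
#' @param model a [detection_model()].
#' @param p_threshold detection probability defining the radius (default
#'   0.5).
#' @return list of class `gw_radius_series`: `radii` (tibble `minute`, `NL`,
#'   `radius_m`, `floored`), `exceedance` (named: `q10_exceed_m` exceeded
#'   10% of minutes, `median_m`, `q90_exceed_m` exceeded 90% of minutes).
#' @export
detection_radius_series <- function(noise, model = detection_model(), p_threshold = 0.5) {
  stopifnot(nrow(noise) >= 1, "NL" %in% names(noise))
  r <- detection_radius(noise$NL, model, p_threshold)
  floored <- noise$NL >= model$SL_mean + 4 * model$SL_sd
  out <- tibble::tibble(
    minute = if ("minute" %in% names(noise)) noise$minute else seq_len(nrow(noise)),
    NL = noise$NL,
    radius_m = r,
    floored = floored
  )
  structure(
    list(
      radii = out,
      exceedance = c(
        q10_exceed_m = unname(stats::quantile(r, 0.90)),
        median_m = unname(stats::quantile(r, 0.50)),
        q90_exceed_m = unname(stats::quantile(r, 0.10))
      ),
      p_threshold = p_threshold
    ),
    class = "gw_radius_series"
  )
}

#' @export
print.gw_radius_series <- function(x, ...) {
  e <- x$exceedance
  cat(sprintf(
    "<gw_radius_series> %d minutes; radius exceeded 10%% of the time: %.0f m, median %.0f m, exceeded 90%%: %.0f m\n",
    nrow(x$radii), e[["q10_exceed_m"]], e[["median_m"]], e[["q90_exceed_m"]]
  ))
  invisible(x)
}

#' Join visual snapshots with concurrent calls and correlate
#'
#' Pairs each transect snapshot with the calls in its concurrent recording
#' window, computes per-class calls/hour/whale, and reports Spearman rank
#' correlations of each class's rate against the number of whales in the
#' bay, the full-transect whale number (when supplied) and the mean
#' nearest-neighbour distance. Motherese is excluded from the rates.
#'
#' @param snapshots list of `gw_snapshot` objects, each with a `timestamp`
#'   and optionally `transect_total_whales`.
#' @param calls call tibble (`timestamp`, `call_class`).
#' @param window_hours length of each snapshot window (default 1).
#' @return list of class `gw_av_join`: `joined` (one row per snapshot with
#'   counts, rates, `n_whales`, `mean_nn_distance`), `correlations`
#'   (tibble `rate`, `against`, `rs`, `p_value`, `n`).
#' @export
join_visual_acoustic <- function(snapshots, calls, window_hours = 1) {
  rows <- lapply(snapshots, function(snap) {
    if (is.null(snap$timestamp)) stop("snapshot without a timestamp", call. = FALSE)
    in_win <- calls[
      calls$timestamp >= snap$timestamp &
        calls$timestamp < snap$timestamp + window_hours * 3600,
    ]
    cr <- call_rate(in_win, snap$n_whales, window_hours)
    cr$timestamp <- snap$timestamp
    cr$mean_nn_distance <- snap$mean_nn_distance
    cr$n_pairs <- snap$n_pairs
    cr$transect_total_whales <- snap$transect_total_whales %||% NA_real_
    cr
  })
  joined <- dplyr::bind_rows(rows)
  if (nrow(joined) == 0) {
    warning("no snapshots joined; empty result")
    return(structure(list(joined = joined, correlations = NULL), class = "gw_av_join"))
  }
  rate_cols <- c("rate_class1", "rate_class2", "rate_class3")
  against <- c("whales_present", "transect_total_whales", "mean_nn_distance")
  cors <- list()
  for (rc in rate_cols) {
    for (ag in against) {
      ok <- stats::complete.cases(joined[[rc]], joined[[ag]])
      x <- joined[[rc]][ok]
      y <- joined[[ag]][ok]
      if (length(x) < 4 || stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
      cors[[length(cors) + 1]] <- tibble::tibble(
        rate = rc, against = ag,
        rs = unname(ct$estimate), p_value = ct$p.value, n = length(x)
      )
    }
  }
  structure(
    list(joined = joined, correlations = dplyr::bind_rows(cors)),
    class = "gw_av_join"
  )
}

#' @export
print.gw_av_join <- function(x, ...) {
  cat(sprintf("<gw_av_join> %d snapshot windows joined\n", nrow(x$joined)))
  if (!is.null(x$correlations) && nrow(x$correlations)) {
    print(x$correlations)
  }
  invisible(x)
}

#' Compare call rates between two years
#'
#' Thin wrapper around the Mann-Whitney U (Wilcoxon rank-sum) test for
#' whether per-window call rates differ between two deployment years, the
#' check used to justify aggregating years.
#'
#' @param rates_a,rates_b numeric vectors of per-window rates.
#' @return the `htest` result of [stats::wilcox.test()].
#' @export
compare_years_call_rates <- function(rates_a, rates_b) {
  stats::wilcox.test(rates_a, rates_b, exact = FALSE)
}
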