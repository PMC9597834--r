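#' Autocorrelation function with 95% confidence bands
#'
#' Biased (1/n) autocorrelation estimator, the standard definition used for
#' correlograms, with +-1.96/sqrt(n) white-noise bands.
#'
#' @param series numeric vector, longer than `max_lag` and non-constant.
#' @param max_lag largest lag to report.
#' @return tibble with `lag` (0..max_lag), `acf`, `lower`, `upper`.
#' @export
acf_stats <- function(series, max_lag) {
  series <- as.numeric(series)
  n <- length(series)
  if (n <= max_lag) stop("series must be longer than max_lag", call. = FALSE)
  if (stats::sd(series) == 0) stop("ACF undefined for a constant series", call. = FALSE)
  r <- as.numeric(stats::acf(series, lag.max = max_lag, plot = FALSE,
                             demean = TRUE)$acf)
  band <- 1.96 / sqrt(n)
  tibble::tibble(lag = 0:max_lag, acf = r, lower = -band, upper = band)
}

#' Partial autocorrelation function
#'
#' Durbin-Levinson partial autocorrelations; `pacf[1]` equals `acf[1]` by
#' definition.
#'
#' @inheritParams acf_stats
#' @return tibble with `lag` (1..max_lag), `pacf`, `lower`, `upper`.
#' @export
pacf_stats <- function(series, max_lag) {
  series <- as.numeric(series)
  n <- length(series)
  if (n <= max_lag) stop("series must be longer than max_lag", call. = FALSE)
  if (stats::sd(series) == 0) stop("PACF undefined for a constant series", call. = FALSE)
  p <- as.numeric(stats::pacf(series, lag.max = max_lag, plot = FALSE)$acf)
  band <- 1.96 / sqrt(n)
  tibble::tibble(lag = 1:max_lag, pacf = p, lower = -band, upper = band)
}

#' Persistence (naive) forecast residuals
#'
#' The persistence model predicts that the next observation equals the
#' current one; its residuals `obs[t] - obs[t-1]` are examined for structure
#' the model leaves unexplained. The split is chronological: the first
#' `train_fraction` of the series establishes the model (which has no
#' parameters, so the split only fixes the evaluation window) and residuals
#' are computed over the remaining observations, each predicted from its
#' immediate predecessor.
#'
#' @param series numeric vector of length >= 3.
#' @param train_fraction fraction of the series preceding the evaluation
#'   window (default 0.66, i.e. testing on the final 34%). Use 0 to
#'   evaluate over the whole series (residual count = length - 1).
#' @return list with `residuals` (numeric) and `summary`, a one-row tibble
#'   `count`/`mean`/`sd`/`min`/`max`.
#' @export
persistence_residuals <- function(series, train_fraction = 0.66) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 3) stop("persistence residuals need at least 3 observations", call. = FALSE)
  stopifnot(train_fraction >= 0, train_fraction < 1)
  split <- max(1L, as.integer(floor(train_fraction * n)))
  idx <- (split + 1L):n
  res <- series[idx] - series[idx - 1L]
  list(
    residuals = res,
    summary = tibble::tibble(
      count = length(res),
      mean = mean(res),
      sd = stats::sd(res),
      min = min(res),
      max = max(res)
    )
  )
}

# MacKinnon (2010) response-surface critical values for the Dickey-Fuller
# tau statistic, constant-only (drift) and no-constant specifications.
df_critical_values <- function(n, type = c("drift", "none")) {
  type <- match.arg(type)
  cv <- switch(type,
    drift = rbind(
      `1%`  = c(-3.43035, -6.5393, -16.786, -79.433),
      `5%`  = c(-2.86154, -2.8903, -4.234, -40.040),
      `10%` = c(-2.56677, -1.5384, -2.809, 0)
    ),
    none = rbind(
      `1%`  = c(-2.56574, -2.2358, -3.627, 0),
      `5%`  = c(-1.94100, -0.2686, -3.365, 31.223),
      `10%` = c(-1.61682, 0.2656, -2.714, 25.364)
    )
  )
  apply(cv, 1, function(b) b[1] + b[2] / n + b[3] / n^2 + b[4] / n^3)
}

# asymptotic quantiles of the constant-only DF tau distribution (Fuller),
# used for an interpolated p-value
df_tau_quantiles <- list(
  drift = stats::setNames(
    c(-3.43, -3.12, -2.86, -2.57, -2.23, -1.57, -0.94, -0.44, -0.07, 0.23, 0.60),
    c(0.01, 0.025, 0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95, 0.975, 0.99)
  ),
  none = stats::setNames(
    c(-2.58, -2.23, -1.95, -1.62, -1.11, -0.49, 0.09, 0.66, 1.04, 1.36, 1.74),
    c(0.01, 0.025, 0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95, 0.975, 0.99)
  )
)

#' Dickey-Fuller unit-root (stationarity) test
#'
#' Regression of the first difference on the lagged level (with intercept by
#' default), optionally augmented with `lags` lagged differences. The test
#' statistic is the t-ratio on the lagged level; the null hypothesis is a
#' unit root, so rejection indicates a stationary series. Critical values
#' at 1/5/10% come from the MacKinnon response surfaces; the p-value is
#' interpolated on the probability scale from tabulated quantiles of the
#' tau distribution (reported to two useful figures -- values beyond the
#' table are clamped to 0.001/0.999).
#'
#' @param series numeric vector, length >= 10.
#' @param lags number of augmenting lagged differences (default 0, the
#'   non-augmented form).
#' @param type `"drift"` (intercept, the default) or `"none"`.
#' @return list: `statistic`, `p_value`, `critical_values` (named, 1/5/10%),
#'   `lags`, `type`, `n` (effective regression sample size).
#' @export
dickey_fuller_test <- function(series, lags = 0, type = c("drift", "none")) {
  type <- match.arg(type)
  series <- as.numeric(series)
  if (length(series) < 10) stop("Dickey-Fuller test needs at least 10 observations", call. = FALSE)
  if (stats::sd(series) == 0) stop("Dickey-Fuller test undefined for a constant series", call. = FALSE)
  dy <- diff(series)
  y_lag <- series[-length(series)]
  if (lags > 0) {
    n_d <- length(dy)
    keep <- (lags + 1):n_d
    X <- sapply(seq_len(lags), function(k) dy[keep - k])
    dat <- data.frame(dy = dy[keep], y_lag = y_lag[keep], X)
  } else {
    dat <- data.frame(dy = dy, y_lag = y_lag)
  }
  fml <- if (type == "drift") stats::as.formula(dy ~ .) else stats::as.formula(dy ~ . - 1)
  fit <- stats::lm(fml, data = dat)
  ct <- summary(fit)$coefficients
  stat <- ct["y_lag", "t value"]
  n_eff <- nrow(dat)
  q <- df_tau_quantiles[[type]]
  p <- stats::approx(x = q, y = as.numeric(names(q)), xout = stat, rule = 2)$y
  p <- min(max(p, 0.001), 0.999)
  list(
    statistic = unname(stat),
    p_value = unname(p),
    critical_values = df_critical_values(n_eff, type),
    lags = lags,
    type = type,
    n = n_eff
  )
}

#' Wald-Wolfowitz runs test of randomness
#'
#' Dichotomises the series about its median (observations equal to the
#' median are dropped, the standard convention), counts runs of consecutive
#' same-side observations, and compares the count to its expectation under
#' exchangeability with a two-sided normal approximation. Too few runs
#' indicate positive serial dependence; too many indicate alternation.
#'
#' @param series numeric vector with at least 2 observations on each side of
#'   the median after dropping ties.
#' @return list: `runs`, `n_above`, `n_below`, `expected_runs`, `statistic`
#'   (z), `p_value`.
#' @export
runs_test <- function(series) {
  series <- as.numeric(series)
  med <- stats::median(series)
  s <- sign(series - med)
  s <- s[s != 0]
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  if (n1 < 2 || n2 < 2) {
    stop("runs test needs at least 2 observations on each side of the median", call. = FALSE)
  }
  runs <- 1L + sum(diff(s) != 0)
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(sigma2)
  list(
    runs = runs, n_above = n1, n_below = n2,
    expected_runs = mu,
    statistic = z,
    p_value = 2 * stats::pnorm(-abs(z))
  )
}

#' Ljung-Box portmanteau test over a range of lags
#'
#' Box-Ljung statistic for each included lag, testing joint absence of
#' autocorrelation up to that lag. The statistic is nonnegative and
#' nondecreasing in the number of included lags.
#'
#' @param series numeric vector.
#' @param lags integer vector of maximum lags to include (default 1:10).
#' @return tibble with `lag`, `statistic`, `p_value`.
#' @export
ljung_box <- function(series, lags = 1:10) {
  series <- as.numeric(series)
  rows <- lapply(lags, function(k) {
    bt <- stats::Box.test(series, lag = k, type = "Ljung-Box")
    tibble::tibble(lag = k, statistic = unname(bt$statistic), p_value = bt$p.value)
  })
  dplyr::bind_rows(rows)
}

#' Lagged cross-correlation with pairwise deletion
#'
#' Pearson cross-correlation between two aligned (e.g. year-indexed) series
#' at lags `-max_lag..max_lag`. At lag k the value correlates `a[t]` with
#' `b[t - k]`, so a positive lag means `a` follows `b`. Missing values are
#' handled by pairwise deletion; a lag whose overlap after shifting and
#' deletion is below 3 is returned as NA and flagged.
#'
#' @param a,b numeric vectors of equal length (NAs allowed).
#' @param max_lag maximum lag in index units (default 10).
#' @return tibble with `lag`, `r`, `n` (overlap), `defined`.
#' @export
cross_correlation <- function(a, b, max_lag = 10) {
  stopifnot(length(a) == length(b), max_lag >= 0)
  n <- length(a)
  rows <- lapply(-max_lag:max_lag, function(k) {
    ia <- seq_len(n)
    ib <- ia - k
    ok <- ib >= 1 & ib <= n
    x <- a[ia[ok]]
    y <- b[ib[ok]]
    cc <- stats::complete.cases(x, y)
    x <- x[cc]
    y <- y[cc]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      tibble::tibble(lag = k, r = NA_real_, n = length(x), defined = FALSE)
    } else {
      tibble::tibble(lag = k, r = stats::cor(x, y), n = length(x), defined = TRUE)
    }
  })
  dplyr::bind_rows(rows)
}

#' Full time-series diagnostics for a count series
#'
#' Bundles the correlogram, partial correlogram, persistence-forecast
#' residual summary, Dickey-Fuller stationarity test, runs test and
#' Ljung-Box statistics for one series -- the within-season (all transects
#' concatenated across years, treating year boundaries as contiguous) or
#' between-year (annual means) analysis.
#'
#' @param series numeric vector.
#' @param max_lag maximum lag for the correlograms and Ljung-Box (default
#'   20, capped at length - 1).
#' @param train_fraction passed to [persistence_residuals()].
#' @return list of class `gw_diagnostics` with components `acf`, `pacf`,
#'   `residuals`, `residual_summary`, `stationarity`, `runs`, `ljung_box`.
#' @export
diagnose_series <- function(series, max_lag = 20, train_fraction = 0.66) {
  series <- as.numeric(series)
  max_lag <- min(max_lag, length(series) - 1)
  pr <- persistence_residuals(series, train_fraction)
  structure(
    list(
      acf = acf_stats(series, max_lag),
      pacf = pacf_stats(series, max_lag),
      residuals = pr$residuals,
      residual_summary = pr$summary,
      stationarity = dickey_fuller_test(series),
      runs = runs_test(series),
      ljung_box = ljung_box(series, lags = seq_len(max_lag))
    ),
    class = "gw_diagnostics"
  )
}

#' @export
print.gw_diagnostics <- function(x, ...) {
  cat("<gw_diagnostics>\n")
  cat(sprintf(
    "  Dickey-Fuller: statistic %.4f (p ~ %.3f); runs test p = %.3f\n",
    x$stationarity$statistic, x$stationarity$p_value, x$runs$p_value
  ))
  s <- x$residual_summary
  cat(sprintf(
    "  persistence residuals: n %d, mean %.4f, sd %.3f, range [%.1f, %.1f]\n",
    s$count, s$mean, s$sd, s$min, s$max
  ))
  invisible(x)
}
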