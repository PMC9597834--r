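#' Assemble a lagged whale/environment feature table
#'
#' One row per year; each predictor appears at lags 0..`max_lag`, where the
#' lag-k column at year t carries the source value at year t - k. The first
#' `max_lag` years necessarily have missing lagged entries. Whale-derived
#' predictors (mean, maximum, peak date, skew, kurtosis) come from the
#' seasonal summaries; the return proportion from the fidelity summary;
#' environmental columns from the annual index table.
#'
#' @param annual per-season summary tibble (from [summarize_seasons()]).
#' @param fidelity optional `gw_fidelity` (adds `return_proportion`).
#' @param env optional annual environment tibble with a `year` column; all
#'   other numeric columns are carried as predictors.
#' @param max_lag deepest lag in years (default 4, since a season's foraging
#'   pressure can echo for up to four subsequent years).
#' @param response column of `annual` (or `fidelity$per_year`) to use as the
#'   response, default `"mean_whales"`.
#' @return list of class `gw_features`: `table` (tibble: `year`, `response`,
#'   and `<var>_lag<k>` columns), `response_name`, `max_lag`, `variables`.
#' @export
build_lagged_features <- function(annual, fidelity = NULL, env = NULL,
                                  max_lag = 4, response = "mean_whales") {
  stopifnot("year" %in% names(annual))
  if (anyDuplicated(annual$year)) stop("duplicate years in annual summaries", call. = FALSE)
  base <- annual[, intersect(
    c("year", "mean_whales", "max_whales", "peak_date_days", "skewness", "excess_kurtosis"),
    names(annual)
  )]
  if (!is.null(fidelity)) {
    stopifnot(inherits(fidelity, "gw_fidelity"))
    base <- dplyr::left_join(
      base, fidelity$per_year[, c("year", "return_proportion")],
      by = "year"
    )
  }
  if (!is.null(env)) {
    stopifnot("year" %in% names(env))
    if (anyDuplicated(env$year)) stop("duplicate years in environment table", call. = FALSE)
    base <- dplyr::left_join(base, env, by = "year")
  }
  years <- sort(base$year)
  if (!all(diff(years) == 1)) {
    stop("years must form a contiguous run for lagging", call. = FALSE)
  }
  base <- base[order(base$year), ]
  resp <- if (response %in% names(base)) {
    base[[response]]
  } else if (!is.null(fidelity) && response %in% names(fidelity$per_year)) {
    fidelity$per_year[[response]][match(base$year, fidelity$per_year$year)]
  } else {
    stop(sprintf("response `%s` not found", response), call. = FALSE)
  }
  vars <- setdiff(names(base), "year")
  whale_vars <- intersect(vars, c(
    "mean_whales", "max_whales", "peak_date_days", "skewness",
    "excess_kurtosis", "return_proportion"
  ))
  out <- tibble::tibble(year = base$year, response = resp)
  for (v in vars) {
    for (k in 0:max_lag) {
      col <- base[[v]]
      lagged <- c(rep(NA_real_, k), col[seq_len(length(col) - k)])
      out[[sprintf("%s_lag%d", v, k)]] <- lagged
    }
  }
  structure(
    list(
      table = out, response_name = response, max_lag = max_lag,
      variables = vars, whale_vars = whale_vars
    ),
    class = "gw_features"
  )
}

#' @export
print.gw_features <- function(x, ...) {
  cat(sprintf(
    "<gw_features> %d years x %d lagged predictors (max lag %d); response: %s\n",
    nrow(x$table), ncol(x$table) - 2, x$max_lag, x$response_name
  ))
  invisible(x)
}

#' Spearman rank-correlation screen of a feature table
#'
#' Pairwise-complete Spearman correlations between all predictor columns
#' (and the response), with two-sided p-values -- the non-parametric screen
#' applied before any model fitting. Constant columns yield NA and are
#' flagged.
#'
#' @param features a `gw_features` or a plain numeric tibble/data frame.
#' @return list: `rho` (symmetric matrix with unit diagonal), `p` (matrix),
#'   `flagged` (character vector of constant/short columns).
#' @export
spearman_screen <- function(features) {
  tab <- if (inherits(features, "gw_features")) features$table else features
  num <- tab[, vapply(tab, is.numeric, logical(1)), drop = FALSE]
  num <- num[, setdiff(names(num), "year"), drop = FALSE]
  k <- ncol(num)
  rho <- matrix(NA_real_, k, k, dimnames = list(names(num), names(num)))
  pm <- rho
  flagged <- character(0)
  for (i in seq_len(k)) {
    rho[i, i] <- 1
    pm[i, i] <- 0
    xi <- num[[i]]
    if (stats::sd(xi, na.rm = TRUE) == 0 || sum(!is.na(xi)) < 3) {
      flagged <- c(flagged, names(num)[i])
    }
  }
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- stats::complete.cases(num[[i]], num[[j]])
      x <- num[[i]][ok]
      y <- num[[j]][ok]
      if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pm[i, j] <- pm[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = pm, flagged = unique(flagged))
}

#' Rank predictors by univariate smooth-fit importance
#'
#' Fits one penalized-spline GAM per lagged predictor (response ~ s(x)),
#' takes each fit's explained deviance, and normalises the shares to sum
#' to 1. Fitting each predictor alone reads its influence without the
#' influence of the other whale- or environment-based variables; with about
#' twenty annual rows a multi-term fit would be badly overparameterised.
#' Before fitting, predictors are screened for collinearity: within any
#' pair whose pairwise-complete Spearman |rs| exceeds the cap, the later
#' column is dropped. The procedure is deterministic given the data and
#' smoothing configuration (GCV; no randomness).
#'
#' @param features a `gw_features` from [build_lagged_features()].
#' @param k smooth basis dimension (default 5; annual series are short).
#' @param collinearity_cap drop-threshold on pairwise |Spearman rs|
#'   (default 0.95); `1` disables screening.
#' @param include_whale_lag0 keep lag-0 copies of whale-derived variables
#'   (default FALSE: whale metrics enter with a lag of at least one year,
#'   since a season's whale numbers regressed on its own contemporaneous
#'   whale metrics is circular; environmental variables stay available at
#'   lag 0).
#' @param min_rows minimum complete rows required per fit (default 8).
#' @return list of class `gw_importance`: `importance` (tibble `variable`,
#'   `explained_deviance`, `share`, `rank`), `dropped` (collinear columns
#'   removed), `response_name`.
#' @export
rank_variable_importance <- function(features, k = 5, collinearity_cap = 0.95,
                                     include_whale_lag0 = FALSE, min_rows = 8) {
  stopifnot(inherits(features, "gw_features"))
  tab <- features$table
  pred_cols <- setdiff(names(tab), c("year", "response"))
  if (!include_whale_lag0) {
    own <- sprintf("%s_lag0", features$whale_vars %||% features$response_name)
    pred_cols <- setdiff(pred_cols, own)
  } else {
    pred_cols <- setdiff(pred_cols, sprintf("%s_lag0", features$response_name))
  }
  # collinearity screen: keep the earlier column of any near-duplicate pair
  dropped <- character(0)
  if (collinearity_cap < 1 && length(pred_cols) > 1) {
    keep <- pred_cols
    for (i in seq_along(pred_cols)) {
      for (j in seq_along(pred_cols)) {
        if (j <= i) next
        a <- pred_cols[i]
        b <- pred_cols[j]
        if (!(a %in% keep) || !(b %in% keep)) next
        ok <- stats::complete.cases(tab[[a]], tab[[b]])
        if (sum(ok) < 3) next
        x <- tab[[a]][ok]
        y <- tab[[b]][ok]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        rs <- abs(stats::cor(x, y, method = "spearman"))
        if (is.finite(rs) && rs > collinearity_cap) {
          keep <- setdiff(keep, b)
          dropped <- c(dropped, b)
        }
      }
    }
    pred_cols <- keep
  }
  rows <- lapply(pred_cols, function(v) {
    d <- tab[stats::complete.cases(tab$response, tab[[v]]), c("response", v)]
    names(d) <- c("y", "x")
    if (nrow(d) < min_rows || stats::sd(d$x) == 0) {
      return(tibble::tibble(variable = v, explained_deviance = NA_real_))
    }
    k_use <- min(k, length(unique(d$x)) - 1)
    if (nrow(d) <= k_use + 1) {
      stop(sprintf(
        "only %d complete rows for `%s`; reduce the basis dimension `k`",
        nrow(d), v
      ), call. = FALSE)
    }
    if (k_use < 3) {
      return(tibble::tibble(variable = v, explained_deviance = NA_real_))
    }
    fit <- mgcv::gam(y ~ s(x, k = k_use), data = d, method = "GCV.Cp")
    dev <- summary(fit)$dev.expl
    tibble::tibble(variable = v, explained_deviance = max(dev, 0))
  })
  imp <- dplyr::bind_rows(rows)
  tot <- sum(imp$explained_deviance, na.rm = TRUE)
  imp$share <- if (tot > 0) imp$explained_deviance / tot else NA_real_
  imp <- dplyr::arrange(imp, dplyr::desc(.data$share))
  imp$rank <- seq_len(nrow(imp))
  structure(
    list(importance = imp, dropped = dropped, response_name = features$response_name),
    class = "gw_importance"
  )
}

#' @export
print.gw_importance <- function(x, ...) {
  cat(sprintf("<gw_importance> response: %s\n", x$response_name))
  print(utils::head(x$importance, 10))
  invisible(x)
}
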