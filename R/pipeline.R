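#' Analysis configuration
#'
#' Collects the tunable parameters of the exposure-lag-response analysis.
#' Defaults follow the study design: quadratic B-spline with 3 df for the
#' exposure-response curve, natural cubic spline with 5 df for the
#' lag-response curve, a 14-day lag window, a seasonal/trend natural spline
#' with 7 df per year of data, and day-of-week indicators.
#'
#' @param factors Factor column names to analyse (default: all non-date,
#'   non-count columns of the data).
#' @param maxlag Lag window in days.
#' @param var_df,var_degree Exposure-basis dimension and degree.
#' @param lag_df Lag-basis dimension.
#' @param time_df_per_year Seasonal-spline df per year of data.
#' @param time_total_df Override: exact total seasonal-spline df (e.g. 84
#'   for a fixed 7 x 12 specification) instead of the per-year rule.
#' @param dow Include day-of-week indicators?
#' @param dow_ref Reference weekday.
#' @param joint_model Include the cross-bases of all configured factors in
#'   one mutually adjusted model (`TRUE`) or fit one model per factor
#'   (`FALSE`, default — results are reported per factor either way).
#' @param ci_level Confidence level for RR intervals.
#' @param grid_points Size of the uniform exposure grid used for the
#'   minimum-risk search and the surfaces.
#' @param sensitivity_df_per_year Seasonal-spline df values refitted in the
#'   sensitivity analysis.
#' @param mode_precision Named numeric vector: recording precision per
#'   factor for the mode statistic (default 0.1 for unlisted factors).
#' @export
analysis_config <- function(factors = NULL, maxlag = 14L, var_df = 3L,
                            var_degree = 2L, lag_df = 5L,
                            time_df_per_year = 7L, time_total_df = NULL,
                            dow = TRUE, dow_ref = "Mon",
                            joint_model = FALSE, ci_level = 0.95,
                            grid_points = 100L,
                            sensitivity_df_per_year = c(5L, 6L, 7L),
                            mode_precision = NULL) {
  structure(
    list(factors = factors, maxlag = as.integer(maxlag),
         var_df = as.integer(var_df), var_degree = as.integer(var_degree),
         lag_df = as.integer(lag_df),
         time_df_per_year = time_df_per_year, time_total_df = time_total_df,
         dow = dow, dow_ref = dow_ref, joint_model = joint_model,
         ci_level = ci_level, grid_points = as.integer(grid_points),
         sensitivity_df_per_year = sensitivity_df_per_year,
         mode_precision = mode_precision),
    class = "analysis_config")
}

#' Validate a daily time series table
#'
#' Checks the analysis input contract: a `date` column of consecutive
#' calendar days, a non-negative integer `count` column, and at least one
#' numeric factor column. Gaps in the dates are an error (the lag structure
#' assumes contiguity), reported with the missing runs.
#'
#' @param data A data frame with columns `date`, `count` and factor columns.
#' @return The validated data as a tibble with attribute `factors`.
#' @export
daily_series <- function(data) {
  data <- tibble::as_tibble(data)
  for (col in c("date", "count"))
    if (!col %in% names(data))
      stop(sprintf("input is missing required column '%s'", col))
  data$date <- as.Date(data$date)
  if (anyNA(data$date)) stop("column 'date' contains unparseable dates")
  gaps <- which(diff(as.integer(data$date)) != 1L)
  if (length(gaps))
    stop("dates are not consecutive; gap(s) after ",
         paste(format(data$date[utils::head(gaps, 5)]), collapse = ", "))
  if (anyNA(data$count) || any(data$count < 0) ||
      any(data$count != round(data$count)))
    stop("column 'count' must hold non-negative integer counts")
  data$count <- as.integer(data$count)
  factors <- setdiff(names(data), c("date", "count"))
  if (!length(factors)) stop("no factor columns found besides date and count")
  for (f in factors) {
    if (!is.numeric(data[[f]]))
      stop(sprintf("factor column '%s' is not numeric", f))
    if (all(is.na(data[[f]])))
      stop(sprintf("factor column '%s' is entirely missing", f))
  }
  attr(data, "factors") <- factors
  data
}

#' Read a daily series CSV
#'
#' Expects columns `date` (ISO-8601), `count` (integer) and one numeric
#' column per factor; validates via [daily_series()].
#' @param path CSV file path.
#' @export
read_daily_series <- function(path) {
  daily_series(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a daily series CSV
#' @param data A [daily_series()] table.
#' @param path Output path.
#' @export
write_daily_series <- function(data, path) {
  out <- data
  out$date <- format(as.Date(out$date))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# Mode at recording precision; ties broken by the smallest value.
mode_value <- function(x, precision = 0.1) {
  x <- x[!is.na(x)]
  r <- round(round(x / precision) * precision, 10)
  tab <- table(r)
  as.numeric(names(tab)[which.max(tab)])   # which.max takes the first
}

#' Descriptive statistics per factor
#'
#' Mean, SD (n-1 denominator), min, quartiles, max, and the mode computed
#' on values rounded to the recording precision (ties broken by the
#' smallest value).
#'
#' @param data A [daily_series()] table.
#' @param precision Named numeric vector of recording precisions; factors
#'   not listed use 0.1.
#' @return A tibble with one row per factor.
#' @export
descriptive_table <- function(data, precision = NULL) {
  data <- daily_series(data)
  factors <- attr(data, "factors")
  rows <- lapply(factors, function(f) {
    x <- data[[f]]
    prec <- if (!is.null(precision) && f %in% names(precision))
      precision[[f]] else 0.1
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    tibble::tibble(factor = f, mean = mean(x), sd = stats::sd(x),
                   min = min(x), p25 = q[1], p50 = q[2], p75 = q[3],
                   max = max(x), mode = mode_value(x, prec))
  })
  do.call(rbind, rows)
}

# Assemble the full design matrix for one analysed factor:
# intercept + cross-basis (+ other factors' cross-bases when joint),
# seasonal time spline, day-of-week indicators.
build_design <- function(data, factor, config) {
  n <- nrow(data)
  cb <- build_crossbasis(data[[factor]], maxlag = config$maxlag,
                         var_df = config$var_df,
                         var_degree = config$var_degree,
                         lag_df = config$lag_df)
  blocks <- list(`(Intercept)` = matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)")),
                 cb$matrix)
  if (isTRUE(config$joint_model)) {
    others <- setdiff(config$factors %||% attr(data, "factors"), factor)
    for (f in others) {
      ocb <- build_crossbasis(data[[f]], maxlag = config$maxlag,
                              var_df = config$var_df,
                              var_degree = config$var_degree,
                              lag_df = config$lag_df)
      om <- ocb$matrix
      colnames(om) <- paste0(f, ".", ocb$labels)
      blocks <- c(blocks, list(om))
    }
  }
  ts <- time_spline(seq_len(n), df_per_year = config$time_df_per_year,
                    total_df = config$time_total_df)
  blocks <- c(blocks, list(ts))
  if (isTRUE(config$dow))
    blocks <- c(blocks, list(dow_indicators(data$date, ref = config$dow_ref)))
  X <- do.call(cbind, blocks)
  mask <- complete_rows(cb)
  list(X = X, cb = cb, mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full exposure-lag-response analysis for one factor
#'
#' Builds the cross-basis (plus the other factors' cross-bases when
#' `joint_model`), seasonal spline and day-of-week block; fits the
#' quasi-Poisson model; finds the minimum-risk centering value; and emits
#' lag-specific and lag-cumulative RR tables at the factor's min, deciles,
#' max and mode.
#'
#' @param data A [daily_series()] table.
#' @param factor Factor column to analyse.
#' @param config An [analysis_config()].
#' @return List with `fit` ([fit_quasipoisson()]), `center`, `surface`
#'   ([predict_rr()]), `at` (the named exposure values tabulated),
#'   `lag_specific` and `cumulative` tibbles, and `cb`.
#' @export
run_factor_analysis <- function(data, factor, config = analysis_config()) {
  data <- daily_series(data)
  if (!factor %in% attr(data, "factors"))
    stop(sprintf("factor column '%s' not found in the data", factor))
  if (nrow(data) < 730L) stop("need at least two years of daily data")
  des <- build_design(data, factor, config)
  fit <- fit_quasipoisson(data$count, des$X, row_mask = des$mask)
  center <- find_min_risk(fit, des$cb, grid_points = config$grid_points)

  x <- data[[factor]]
  prec <- if (!is.null(config$mode_precision) &&
              factor %in% names(config$mode_precision))
    config$mode_precision[[factor]] else 0.1
  at <- c(min = min(x),
          stats::setNames(stats::quantile(x, seq(0.1, 0.9, by = 0.1),
                                          names = FALSE, type = 7),
                          paste0("p", seq(10, 90, by = 10))),
          max = max(x), mode = mode_value(x, prec))
  grid <- sort(unique(c(seq(min(x), max(x),
                            length.out = config$grid_points),
                        unname(at), center)))
  surface <- predict_rr(fit, des$cb, grid, center, level = config$ci_level)
  tab <- rr_table(surface, at, level = config$ci_level)
  list(fit = fit, center = center, surface = surface, at = at,
       lag_specific = tab[tab$type == "lag", ],
       cumulative = tab[tab$type == "cumulative", ],
       cb = des$cb)
}

#' Seasonal-spline sensitivity analysis
#'
#' Refits the model for each seasonal-spline df-per-year value in
#' `config$sensitivity_df_per_year` and reports the mode-value cumulative
#' (lag 0..maxlag) RR with its CI per fit, flagging sign changes of the
#' log RR relative to the first df.
#'
#' @inheritParams run_factor_analysis
#' @return Tibble with one row per df value.
#' @export
sensitivity_analysis <- function(data, factor, config = analysis_config()) {
  rows <- lapply(config$sensitivity_df_per_year, function(df) {
    cfg <- config
    cfg$time_df_per_year <- df
    cfg$time_total_df <- NULL
    res <- run_factor_analysis(data, factor, cfg)
    cum <- res$cumulative
    row <- cum[cum$value_name == "mode" & cum$lag == config$maxlag, ]
    tibble::tibble(factor = factor, time_df_per_year = df,
                   mode_value = unname(res$at["mode"]),
                   center = res$center,
                   log_rr = log(row$rr),
                   se = (log(row$ci_hi) - log(row$rr)) /
                     stats::qnorm(1 - (1 - config$ci_level) / 2),
                   rr = row$rr, ci_lo = row$ci_lo, ci_hi = row$ci_hi,
                   significant = row$significant)
  })
  out <- do.call(rbind, rows)
  out$sign_change <- sign(out$log_rr) != sign(out$log_rr[1])
  out
}

#' Write the per-factor RR tables
#'
#' One lag-specific and one cumulative CSV per factor (columns
#' `factor_value`, `lag`, `rr`, `ci_lo`, `ci_hi`, `significant`).
#' @param result A [run_factor_analysis()] result.
#' @param factor Factor name (used in file names).
#' @param dir Output directory (created if missing).
#' @export
write_factor_tables <- function(result, factor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$lag_specific,
                   file.path(dir, paste0("lag_specific_", factor, ".csv")),
                   row.names = FALSE)
  utils::write.csv(result$cumulative,
                   file.path(dir, paste0("cumulative_", factor, ".csv")),
                   row.names = FALSE)
  invisible(dir)
}

#' Replicated simulate-fit-predict experiments
#'
#' Repeatedly simulates a study (one factor), fits the full model, and
#' records the overall cumulative log RR with its Wald CI at a fixed
#' exposure value and centering, for CI-coverage and type-I-error studies.
#'
#' @param n_reps Number of replicates.
#' @param n_days Days per replicate.
#' @param surface True surface used to generate counts.
#' @param eval_x Exposure value at which the cumulative log RR is recorded
#'   (`"p10"` to use each replicate's empirical 10th percentile).
#' @param center Centering value used in prediction (a number, or
#'   `"median"` for each replicate's empirical median).
#' @param preset [factor_spec()] for the simulated exposure.
#' @param baseline [baseline_spec()] for the counts.
#' @param config [analysis_config()] used for fitting.
#' @param seed Base seed; replicate `r` uses `seed + r` streams.
#' @return Tibble with columns `rep`, `eval_x`, `log_rr`, `se`, `lo`, `hi`.
#' @export
rr_ci_replicates <- function(n_reps, n_days, surface,
                             eval_x = "p10", center = "median",
                             preset = weather_presets()$mean_temperature,
                             baseline = baseline_spec(dispersion = 1),
                             config = analysis_config(), seed = 1L) {
  z <- stats::qnorm(1 - (1 - config$ci_level) / 2)
  dates <- seq(as.Date("2009-01-01"), by = "day", length.out = n_days)
  rows <- lapply(seq_len(n_reps), function(r) {
    x <- simulate_weather(n_days, preset, seed = seed + 131L * r)
    y <- simulate_counts(x, dates, surface, baseline,
                         seed = seed + 131L * r + 62501L,
                         maxlag = config$maxlag)
    data <- tibble::tibble(date = dates, count = as.integer(y), exposure = x)
    des <- build_design(data, "exposure", config)
    fit <- fit_quasipoisson(data$count, des$X, row_mask = des$mask)
    xe <- if (identical(eval_x, "p10"))
      stats::quantile(x, 0.1, names = FALSE) else eval_x
    ce <- if (identical(center, "median")) stats::median(x) else center
    surf <- predict_rr(fit, des$cb, xe, ce, level = config$ci_level)
    est <- surf$cum_log_rr[1, ncol(surf$cum_log_rr)]
    s <- surf$cum_se[1, ncol(surf$cum_se)]
    tibble::tibble(rep = r, eval_x = xe, log_rr = est, se = s,
                   lo = est - z * s, hi = est + z * s)
  })
  do.call(rbind, rows)
}
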