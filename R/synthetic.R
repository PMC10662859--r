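#' Weather-factor simulation spec
#'
#' One daily meteorological factor is simulated as an annual cosine cycle
#' plus AR(1) Gaussian noise, clipped to physical bounds and rounded to the
#' recording precision:
#' \deqn{x_t = m + a \cos(2\pi (t - p)/365.25) + e_t, \quad
#'       e_t = \rho e_{t-1} + N(0, \sigma^2).}
#'
#' @param name Factor name (column name in the simulated table).
#' @param annual_mean,seasonal_amplitude,phase_day Cycle parameters
#'   (`phase_day` = day index of the seasonal peak).
#' @param ar AR(1) coefficient in `[0, 1)`.
#' @param noise_sd Innovation standard deviation.
#' @param bounds Length-2 physical bounds; simulated values are clipped.
#' @param precision Recording step (e.g. 0.1 degC); values are rounded to it.
#' @param mean_tol,sd_tol Calibration tolerances: the simulated mean/SD of a
#'   study-length series is expected within these of the calibration target.
#' @return An object of class `factor_spec`.
#' @export
factor_spec <- function(name, annual_mean, seasonal_amplitude, phase_day,
                        ar, noise_sd, bounds, precision = 0.1,
                        mean_tol = NA_real_, sd_tol = NA_real_) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2],
            ar >= 0, ar < 1, noise_sd > 0, precision > 0)
  structure(
    list(name = name, annual_mean = annual_mean,
         seasonal_amplitude = seasonal_amplitude, phase_day = phase_day,
         ar = ar, noise_sd = noise_sd, bounds = as.numeric(bounds),
         precision = precision, mean_tol = mean_tol, sd_tol = sd_tol),
    class = "factor_spec")
}

#' Calibrated weather presets
#'
#' Nine [factor_spec()] presets, one per meteorological factor analysed in
#' the study region (a subtropical monsoon coastal climate): mean
#' temperature (degC), relative humidity (%), wind speed (0.1 m/s), mean air
#' pressure (hPa), visibility (km), total cloud cover (%), sunshine duration
#' (h), daily evaporation (mm) and daily average solar radiation (W/m^2).
#' Parameters are calibrated so that a study-length (~4,078-day) simulation
#' reproduces the observed long-run mean and SD of each factor within the
#' stored per-factor tolerances (`mean_tol` = 0.1 SD, `sd_tol` = 0.2 SD);
#' bounded factors (cloud cover, sunshine) pile up at their physical limits,
#' reproducing the observed modes at 100% cover and 0 h sunshine.
#'
#' @return Named list of `factor_spec` objects.
#' @export
weather_presets <- function() {
  p <- list(
    factor_spec("mean_temperature",   23.25, 6.74, 196, 0.85, 1.45,
                c(-5, 40),    0.1, 0.50,  1.00),
    factor_spec("relative_humidity",  74.71, 10.06, 170, 0.80, 6.52,
                c(0, 100),    1,   1.30,  2.60),
    factor_spec("wind_speed",         20.42, 3.59, 350, 0.70, 5.45,
                c(0, 80),     1,   0.80,  1.61),
    factor_spec("mean_air_pressure",  1005.23, 8.13, 15, 0.85, 1.51,
                c(980, 1030), 0.1, 0.64,  1.29),
    factor_spec("visibility",         17.93, 4.95, 300, 0.75, 4.63,
                c(1, 40),     0.1, 0.78,  1.56),
    factor_spec("total_cloud_cover",  65.50, 14.5, 170, 0.75, 16.4,
                c(0, 100),    1,   2.50,  5.00),
    factor_spec("sunshine_duration",  5.02, 3.05, 280, 0.60, 2.75,
                c(0, 12.5),   0.1, 0.38,  0.76),
    factor_spec("daily_evaporation",  3.29, 1.37, 200, 0.60, 1.07,
                c(0, 12),     0.1, 0.16,  0.32),
    factor_spec("solar_radiation",    143.90, 62.5, 180, 0.60, 43.5,
                c(0, 400),    0.1, 6.90, 13.80))
  stats::setNames(p, vapply(p, `[[`, "", "name"))
}

#' Calibration targets for the weather presets
#'
#' The long-run mean and SD each preset is calibrated to reproduce, with
#' its stored tolerances. Used by the calibration checks.
#' @return A tibble with columns `factor`, `target_mean`, `target_sd`,
#'   `mean_tol`, `sd_tol`.
#' @export
calibration_targets <- function() {
  tibble::tibble(
    factor = c("mean_temperature", "relative_humidity", "wind_speed",
               "mean_air_pressure", "visibility", "total_cloud_cover",
               "sunshine_duration", "daily_evaporation", "solar_radiation"),
    target_mean = c(23.25, 74.71, 20.61, 1005.42, 18.09, 64.59, 5.23, 3.30,
                    144.45),
    target_sd = c(5.50, 12.99, 8.04, 6.43, 7.82, 25.05, 3.78, 1.62, 69.18),
    mean_tol = c(0.50, 1.30, 0.80, 0.64, 0.78, 2.50, 0.38, 0.16, 6.90),
    sd_tol = c(1.00, 2.60, 1.61, 1.29, 1.56, 5.00, 0.76, 0.32, 13.80))
}

#' Simulate one weather factor
#'
#' @param n_days Number of consecutive days.
#' @param spec A [factor_spec()].
#' @param seed RNG seed; the same seed reproduces the series exactly.
#' @return Numeric vector of length `n_days`.
#' @export
simulate_weather <- function(n_days, spec, seed) {
  stopifnot(inherits(spec, "factor_spec"), n_days >= 1)
  set.seed(seed)
  e0 <- stats::rnorm(1, 0, spec$noise_sd / sqrt(1 - spec$ar^2))
  eps <- stats::rnorm(n_days, 0, spec$noise_sd)
  e <- as.numeric(stats::filter(eps, spec$ar, method = "recursive",
                                init = e0))
  t <- seq_len(n_days)
  x <- spec$annual_mean +
    spec$seasonal_amplitude * cos(2 * pi * (t - spec$phase_day) / 365.25) + e
  x <- pmin(pmax(x, spec$bounds[1]), spec$bounds[2])
  round(x / spec$precision) * spec$precision
}

#' True exposure-lag-response surface
#'
#' Parametric log-RR surface used as simulation truth: a quadratic exposure
#' term times an exponential lag decay,
#' \deqn{f(x, l) = \gamma \left(\frac{x - x_{ref}}{s}\right)^2 e^{-l/\tau},}
#' zero at the reference exposure for every lag (so `x_ref` is the
#' minimum-risk value when `gamma > 0`), smooth within the span of the
#' default 3 x 5 cross-basis so recovery is achievable.
#'
#' @param gamma Effect size (log-RR at `|x - x_ref| = scale`, lag 0).
#'   `gamma = 0` gives the null surface.
#' @param x_ref Reference (minimum-risk) exposure.
#' @param scale Exposure scale of the quadratic.
#' @param tau Lag-decay constant in days.
#' @return An object of class `true_surface`.
#' @export
true_surface <- function(gamma = 0.12, x_ref = 27, scale = 10, tau = 3) {
  structure(list(gamma = gamma, x_ref = x_ref, scale = scale, tau = tau),
            class = "true_surface")
}

#' @rdname true_surface
#' @export
zero_surface <- function() true_surface(gamma = 0)

#' Evaluate a true surface
#'
#' @param surface A [true_surface()].
#' @param x Exposure values.
#' @param lag Lags in days (recycled against `x`).
#' @return Log relative risk relative to the surface reference.
#' @export
surface_effect <- function(surface, x, lag) {
  stopifnot(inherits(surface, "true_surface"))
  surface$gamma * ((x - surface$x_ref) / surface$scale)^2 * exp(-lag / surface$tau)
}

#' Cumulative true log RR over lags 0..upto
#' @inheritParams surface_effect
#' @param upto Last lag included (default 14).
#' @export
surface_cumulative <- function(surface, x, upto = 14L) {
  rowSums(outer(x, 0:upto, function(xx, ll) surface_effect(surface, xx, ll)))
}

#' Baseline (non-exposure) structure of the daily case counts
#'
#' @param mean_daily_count Baseline mean cases/day (default 863/4078, the
#'   study's overall admission rate).
#' @param seasonal_log_amplitude Amplitude of an annual cosine on the log
#'   rate (peak at `phase_day`).
#' @param phase_day Day index of the seasonal admission peak.
#' @param trend_log_slope Log-linear trend per year.
#' @param dow_log_effects Length-7 log-rate effects `Mon..Sun` (Monday is
#'   the reference, 0). Defaults encode mildly lower weekend admissions.
#' @param dispersion Variance inflation: counts are Poisson at 1, else
#'   negative binomial (NB2) parameterised so `Var = dispersion * mu`.
#' @export
baseline_spec <- function(mean_daily_count = 863 / 4078,
                          seasonal_log_amplitude = 0.15,
                          phase_day = 15,
                          trend_log_slope = 0,
                          dow_log_effects = c(Mon = 0, Tue = 0.05, Wed = 0.05,
                                              Thu = 0.05, Fri = 0.05,
                                              Sat = -0.3, Sun = -0.4),
                          dispersion = 1.2) {
  stopifnot(mean_daily_count > 0, dispersion >= 1,
            length(dow_log_effects) == 7L)
  structure(
    list(mean_daily_count = mean_daily_count,
         seasonal_log_amplitude = seasonal_log_amplitude,
         phase_day = phase_day, trend_log_slope = trend_log_slope,
         dow_log_effects = dow_log_effects, dispersion = dispersion),
    class = "baseline_spec")
}

#' Simulate daily case counts given an exposure series
#'
#' The converse of the analysis model:
#' \deqn{\log \mu_t = \log m + \text{seasonal}_t + \text{trend}_t +
#'   \text{dow}_t + \sum_{l=0}^{14} f(x_{t-l}, l),}
#' with `Y_t ~ Poisson(mu_t)` when `dispersion = 1` and NB2 with
#' `Var = dispersion * mu_t` otherwise. Lags before the series start reuse
#' the first exposure value; the first `maxlag` days are flagged burn-in
#' (attribute `burn_in`) and should be excluded from fitting.
#'
#' @param exposure Daily exposure values (length > `maxlag`).
#' @param dates `Date` vector aligned with `exposure`.
#' @param surface A [true_surface()].
#' @param baseline A [baseline_spec()].
#' @param seed RNG seed.
#' @param maxlag Lag window of the true surface (default 14).
#' @return Integer count vector with attribute `burn_in`.
#' @export
simulate_counts <- function(exposure, dates, surface, baseline, seed,
                            maxlag = 14L) {
  stopifnot(inherits(surface, "true_surface"),
            inherits(baseline, "baseline_spec"),
            length(exposure) > maxlag, length(dates) == length(exposure))
  n <- length(exposure)
  padded <- c(rep(exposure[1], maxlag), exposure)
  s <- vapply(seq_len(n), function(t) {
    x_hist <- padded[(t + maxlag):t]          # lags 0..maxlag
    sum(surface_effect(surface, x_hist, 0:maxlag))
  }, numeric(1))
  doy <- as.POSIXlt(as.Date(dates))$yday + 1
  wd <- as.POSIXlt(as.Date(dates))$wday        # 0 = Sunday
  dow_idx <- ifelse(wd == 0, 7L, wd)           # Mon = 1 ... Sun = 7
  log_mu <- log(baseline$mean_daily_count) +
    baseline$seasonal_log_amplitude *
      cos(2 * pi * (doy - baseline$phase_day) / 365.25) +
    baseline$trend_log_slope * (seq_len(n) - 1) / 365.25 +
    baseline$dow_log_effects[dow_idx] + s
  if (!all(is.finite(log_mu))) stop("non-finite log mean in count simulation")
  mu <- exp(log_mu)
  set.seed(seed)
  y <- if (baseline$dispersion <= 1) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, mu = mu, size = mu / (baseline$dispersion - 1))
  }
  structure(as.integer(y), burn_in = seq_len(maxlag))
}

#' Simulate a complete synthetic study
#'
#' Generates the nine weather factors and a matching daily case-count
#' series from a known true surface acting through one factor, on
#' consecutive calendar dates. Weather and counts use independent seed
#' streams derived from `seed`.
#'
#' @param n_days Number of days (default 4078, the study window length).
#' @param seed Base seed.
#' @param start_date First calendar day.
#' @param surface True surface (default [true_surface()]; use
#'   [zero_surface()] for null data).
#' @param surface_factor Name of the factor the surface acts through.
#' @param baseline A [baseline_spec()].
#' @param presets Weather presets (default [weather_presets()]).
#' @param maxlag Lag window (default 14).
#' @return List with `data` (tibble: `date`, `count`, one column per
#'   factor) and `truth` (surface, baseline, seeds) suitable for
#'   [write_truth_yaml()].
#' @export
simulate_study <- function(n_days = 4078L, seed = 1L,
                           start_date = as.Date("2009-01-01"),
                           surface = true_surface(),
                           surface_factor = "mean_temperature",
                           baseline = baseline_spec(),
                           presets = weather_presets(), maxlag = 14L) {
  stopifnot(surface_factor %in% names(presets))
  dates <- seq(as.Date(start_date), by = "day", length.out = n_days)
  weather <- lapply(seq_along(presets), function(i)
    simulate_weather(n_days, presets[[i]], seed = seed + 97L * i))
  names(weather) <- names(presets)
  count_seed <- seed + 9973L
  counts <- simulate_counts(weather[[surface_factor]], dates, surface,
                            baseline, seed = count_seed, maxlag = maxlag)
  data <- tibble::tibble(date = dates, count = as.integer(counts))
  for (nm in names(weather)) data[[nm]] <- weather[[nm]]
  truth <- list(
    seed = seed, count_seed = count_seed, n_days = n_days,
    start_date = as.character(start_date), maxlag = maxlag,
    surface_factor = surface_factor, surface = unclass(surface),
    baseline = lapply(unclass(baseline), function(v)
      if (is.numeric(v)) as.numeric(v) else v))
  list(data = data, truth = truth)
}

#' Write / read the simulation truth sidecar
#'
#' YAML record of the surface parameters, baseline and seeds of a
#' synthetic study, written next to the simulated CSV.
#' @param truth The `truth` element of [simulate_study()].
#' @param path Output / input file path.
#' @export
write_truth_yaml <- function(truth, path) {
  yaml::write_yaml(truth, path)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @export
read_truth_yaml <- function(path) yaml::read_yaml(path)
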