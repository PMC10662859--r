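test_that("weather simulation is deterministic and degenerates correctly", {
  sp <- weather_presets()$mean_temperature
  x1 <- simulate_weather(500, sp, seed = 7)
  x2 <- simulate_weather(500, sp, seed = 7)
  expect_identical(x1, x2)
  expect_false(identical(x1, simulate_weather(500, sp, seed = 8)))

  # no seasonality, no noise: constant at the annual mean
  flat <- factor_spec("flat", 10, seasonal_amplitude = 0, phase_day = 1,
                      ar = 0, noise_sd = 1e-12, bounds = c(0, 20),
                      precision = 0.1)
  expect_equal(simulate_weather(50, flat, seed = 1), rep(10, 50))
})

test_that("each preset reproduces its calibration mean and SD", {
  tg <- calibration_targets()
  pr <- weather_presets()
  for (i in seq_len(nrow(tg))) {
    f <- tg$factor[i]
    x <- simulate_weather(4078, pr[[f]], seed = 20 + i)
    expect_lt(abs(mean(x) - tg$target_mean[i]), tg$mean_tol[i])
    expect_lt(abs(sd(x) - tg$target_sd[i]), tg$sd_tol[i])
    expect_true(all(x >= pr[[f]]$bounds[1] & x <= pr[[f]]$bounds[2]))
  }
})

test_that("bounded factors reproduce the observed boundary modes", {
  pr <- weather_presets()
  cloud <- simulate_weather(4078, pr$total_cloud_cover, seed = 31)
  sun <- simulate_weather(4078, pr$sunshine_duration, seed = 32)
  expect_equal(crosslag:::mode_value(cloud, 1), 100)
  expect_equal(crosslag:::mode_value(sun, 0.1), 0)
})

test_that("true surface is zero at its reference and decays over lag", {
  sf <- true_surface(gamma = 0.12, x_ref = 27, scale = 10, tau = 3)
  expect_equal(surface_effect(sf, rep(27, 15), 0:14), rep(0, 15))
  expect_gt(surface_effect(sf, 17, 0), surface_effect(sf, 17, 5))
  expect_equal(surface_cumulative(sf, 27), 0)
  expect_equal(surface_cumulative(sf, 17),
               0.12 * sum(exp(-(0:14) / 3)), tolerance = 1e-12)
  expect_equal(surface_effect(zero_surface(), 5, 3), 0)
})

test_that("null Poisson counts concentrate at the expected total", {
  n <- 4078
  m <- 863 / 4078
  dates <- seq(as.Date("2009-01-01"), by = "day", length.out = n)
  bl <- baseline_spec(mean_daily_count = m, seasonal_log_amplitude = 0,
                      dow_log_effects = rep(0, 7), dispersion = 1)
  y <- simulate_counts(rep(20, n), dates, zero_surface(), bl, seed = 77)
  expect_identical(attr(y, "burn_in"), 1:14)
  expect_lt(abs(sum(y) - n * m), 3 * sqrt(n * m))
  # determinism
  expect_identical(as.integer(y),
                   as.integer(simulate_counts(rep(20, n), dates,
                                              zero_surface(), bl, seed = 77)))
})

test_that("NB2 overdispersion delivers Var = dispersion * mu", {
  n <- 20000
  dates <- seq(as.Date("2009-01-01"), by = "day", length.out = n)
  bl <- baseline_spec(mean_daily_count = 2, seasonal_log_amplitude = 0,
                      dow_log_effects = rep(0, 7), dispersion = 2)
  y <- simulate_counts(rep(5, n), dates, zero_surface(), bl, seed = 13)
  expect_equal(mean(y), 2, tolerance = 0.1)
  expect_equal(var(y) / mean(y), 2, tolerance = 0.25)
})

test_that("simulate_study assembles aligned data and a faithful truth sidecar", {
  study <- simulate_study(n_days = 400, seed = 3)
  expect_equal(nrow(study$data), 400)
  expect_setequal(setdiff(names(study$data), c("date", "count")),
                  names(weather_presets()))
  expect_equal(diff(range(diff(as.integer(study$data$date)))), 0)

  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth_yaml(study$truth, path)
  back <- read_truth_yaml(path)
  expect_equal(back$surface$gamma, study$truth$surface$gamma)
  expect_equal(back$seed, 3)
  expect_equal(back$surface_factor, "mean_temperature")

  # weather and count streams are independent: changing the surface leaves
  # the weather untouched
  study0 <- simulate_study(n_days = 400, seed = 3, surface = zero_surface())
  expect_identical(study$data$mean_temperature, study0$data$mean_temperature)
  expect_false(identical(study$data$count, study0$data$count))
})
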