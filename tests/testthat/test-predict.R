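# One moderately sized fitted model shared across the prediction tests.
fit_shared_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      study <- make_small_study(n_days = 1096, seed = 42)
      data <- study$data
      des <- crosslag:::build_design(data, "mean_temperature",
                                     analysis_config())
      fit <- fit_quasipoisson(data$count, des$X, row_mask = des$mask)
      cache <<- list(data = data, cb = des$cb, fit = fit)
    }
    cache
  }
})

test_that("RR is exactly 1 with zero-width CI at the centering value", {
  st <- fit_shared_study()
  center <- 24
  grid <- c(15, 20, center, 30)
  surf <- predict_rr(st$fit, st$cb, grid, center)
  i <- which(grid == center)
  expect_identical(unname(surf$log_rr[i, ]), rep(0, 15))
  expect_identical(unname(surf$se[i, ]), rep(0, 15))
  expect_identical(unname(surf$cum_log_rr[i, ]), rep(0, 15))
  expect_identical(unname(surf$cum_se[i, ]), rep(0, 15))
})

test_that("cumulative log RR is the running sum of lag-specific log RRs", {
  st <- fit_shared_study()
  surf <- predict_rr(st$fit, st$cb, seq(12, 32, length.out = 9), center = 27)
  running <- t(apply(surf$log_rr, 1, cumsum))
  expect_lt(max(abs(surf$cum_log_rr - running)), 1e-12)
})

test_that("delta-method variances equal explicit-loop quadratic forms", {
  st <- fit_shared_study()
  cb <- st$cb
  fit <- st$fit
  center <- 27
  xs <- c(14.2, 22.8, 31.5)
  surf <- predict_rr(fit, cb, xs, center)

  idx <- match(cb$labels, fit$labels)
  V <- fit$vcov[idx, idx]
  Rg <- eval_basis(xs, cb$var_spec)
  Rc <- drop(eval_basis(center, cb$var_spec))
  C <- eval_basis(0:cb$maxlag, cb$lag_spec)
  vx <- cb$var_spec$df; vl <- cb$lag_spec$df
  zvec <- function(ix, l) {
    z <- numeric(vx * vl)
    for (j in 1:vx) for (k in 1:vl)
      z[(j - 1) * vl + k] <- (Rg[ix, j] - Rc[j]) * C[l + 1, k]
    z
  }
  for (ix in seq_along(xs)) {
    # lag-specific variance at a middle lag
    z <- zvec(ix, 7)
    expect_equal(unname(surf$se[ix, 8])^2, drop(t(z) %*% V %*% z),
                 tolerance = 1e-10)
    # cumulative variance over lags 0..14 via the explicit double sum
    acc <- 0
    for (l in 0:14) for (m in 0:14)
      acc <- acc + drop(t(zvec(ix, l)) %*% V %*% zvec(ix, m))
    expect_equal(unname(surf$cum_se[ix, 15])^2, acc, tolerance = 1e-10)
  }
})

test_that("label mismatch between cross-basis and fit errors", {
  st <- fit_shared_study()
  cb2 <- st$cb
  cb2$labels <- paste0("zz_", cb2$labels)
  expect_error(predict_rr(st$fit, cb2, 20, 27), "label mismatch")
})

test_that("find_min_risk locates the true argmin and ignores the provisional center", {
  # high-information validation scenario: a mortality-scale series (8
  # events/day) with a well-curved surface, so the argmin is identifiable
  study <- simulate_study(
    n_days = 2500, seed = 1,
    surface = true_surface(gamma = 0.3, x_ref = 27),
    baseline = baseline_spec(mean_daily_count = 8, dispersion = 1))
  data <- study$data
  des <- crosslag:::build_design(data, "mean_temperature", analysis_config())
  fit <- fit_quasipoisson(data$count, des$X, row_mask = des$mask)
  grid <- seq(min(data$mean_temperature), max(data$mean_temperature),
              length.out = 100)
  center <- find_min_risk(fit, des$cb, grid)
  step <- diff(grid[1:2])
  expect_lt(abs(center - 27), 2 * step + 1e-9)

  # argmin is invariant to the provisional centering (median vs min):
  # the provisional center only shifts the curve by a constant
  surf_med <- predict_rr(fit, des$cb, grid, stats::median(data$mean_temperature))
  surf_min <- predict_rr(fit, des$cb, grid, min(data$mean_temperature))
  expect_equal(which.min(surf_med$cum_log_rr[, 15]),
               which.min(surf_min$cum_log_rr[, 15]))

  # re-centering at the returned value puts its RR at exactly 1
  surf_c <- predict_rr(fit, des$cb, grid, center)
  i <- which.min(abs(grid - center))
  expect_equal(unname(surf_c$cum_log_rr[i, 15]), 0, tolerance = 1e-12)
  expect_lte(min(surf_c$cum_log_rr[, 15]), 0)
})

test_that("null data give a finite, crash-free minimum-risk search", {
  study <- make_small_study(n_days = 1096, seed = 8, surface = zero_surface())
  data <- study$data
  des <- crosslag:::build_design(data, "mean_temperature", analysis_config())
  fit <- fit_quasipoisson(data$count, des$X, row_mask = des$mask)
  center <- find_min_risk(fit, des$cb)
  expect_true(is.finite(center))
})

test_that("rr_table lays out Wald intervals and significance flags", {
  st <- fit_shared_study()
  x <- st$data$mean_temperature
  at <- c(min = min(x), p50 = unname(quantile(x, 0.5, type = 7)),
          max = max(x), mode = crosslag:::mode_value(x, 0.1))
  grid <- sort(unique(c(seq(min(x), max(x), length.out = 50), unname(at), 24)))
  surf <- predict_rr(st$fit, st$cb, grid, center = 24)
  tab <- rr_table(surf, at)

  # shape: each requested value x 15 lags, lag-specific plus cumulative
  expect_equal(nrow(tab), length(at) * 15 * 2)
  expect_setequal(unique(tab$type), c("lag", "cumulative"))

  # CI bounds are exp(log RR +/- 1.959964 se)
  row <- tab[tab$value_name == "p50" & tab$type == "lag" & tab$lag == 3, ]
  i <- which(abs(grid - at[["p50"]]) < 1e-9)
  expect_equal(row$ci_hi,
               exp(unname(surf$log_rr[i, 4] + 1.959964 * surf$se[i, 4])),
               tolerance = 1e-6)
  expect_equal(row$ci_lo,
               exp(unname(surf$log_rr[i, 4] - 1.959964 * surf$se[i, 4])),
               tolerance = 1e-6)

  # a row at the centering value is RR 1 and non-significant
  at_c <- c(center = 24)
  tab_c <- rr_table(surf, at_c)
  expect_true(all(tab_c$rr == 1))
  expect_true(all(!tab_c$significant))

  # requesting a value off the grid errors
  expect_error(rr_table(surf, c(odd = 23.123456)), "not on the surface grid")
})
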