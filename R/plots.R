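#' Overall cumulative exposure-response curve
#'
#' RR over the full lag window (0..maxlag) against exposure, with the Wald
#' confidence ribbon and the centering value marked.
#'
#' @param surface An [predict_rr()] `rr_surface`.
#' @param xlab Exposure axis label.
#' @return A ggplot object.
#' @export
plot_overall_rr <- function(surface, xlab = "exposure") {
  stopifnot(inherits(surface, "rr_surface"))
  z <- stats::qnorm(1 - (1 - surface$level) / 2)
  L <- ncol(surface$cum_log_rr)
  df <- tibble::tibble(
    x = surface$exposure_grid,
    rr = exp(surface$cum_log_rr[, L]),
    lo = exp(surface$cum_log_rr[, L] - z * surface$cum_se[, L]),
    hi = exp(surface$cum_log_rr[, L] + z * surface$cum_se[, L]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$rr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_vline(xintercept = surface$center, linetype = 3) +
    ggplot2::labs(x = xlab, y = sprintf("RR (lag 0-%d)", max(surface$lags)))
}

#' Lag-response curve at one exposure value
#'
#' Lag-specific RR against lag at the grid value nearest `at`.
#'
#' @inheritParams plot_overall_rr
#' @param at Exposure value of interest.
#' @export
plot_lag_rr <- function(surface, at, xlab = "lag (days)") {
  stopifnot(inherits(surface, "rr_surface"))
  z <- stats::qnorm(1 - (1 - surface$level) / 2)
  i <- which.min(abs(surface$exposure_grid - at))
  df <- tibble::tibble(
    lag = surface$lags,
    rr = exp(surface$log_rr[i, ]),
    lo = exp(surface$log_rr[i, ] - z * surface$se[i, ]),
    hi = exp(surface$log_rr[i, ] + z * surface$se[i, ]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$rr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = xlab,
                  y = sprintf("RR at %s", format(surface$exposure_grid[i])))
}
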