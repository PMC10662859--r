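#!/usr/bin/env Rscript
# Per-factor exposure-lag-response analysis: for each of the nine weather
# factors, fit the quasi-Poisson model
#   log E(Y_t) = alpha + cb(x_t, lag 0..14) + ns(time, 7 df/yr) + dow
# find the minimum-risk centering value, and write lag-specific and
# lag-cumulative RR tables at the factor's min, deciles, max and mode.
# Only mean temperature carries a true effect in the synthetic data, so
# its table should show elevated RRs away from ~27 degC while the other
# factors stay null.

suppressPackageStartupMessages(library(crosslag))

data <- read_daily_series("results/synthetic_daily.csv")
truth <- read_truth_yaml("results/synthetic_truth.yaml")
cfg <- analysis_config(mode_precision = c(relative_humidity = 1,
                                          wind_speed = 1,
                                          total_cloud_cover = 1))

summ <- lapply(attr(data, "factors"), function(f) {
  res <- run_factor_analysis(data, f, cfg)
  write_factor_tables(res, f, "results")
  mode_row <- res$cumulative[res$cumulative$value_name == "mode" &
                               res$cumulative$lag == 14, ]
  n_sig <- sum(res$cumulative$significant)
  message(sprintf(
    "%-20s center %8.2f | dispersion %.3f | mode cum RR(0-14) %.3f [%.3f, %.3f] | %d/%d cumulative cells significant",
    f, res$center, res$fit$dispersion, mode_row$rr, mode_row$ci_lo,
    mode_row$ci_hi, n_sig, nrow(res$cumulative)))
  tibble::tibble(factor = f, center = res$center,
                 dispersion = res$fit$dispersion,
                 mode_cum_rr = mode_row$rr, mode_cum_lo = mode_row$ci_lo,
                 mode_cum_hi = mode_row$ci_hi, n_significant = n_sig)
})
summ <- do.call(rbind, summ)
utils::write.csv(summ, "results/factor_summary.csv", row.names = FALSE)

message(sprintf(
  "true surface acts through %s with minimum risk at %g degC; fitted center there: %.2f",
  truth$surface_factor, truth$surface$x_ref,
  summ$center[summ$factor == truth$surface_factor]))
message("wrote per-factor RR tables and results/factor_summary.csv")
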