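#!/usr/bin/env Rscript
# Robustness of the mode-value cumulative RR (lag 0..14) to the seasonal
# spline dimension: refit every factor with 5, 6 and 7 df per year and
# compare. A stable analysis moves the mode-value log RR by well under
# one standard error across the df choices.

suppressPackageStartupMessages(library(crosslag))

data <- read_daily_series("results/synthetic_daily.csv")
cfg <- analysis_config(mode_precision = c(relative_humidity = 1,
                                          wind_speed = 1,
                                          total_cloud_cover = 1))

all_sens <- lapply(attr(data, "factors"), function(f) {
  sens <- sensitivity_analysis(data, f, cfg)
  utils::write.csv(sens, file.path("results",
                                   paste0("sensitivity_", f, ".csv")),
                   row.names = FALSE)
  se_ref <- sens$se[nrow(sens)]
  spread <- if (se_ref > 0)
    (max(sens$log_rr) - min(sens$log_rr)) / se_ref else 0  # mode == center
  message(sprintf("%-20s mode cum log RR across df 5/6/7: %s | spread %.2f SE%s",
                  f, paste(sprintf("%+.3f", sens$log_rr), collapse = " "),
                  spread,
                  if (any(sens$sign_change)) " [sign change]" else ""))
  sens
})
utils::write.csv(do.call(rbind, all_sens), "results/sensitivity_all.csv",
                 row.names = FALSE)
message("wrote per-factor sensitivity tables and results/sensitivity_all.csv")
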