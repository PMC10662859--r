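#!/usr/bin/env Rscript
# Figures for the temperature analysis: the overall cumulative
# exposure-response curve (RR over lag 0..14 against temperature, centered
# at the fitted minimum-risk value) and the lag-response curve at the mode.

suppressPackageStartupMessages({
  library(crosslag)
  library(ggplot2)
})

data <- read_daily_series("results/synthetic_daily.csv")
res <- run_factor_analysis(data, "mean_temperature")
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

p1 <- plot_overall_rr(res$surface, xlab = "mean temperature (degC)") +
  ggtitle("Overall cumulative exposure-response (lag 0-14)")
ggsave("results/figures/overall_mean_temperature.pdf", p1,
       width = 6, height = 4)

p2 <- plot_lag_rr(res$surface, at = res$at[["mode"]]) +
  ggtitle(sprintf("Lag-response at the mode (%.1f degC)",
                  res$at[["mode"]]))
ggsave("results/figures/lag_mode_mean_temperature.pdf", p2,
       width = 6, height = 4)

message("wrote results/figures/{overall,lag_mode}_mean_temperature.pdf")
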