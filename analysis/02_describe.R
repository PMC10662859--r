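#!/usr/bin/env Rscript
# Descriptive statistics of the daily series: mean, SD, min, quartiles,
# max and the mode at each factor's recording precision. The integer-
# recorded factors (humidity, wind speed, cloud cover) use precision 1;
# the rest 0.1. Bounded factors show their boundary pile-ups (cloud-cover
# mode at 100%, sunshine mode at 0 h), as observed series do.

suppressPackageStartupMessages(library(crosslag))

data <- read_daily_series("results/synthetic_daily.csv")
desc <- descriptive_table(
  data, precision = c(relative_humidity = 1, wind_speed = 1,
                      total_cloud_cover = 1))
utils::write.csv(desc, "results/describe.csv", row.names = FALSE)

print(as.data.frame(desc), digits = 4)
message(sprintf("total cases: %d over %d days", sum(data$count), nrow(data)))
message("wrote results/describe.csv")
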