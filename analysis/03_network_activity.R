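#!/usr/bin/env Rscript
# Network-level analysis of the simulated spike trains: whole-network firing
# rate, network-burst detection from the 50-ms histogram (mean + 5 SD
# threshold, 20% participation pruning, adjacent-bin merging), burst-spike
# fraction, low-activity exclusion and maturity staging.

library(motormea)

trains <- read_spikes_csv("scratch/data/spike_trains.csv")
truth <- read_ground_truth("scratch/data/spike_trains.truth.json")

summ <- network_summary(trains)
print(summ)
message(sprintf("planted bursts: %d, detected: %d",
                nrow(truth$true_burst_epochs), summ$n_bursts))
message(sprintf("excluded as low-activity: %s", exclude_low_activity(summ)))

b <- summ$bursts$bursts
b$n_electrodes <- lengths(summ$bursts$participants)
dir.create("results", showWarnings = FALSE)
write.table(b, "results/network_bursts.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

# staging across the recording-day schedule of a longitudinal experiment
days <- c(15, 22, 28, 35, 42, 49, 56, 63, 70)
staging <- data.frame(div = days, stage = classify_stage(days))
write.csv(staging, "results/staging.csv", row.names = FALSE)
message("stage partition: ",
        paste(names(table(staging$stage)), table(staging$stage),
              sep = "=", collapse = ", "))

summary_row <- data.frame(
  firing_rate_hz = summ$firing_rate_hz,
  burst_fraction = summ$burst_fraction,
  n_bursts = summ$n_bursts,
  n_active_electrodes = summ$n_active_electrodes,
  div = summ$div, stage = summ$stage)
write.csv(summary_row, "results/network_summary.csv", row.names = FALSE)
message("wrote results/network_summary.csv, network_bursts.tsv, staging.csv")
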