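#!/usr/bin/env Rscript
# Filter the simulated raw recording (4th-order Butterworth bandpass,
# 300-3,000 Hz, zero-phase) and detect spikes at 7 SD from the mean signal.
# Scores the detections against the generator's ground truth.

library(motormea)

data_dir <- "scratch/data"
rec <- read_raw_csv(file.path(data_dir, "raw_recording.csv"))
truth <- read_ground_truth(file.path(data_dir, "raw_recording.truth.json"))

filtered <- bandpass_filter(rec, filter_settings(4, 300, 3000))
spikes <- detect_spikes(filtered, threshold_sd = 7, dead_time = 0.001)
write_spikes_csv(spikes, file.path("results", "detected_spikes.csv"))

tol <- 0.001
tp <- fp <- fn <- 0
for (id in rec$electrode_ids) {
  tt <- truth$true_spike_times[[id]]
  ft <- spikes$trains[[id]]
  hit <- vapply(tt, function(t0) any(abs(ft - t0) <= tol), logical(1))
  tp <- tp + sum(hit); fn <- fn + sum(!hit)
  fp <- fp + sum(vapply(ft, function(t0) !any(abs(tt - t0) <= tol), logical(1)))
}
message(sprintf("detected %d spikes on %d electrodes", n_spikes(spikes),
                length(spikes$trains)))
message(sprintf("vs ground truth (1-ms tolerance): precision %.3f, recall %.3f",
                tp / (tp + fp), tp / (tp + fn)))
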