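#!/usr/bin/env Rscript
# Generate the synthetic study inputs with known ground truth:
#  - a short raw multichannel recording with embedded spike waveforms,
#  - 60-electrode spike trains with five planted network bursts,
#  - a treated and a sham contraction series for the blockade assay.
# Inputs are bulky and regenerable, so they go to scratch/data/ as CSV plus
# JSON sidecars and ground truth; downstream scripts read them from there.

library(motormea)

seed <- 20260924L
out <- "scratch/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("-- raw recording: 8 electrodes, 20 s at 10 kHz, spikes at 10x noise SD")
set.seed(seed)
sched <- lapply(1:8, function(j) sort(runif(15, 0.5, 19.5)))
names(sched) <- paste0("E", 1:8)
raw <- gen_raw_recording(sched, waveform = spike_waveform(10000, 40),
                         noise_sd = 4, fs = 10000, duration = 20, seed = seed)
write_raw_csv(raw$recording, file.path(out, "raw_recording.csv"))
write_ground_truth(raw$truth, file.path(out, "raw_recording.truth.json"))

message("-- spike trains: 60 electrodes, 240 s, 2 Hz background, 5 planted bursts")
bursts <- lapply(c(30, 70, 110, 150, 190), function(t0)
  burst_spec(t0, 0.5, rate_multiplier = 40, participation = 0.8))
tr <- gen_spike_trains(60, 2, bursts = bursts, duration = 240, seed = seed)
tr$trains$div <- 49L
write_spikes_csv(tr$trains, file.path(out, "spike_trains.csv"))
write_ground_truth(tr$truth, file.path(out, "spike_trains.truth.json"))
message("   total spikes: ", n_spikes(tr$trains))

message("-- contraction series: treated 12.4 -> 1.1 /min, sham 12.4 -> 12.4 /min")
treated <- gen_contraction_series(12.4, 1.1, myotube_id = "treated_1",
                                  group = "treated", seed = seed)
sham <- gen_contraction_series(12.4, 12.4, myotube_id = "sham_1",
                               group = "sham", seed = seed + 1L)
write_events_csv(treated$series, file.path(out, "contractions_treated.csv"))
write_events_csv(sham$series, file.path(out, "contractions_sham.csv"))
write_ground_truth(treated$truth, file.path(out, "contractions_treated.truth.json"))

message("done: inputs written to ", out)
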