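---
title: "MEA network activity and neuromuscular contraction analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MEA network activity and neuromuscular contraction analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motormea)
```

# Scope

`motormea` implements the computational chain used to characterise
engineered neuromuscular co-cultures of iPSC-derived motor neurons: spike
detection on multielectrode-array (MEA) voltage recordings, network-burst
analysis, maturity staging of the cultures, and quantification of myotube
contraction series before and after pharmacological blockade of the
neuromuscular junction (NMJ) with α-bungarotoxin (BTX). Because raw
recordings of this kind are rarely shared, the package pairs every analysis
stage with a seeded synthetic-data generator that emits the ground truth
needed to score that stage.

# Spike detection

## Model and procedure

A recording is a 60-electrode extracellular voltage trace, 4 min at
10 kHz in the reference protocol. The trace is bandpass filtered with a
4th-order Butterworth design from 300 to 3,000 Hz to isolate multi-unit
spiking from field potentials and high-frequency noise. A spike is any
excursion of the filtered trace more than 7 SD from the mean of that
electrode's full trace.

Design choices where the procedure was genuinely open:

* **Zero-phase filtering.** `bandpass_filter()` applies the design forward
  and backward by default. Detected timestamps feed 50-ms bins downstream,
  and a causal 4th-order bandpass would delay spikes by a substantial
  fraction of a bin. The effective magnitude response is then the *square*
  of the single-pass design; `filter_gain()` reports the gain of whichever
  mode is configured, and the test suite checks measured sinusoid
  amplitudes against it in both modes.
* **Threshold polarity.** "More than 7 SD from the mean" is read as
  two-sided (absolute deviation). Extracellular spikes are dominantly
  negative, so a `polarity = "negative"` mode is provided, but the
  two-sided reading is the default because it is the literal one.
* **SD estimator.** The plain SD of the entire trace, not a robust
  (median-based) estimate. At realistic firing rates the spike samples are
  a vanishing fraction of a 4-min trace, so the inflation is negligible; a
  `robust_sd = TRUE` option exists for spike-dense traces.
* **Dead time and event chaining.** Crossing samples separated by at most
  `dead_time` (default 1 ms) belong to the same event, and the event's
  timestamp is its first crossing sample. Chaining on the previous
  *crossing* rather than on the event's first sample matters: when noise is
  very low the 7-SD threshold sits far below the waveform, the excursion
  spans more than the dead time, and anchoring on the event start would
  emit several timestamps for one action potential. The chained rule keeps
  exactly one event per excursion regardless of its duration.
* **Degenerate traces.** A constant trace has SD 0; it yields zero spikes
  and a warning, not an error, so dead electrodes do not abort a batch.

## What the tests show

Detection is verified three ways: equality with an independent
crossing-scan oracle on every fixture; precision and recall ≥ 0.95 with
≤ 1 ms timing error on recordings with waveforms injected at ≥ 10× the
noise SD; and, on pure Gaussian noise, false-positive counts consistent
with the analytic per-sample exceedance probability `2(1 − Φ(k))` (checked
quantitatively at a 4-SD threshold where the expected count is informative,
and at the default 7 SD where it is effectively zero).

# Network bursts

The population firing-rate histogram uses half-open 50-ms bins. A bin is a
burst candidate when its count strictly exceeds the mean bin count plus
5 SD; candidates in which fewer than 20% of the *active* electrodes fire
are pruned; surviving adjacent bins are merged into single bursts.

Open points decided here:

* The histogram mean and SD are computed over **all** bins of the
  recording, empty bins included, and **once**, before pruning.
* "Exceeded" is a strict inequality, so a perfectly flat histogram
  (SD = 0) produces no bursts.
* "Fewer than 20%" is strict: a bin at exactly 20% participation survives.
* An electrode is *active in a bin* when it fires ≥ 1 spike there; an
  electrode is *active on the MEA* when its whole-recording rate is at
  least 0.1 Hz (24 spikes in 4 min). The latter threshold is a documented
  package default — the underlying protocol uses the notion without
  defining it — and it is exposed as `active_min_rate_hz` everywhere.
* Burst boundaries snap to bin edges, and burst spike counts are the sums
  of the constituent bins, which equal an event-level recount because the
  bins partition `[start, end)`.

Whole-recording summaries add the network firing rate (total spikes over
all electrodes divided by duration), the burst-spike fraction (a
synchronization measure in [0, 1]), and a low-activity exclusion rule
(strictly below 0.05 Hz network rate), mirroring the practice of dropping
near-silent early recordings (8 days in vitro) from longitudinal analyses.

Maturity staging maps days in vitro (DIV) to young (15–35), middle-aged
(42–56) and old (63–70) networks. Days in the gaps (36–41, 57–62) and
below 15 return `"unstaged"`: inventing boundaries inside the gaps would
fabricate a precision the staging scheme does not have.

The burst detector is validated by exact equality against a brute-force
mark/prune/merge oracle on ≥ 1,000 randomized small histograms, and by
planted-burst recovery (below).

# Contraction assay

Contraction series are event times per myotube in named observation
windows (`pre`, `post`), with a `treated`/`sham` group label. The
quantities computed are those of a BTX blockade experiment:

* **Selection**: a myotube qualifies when, over a 5-min baseline, it shows
  *strictly more than* 1 contraction/min on average (total > 5) *and* at
  least one contraction in every minute. The two clauses are a literal
  conjunction of the stated criterion.
* **Counting**: events in the half-open `[0, 600)` s of each window.
* **Time course**: counts per half-open 30-s bin; these sum exactly to the
  window count (an accounting identity asserted on every fixture).
* **Percent reduction**: `100 (1 − post/pre)`; undefined (rejected) for a
  zero baseline, negative when activity increases. The worked example
  124 → 11 contractions per 10 min gives 91.13%, i.e. "over 91%".
* **Classification**: `abolished` requires a post count of exactly zero;
  `reduced`/`increased` when the change exceeds a configurable ±10% band;
  `unchanged` otherwise. Only abolition is an externally defined outcome;
  the remaining classes (and the 10% band) are package conventions exposed
  in the configuration.
* **Partial contractions** carry a per-event flag and are tallied
  separately, never merged into full-contraction counts — this preserves
  the qualitative distinction without inventing a weighting.

# Synthetic data: what it emulates, and what it does not

All generators are pure functions of their parameters and an integer seed.

* `gen_raw_recording()`: i.i.d. Gaussian noise per electrode with a
  biphasic waveform (sharp negative lobe, ~0.6 ms, normalised to the
  stated peak amplitude; positive overshoot at 35% of it, ~0.9 ms) added
  at scheduled times. The noise level is a free parameter — no noise
  statistics are available for the reference hardware — so tests state
  signal strength as a multiple of the noise SD rather than in absolute µV.
* `gen_spike_trains()`: homogeneous Poisson background per electrode;
  inside each planted epoch a freshly drawn participation fraction of
  electrodes receives superposed extra Poisson events so the epoch rate is
  exactly `background × multiplier`. Redrawing participants per epoch
  mimics the electrode-to-electrode variability of real network bursts
  without extra parameters.
* `gen_contraction_series()`: Poisson events thinned by a refractory
  period (default 1 s — a myotube cannot re-contract instantaneously).
  The thinned process is a renewal process with gaps
  `refractory + Exp(rate)`; the test suite compares the generator's mean
  percent reduction at the reported treated rates (12.4 → 1.1 events/min
  over 10-min windows) against a frozen Monte-Carlo estimate from that
  independent renewal sampler (89.40%).

These generators reproduce the *statistical structure the analyses
assume* — stationary noise, Poisson firing, step-like rate changes — and
none of the structure they do not: no electrode drift or artifacts, no
bursty single-unit ISI structure outside planted epochs, no waveform
variability or overlapping spikes, no gradual pharmacological onset.
Passing recovery tests therefore demonstrates correctness of the
algorithms under their own assumptions, not robustness to every failure
mode of real MEA data.

## Study conditions used in the recovery suites

Planted-burst recovery runs at the reference recording geometry — 60
electrodes, 240 s, 2 Hz background — with five 0.5-s epochs at 40× rate
and 0.8 participation, over 20 seeds; recovery must be total (recall 1.0,
≤ 5% spurious burst time). Spike-detection recovery uses 20 fixtures of
4 electrodes × 20 s (zero-noise and noise-SD 3 with 40-µV waveforms,
i.e. ≥ 10× SNR); these sizes exercise the full pipeline while keeping the
suite fast, and the statistical bounds (4-SD Poisson bands, 3-SE
Monte-Carlo bands) are computed for the sizes actually run.

# Numerical conventions

All times are seconds as doubles with one origin per file (recordings
start at 0; contraction windows each start at their own 0). Every binning
operation uses half-open intervals `[i·w, (i+1)·w)`, so each event falls
in exactly one bin and bin sums conserve totals; an event exactly at a
recording's final instant is assigned to the last bin rather than dropped.
Timestamps are reported at the sample resolution of the source recording.
Reruns of `run_pipeline()` with an identical configuration produce
byte-identical reports; configuration validation rejects unknown keys and
out-of-range values naming the offending parameter.

# Known limitations

* No spike sorting: electrodes are analysed as multi-unit channels.
* No per-electrode burst detection or connectivity inference.
* The contraction module consumes event lists; detecting contractions from
  video is out of scope.
* Reference-protocol figure-level results from real recordings
  (firing-rate and burst-fraction development curves) cannot be reproduced
  without the original data; they are covered only indirectly by the
  recovery and property suites.
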