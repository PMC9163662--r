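# Independent brute-force oracles the implementation is checked against.
# These deliberately use plain loops and no code from R/.

# Threshold-crossing scan: emit the first sample of each excursion beyond
# mean +/- k*SD; crossings separated by at most dead_time belong to the
# same event.
oracle_scan_spikes <- function(x, fs, threshold_sd = 7, dead_time = 0.001,
                               polarity = "both") {
  mu <- mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(numeric(0))
  thr <- threshold_sd * s
  dead <- round(dead_time * fs)
  out <- integer(0)
  last <- -Inf
  for (i in seq_along(x)) {
    dev <- if (polarity == "both") abs(x[i] - mu) else mu - x[i]
    if (dev > thr) {
      if (i - last > dead) out <- c(out, i)
      last <- i
    }
  }
  (out - 1) / fs
}

# Mark / prune / merge network-burst detection, bin by bin.
oracle_detect_bursts <- function(counts, flags, active_ids, threshold_sd = 5,
                                 min_participation = 0.20) {
  thr <- mean(counts) + threshold_sd * sd(counts)
  marked <- logical(length(counts))
  for (i in seq_along(counts)) {
    if (counts[i] > thr) {
      if (length(active_ids) == 0L) next
      n_act <- 0L
      for (id in active_ids) if (flags[id, i]) n_act <- n_act + 1L
      if (n_act / length(active_ids) >= min_participation) marked[i] <- TRUE
    }
  }
  bursts <- list()
  i <- 1L
  while (i <= length(marked)) {
    if (marked[i]) {
      j <- i
      while (j < length(marked) && marked[j + 1L]) j <- j + 1L
      bursts[[length(bursts) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  bursts
}

# Build a spike_histogram-shaped fixture directly from raw bin counts.
make_histogram <- function(counts, flags, bin_s = 0.05) {
  structure(
    list(counts = counts, flags = flags, bin_s = bin_s,
         n_bins = length(counts), duration = length(counts) * bin_s,
         electrode_ids = rownames(flags)),
    class = "spike_histogram")
}

# Random small burst-detection instance for oracle-equivalence checks.
random_burst_instance <- function(n_bins_max = 200, n_electrodes_max = 10) {
  n_bins <- sample(5:n_bins_max, 1)
  n_e <- sample(2:n_electrodes_max, 1)
  ids <- paste0("E", seq_len(n_e))
  # mostly-quiet background with occasional tall bins so thresholds engage
  counts <- rpois(n_bins, sample(c(0.5, 1, 3), 1))
  hot <- sample(n_bins, max(1, round(n_bins * 0.05)))
  counts[hot] <- counts[hot] + rpois(length(hot), 30)
  flags <- matrix(runif(n_e * n_bins) < 0.3, nrow = n_e,
                  dimnames = list(ids, NULL))
  flags[, hot] <- matrix(runif(n_e * length(hot)) < runif(1, 0.1, 0.9),
                         nrow = n_e)
  # flags must be consistent with counts: a bin with zero spikes has no
  # active electrodes; force at least rough consistency
  flags[, counts == 0] <- FALSE
  list(counts = counts, flags = flags, ids = ids,
       active = sample(ids, sample(seq_len(n_e), 1)))
}

# Contraction series with prescribed per-minute counts in the pre window
# (events placed mid-minute, extras offset within the minute).
series_from_minute_counts <- function(per_min, pre_window = 600) {
  times <- unlist(lapply(seq_along(per_min), function(m) {
    k <- per_min[m]
    if (k == 0) return(numeric(0))
    (m - 1) * 60 + 60 * seq_len(k) / (k + 1)
  }))
  contraction_series(
    data.frame(time_s = times, window = rep("pre", length(times))),
    windows = c(pre = pre_window, post = 600))
}
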