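#' Biphasic extracellular spike waveform template
#'
#' Canonical extracellular action-potential shape: a sharp negative lobe
#' followed by a slower, smaller positive overshoot, about 1.5 ms in total.
#' The negative peak reaches \code{-amplitude}; the positive lobe peaks at
#' \code{0.35 * amplitude}, keeping it below detection threshold when the
#' negative peak sits just above it.
#'
#' @param fs sampling rate in Hz.
#' @param amplitude peak (negative-lobe) amplitude in uV.
#' @param neg_ms,pos_ms durations of the negative and positive lobes (ms).
#' @return numeric vector of waveform samples in uV.
#' @export
spike_waveform <- function(fs = 10000, amplitude = 50,
                           neg_ms = 0.6, pos_ms = 0.9) {
  n_neg <- max(2L, round(fs * neg_ms / 1000))
  n_pos <- max(2L, round(fs * pos_ms / 1000))
  neg <- sin(pi * seq_len(n_neg) / (n_neg + 1))
  pos <- sin(pi * seq_len(n_pos) / (n_pos + 1))
  # normalise each lobe so the peaks hit the stated amplitudes exactly
  c(-amplitude * neg / max(neg), 0.35 * amplitude * pos / max(pos))
}

#' Ground truth emitted by the synthetic generators
#'
#' @param true_spike_times named list of per-electrode sorted spike times (s).
#' @param true_burst_epochs data.frame with \code{start_s}, \code{end_s} and a
#'   list-column \code{participants}; epochs ordered and non-overlapping.
#' @param true_rates named list of the generator's rate parameters.
#' @param seed integer seed the generator was called with.
#' @return object of class \code{ground_truth}.
#' @export
ground_truth <- function(true_spike_times = NULL, true_burst_epochs = NULL,
                         true_rates = NULL, seed = NA_integer_) {
  if (!is.null(true_burst_epochs) && nrow(true_burst_epochs) > 1L) {
    e <- true_burst_epochs
    if (any(e$start_s[-1L] < e$end_s[-nrow(e)]))
      stop("ground-truth burst epochs must be ordered and non-overlapping")
  }
  structure(
    list(true_spike_times = true_spike_times,
         true_burst_epochs = true_burst_epochs,
         true_rates = true_rates, seed = as.integer(seed)),
    class = "ground_truth")
}

#' Planted network-burst specification
#'
#' @param start_s epoch start time in seconds (>= 0).
#' @param duration_s epoch duration in seconds (> 0).
#' @param rate_multiplier factor (>= 1) applied to the background rate for
#'   participating electrodes during the epoch.
#' @param participation fraction of electrodes, in (0, 1], drawn afresh for
#'   each epoch, that take part in the burst.
#' @return object of class \code{burst_spec}.
#' @export
burst_spec <- function(start_s, duration_s, rate_multiplier, participation) {
  if (start_s < 0) stop("start_s must be >= 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (rate_multiplier < 1) stop("rate_multiplier must be >= 1")
  if (participation <= 0 || participation > 1)
    stop("participation must be in (0, 1]")
  structure(list(start_s = start_s, duration_s = duration_s,
                 rate_multiplier = rate_multiplier,
                 participation = participation),
            class = "burst_spec")
}

#' Generate a raw multichannel recording with embedded spike waveforms
#'
#' Produces i.i.d. Gaussian noise per electrode with a spike waveform added
#' at each scheduled time. Identical arguments and seed give bit-identical
#' output. The returned ground truth echoes the schedule.
#'
#' @param spike_schedule named list, one numeric vector of spike times (s)
#'   per electrode; the names become electrode ids.
#' @param waveform waveform samples in uV (see \code{\link{spike_waveform}}).
#' @param noise_sd Gaussian noise SD in uV.
#' @param fs sampling rate in Hz.
#' @param duration recording length in seconds.
#' @param seed integer seed.
#' @return list with elements \code{recording} (\code{raw_recording}) and
#'   \code{truth} (\code{ground_truth}).
#' @export
gen_raw_recording <- function(spike_schedule,
                              waveform = spike_waveform(fs),
                              noise_sd = 5, fs = 10000, duration = 240,
                              seed = 1L) {
  if (is.null(names(spike_schedule)))
    names(spike_schedule) <- paste0("E", seq_along(spike_schedule))
  n_samp <- round(fs * duration)
  if (length(waveform) >= n_samp)
    stop("waveform must be shorter than the recording")
  for (id in names(spike_schedule)) {
    t <- spike_schedule[[id]]
    bad <- t < 0 | t >= duration
    if (any(bad))
      stop("spike schedule time out of range on electrode ", id, ": t = ",
           t[which(bad)[1L]], " s (recording is [0, ", duration, ") s)")
  }
  set.seed(as.integer(seed))
  n_e <- length(spike_schedule)
  x <- matrix(if (noise_sd > 0) rnorm(n_samp * n_e, sd = noise_sd) else 0,
              nrow = n_samp, ncol = n_e)
  wlen <- length(waveform)
  for (j in seq_len(n_e)) {
    for (t in spike_schedule[[j]]) {
      i0 <- round(t * fs) + 1L
      i1 <- min(i0 + wlen - 1L, n_samp)
      x[i0:i1, j] <- x[i0:i1, j] + waveform[seq_len(i1 - i0 + 1L)]
    }
  }
  rec <- raw_recording(x, fs = fs, electrode_ids = names(spike_schedule))
  truth <- ground_truth(
    true_spike_times = lapply(spike_schedule, function(t) sort(as.numeric(t))),
    true_rates = list(noise_sd = noise_sd),
    seed = seed)
  list(recording = rec, truth = truth)
}

#' Generate multielectrode Poisson spike trains with planted network bursts
#'
#' Each electrode fires as a homogeneous Poisson process at
#' \code{background_rate}. Inside each planted epoch a freshly drawn
#' \code{participation} fraction of electrodes fires at
#' \code{background_rate * rate_multiplier} (extra events are superposed on
#' the background, which is itself Poisson, so the epoch rate is exact).
#'
#' @param n_electrodes number of electrodes.
#' @param background_rate per-electrode background rate in Hz (>= 0).
#' @param bursts list of \code{\link{burst_spec}} objects; epochs must lie
#'   within the recording and must not overlap.
#' @param duration recording length in seconds.
#' @param seed integer seed.
#' @return list with elements \code{trains} (\code{spike_train_set}) and
#'   \code{truth} (\code{ground_truth} carrying the epochs and the chosen
#'   participants).
#' @export
gen_spike_trains <- function(n_electrodes = 60, background_rate = 2,
                             bursts = list(), duration = 240, seed = 1L) {
  if (background_rate < 0) stop("background_rate must be >= 0")
  ids <- paste0("E", seq_len(n_electrodes))
  if (length(bursts)) {
    stopifnot(all(vapply(bursts, inherits, logical(1), "burst_spec")))
    starts <- vapply(bursts, `[[`, numeric(1), "start_s")
    ends <- starts + vapply(bursts, `[[`, numeric(1), "duration_s")
    o <- order(starts)
    bursts <- bursts[o]; starts <- starts[o]; ends <- ends[o]
    if (any(ends > duration)) stop("burst epoch extends past the recording")
    if (length(bursts) > 1L && any(starts[-1L] < ends[-length(ends)]))
      stop("burst specs overlap")
  }
  set.seed(as.integer(seed))
  trains <- lapply(ids, function(id) {
    n <- rpois(1L, background_rate * duration)
    sort(runif(n, 0, duration))
  })
  names(trains) <- ids
  epochs <- data.frame(start_s = numeric(0), end_s = numeric(0))
  participants <- list()
  for (b in bursts) {
    k <- max(1L, round(b$participation * n_electrodes))
    chosen <- sort(sample(ids, k))
    extra_rate <- background_rate * (b$rate_multiplier - 1)
    for (id in chosen) {
      n <- rpois(1L, extra_rate * b$duration_s)
      if (n > 0) {
        t <- runif(n, b$start_s, b$start_s + b$duration_s)
        trains[[id]] <- sort(c(trains[[id]], t))
      }
    }
    epochs <- rbind(epochs,
                    data.frame(start_s = b$start_s,
                               end_s = b$start_s + b$duration_s))
    participants[[length(participants) + 1L]] <- chosen
  }
  epochs$participants <- participants
  truth <- ground_truth(
    true_spike_times = trains,
    true_burst_epochs = epochs,
    true_rates = list(background_rate = background_rate,
                      rate_multipliers =
                        vapply(bursts, `[[`, numeric(1), "rate_multiplier")),
    seed = seed)
  list(trains = spike_train_set(trains, duration = duration), truth = truth)
}

# Poisson events on [0, window) thinned by a refractory period: after a kept
# event, candidates closer than `refractory` to it are dropped.
thin_poisson_events <- function(rate_hz, window_s, refractory) {
  n <- rpois(1L, rate_hz * window_s)
  t <- sort(runif(n, 0, window_s))
  if (refractory <= 0 || length(t) < 2L) return(t)
  kept <- t[1L]
  last <- t[1L]
  for (x in t[-1L]) {
    if (x - last >= refractory) {
      kept <- c(kept, x)
      last <- x
    }
  }
  kept
}

#' Generate a pre/post contraction event series for one myotube
#'
#' Events are homogeneous Poisson within each window, thinned by a
#' refractory period (a myotube cannot re-contract instantaneously), with
#' independent pre- and post-intervention windows and condition labels
#' attached. Times are relative to their own window start.
#'
#' @param rate_pre,rate_post event rates in events per minute (>= 0).
#' @param pre_window,post_window window lengths in seconds (> 0).
#' @param refractory minimum gap between kept events in seconds (>= 0);
#'   default 1 s.
#' @param myotube_id label.
#' @param group \code{"treated"} or \code{"sham"}.
#' @param seed integer seed.
#' @return list with elements \code{series} (\code{contraction_series}) and
#'   \code{truth} (\code{ground_truth} carrying the rate parameters).
#' @export
gen_contraction_series <- function(rate_pre = 12.4, rate_post = 1.1,
                                   pre_window = 600, post_window = 600,
                                   refractory = 1, myotube_id = "myotube",
                                   group = "treated", seed = 1L) {
  if (rate_pre < 0 || rate_post < 0) stop("rates must be >= 0")
  if (pre_window <= 0 || post_window <= 0)
    stop("window lengths must be positive")
  if (refractory < 0) stop("refractory must be >= 0")
  set.seed(as.integer(seed))
  pre <- thin_poisson_events(rate_pre / 60, pre_window, refractory)
  post <- thin_poisson_events(rate_post / 60, post_window, refractory)
  events <- data.frame(
    time_s = c(pre, post),
    window = rep(c("pre", "post"), c(length(pre), length(post))),
    partial = FALSE)
  series <- contraction_series(
    events, windows = c(pre = pre_window, post = post_window),
    myotube_id = myotube_id, group = group)
  truth <- ground_truth(
    true_rates = list(rate_pre_per_min = rate_pre,
                      rate_post_per_min = rate_post,
                      refractory_s = refractory),
    seed = seed)
  list(series = series, truth = truth)
}
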