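#' Multichannel raw extracellular recording
#'
#' Container for a multichannel voltage trace. Samples are stored as a
#' numeric matrix with one column per electrode and one row per sample;
#' all channels share the sampling rate, so every column has length
#' \code{round(fs * duration)}.
#'
#' @param samples numeric matrix, samples in rows, electrodes in columns (uV).
#' @param fs sampling frequency in Hz.
#' @param electrode_ids character vector of electrode labels; defaults to
#'   \code{"E1"..."En"} or the matrix column names.
#' @return an object of class \code{raw_recording} with fields
#'   \code{samples}, \code{fs}, \code{duration}, \code{electrode_ids}.
#' @export
raw_recording <- function(samples, fs, electrode_ids = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(electrode_ids)) {
    electrode_ids <- colnames(samples)
    if (is.null(electrode_ids))
      electrode_ids <- paste0("E", seq_len(ncol(samples)))
  }
  if (length(electrode_ids) != ncol(samples))
    stop("electrode_ids length (", length(electrode_ids),
         ") does not match electrode count (", ncol(samples), ")")
  colnames(samples) <- electrode_ids
  structure(
    list(samples = samples, fs = fs, duration = nrow(samples) / fs,
         electrode_ids = as.character(electrode_ids)),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d electrodes, %.6g s at %g Hz (%d samples)\n",
              ncol(x$samples), x$duration, x$fs, nrow(x$samples)))
  invisible(x)
}

#' Per-electrode spike-time trains for one recording
#'
#' @param trains named list of numeric vectors of spike times in seconds;
#'   each is sorted and deduplicated on construction.
#' @param duration recording length in seconds; all times must lie in
#'   \code{[0, duration]}.
#' @param fs sampling rate of the source recording (Hz), optional.
#' @param div days in vitro of the culture at recording, optional integer.
#' @param threshold_sd detection threshold multiplier used, optional.
#' @return an object of class \code{spike_train_set}.
#' @export
spike_train_set <- function(trains, duration, fs = NULL, div = NULL,
                            threshold_sd = NULL) {
  if (!is.list(trains)) stop("trains must be a named list of numeric vectors")
  if (is.null(names(trains)) || anyDuplicated(names(trains)))
    stop("trains must have unique electrode names")
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("duration must be a single positive number")
  trains <- lapply(trains, function(t) {
    t <- as.numeric(t)
    if (length(t) && (min(t) < 0 || max(t) > duration))
      stop("spike time outside [0, duration]")
    sort(unique(t))
  })
  structure(
    list(trains = trains, duration = duration, fs = fs, div = div,
         threshold_sd = threshold_sd),
    class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- sum(lengths(x$trains))
  cat(sprintf("<spike_train_set> %d electrodes, %d spikes over %.6g s%s\n",
              length(x$trains), n, x$duration,
              if (!is.null(x$div)) sprintf(" (DIV %d)", x$div) else ""))
  invisible(x)
}

#' Total spike count of a spike train set
#' @param trains a \code{spike_train_set}.
#' @return integer spike count summed over electrodes.
#' @export
n_spikes <- function(trains) {
  stopifnot(inherits(trains, "spike_train_set"))
  sum(lengths(trains$trains))
}

#' Detected network bursts
#'
#' @param bursts data.frame with columns \code{start_s}, \code{end_s},
#'   \code{spike_count}; rows ordered and non-overlapping. Burst boundaries
#'   snap to histogram bin edges, so \code{end_s - start_s} is a positive
#'   multiple of \code{bin_s}.
#' @param participants list (one element per burst) of character vectors of
#'   electrodes that fired at least one spike inside the burst.
#' @param bin_s histogram bin width in seconds used for detection.
#' @param threshold_sd SD multiplier of the histogram threshold.
#' @param min_participation participation-pruning fraction.
#' @return an object of class \code{burst_set}.
#' @export
burst_set <- function(bursts, participants = NULL, bin_s = 0.05,
                      threshold_sd = 5, min_participation = 0.20) {
  bursts <- as.data.frame(bursts)
  need <- c("start_s", "end_s", "spike_count")
  if (!all(need %in% names(bursts)))
    stop("bursts must have columns start_s, end_s, spike_count")
  if (nrow(bursts)) {
    if (any(bursts$end_s <= bursts$start_s))
      stop("burst end must exceed start")
    if (is.unsorted(bursts$start_s, strictly = TRUE) && nrow(bursts) > 1L)
      stop("bursts must be ordered by start time")
    if (nrow(bursts) > 1L &&
        any(bursts$start_s[-1L] < bursts$end_s[-nrow(bursts)]))
      stop("bursts must be non-overlapping")
  }
  if (is.null(participants)) participants <- rep(list(character()), nrow(bursts))
  if (length(participants) != nrow(bursts))
    stop("participants must have one entry per burst")
  structure(
    list(bursts = bursts, participants = participants, bin_s = bin_s,
         threshold_sd = threshold_sd, min_participation = min_participation),
    class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("<burst_set> %d bursts (bin %g s, threshold mean + %g SD, participation >= %g)\n",
              nrow(x$bursts), x$bin_s, x$threshold_sd, x$min_participation))
  invisible(x)
}

#' Number of detected bursts
#' @param bursts a \code{burst_set}.
#' @return integer count of bursts.
#' @export
n_bursts <- function(bursts) {
  stopifnot(inherits(bursts, "burst_set"))
  nrow(bursts$bursts)
}

#' Contraction event series for one myotube
#'
#' Ordered contraction times for one myotube, organised into named
#' observation windows (typically \code{pre} and \code{post} an
#' intervention). Times are seconds relative to the start of their own
#' window.
#'
#' @param events data.frame with columns \code{time_s}, \code{window}, and
#'   optionally a logical \code{partial} flag marking partial contractions
#'   (tallied separately from full contractions, never merged).
#' @param windows named numeric vector of window durations in seconds,
#'   e.g. \code{c(pre = 600, post = 600)}.
#' @param myotube_id label of the myotube.
#' @param group experimental group, \code{"treated"} or \code{"sham"}.
#' @return an object of class \code{contraction_series}.
#' @export
contraction_series <- function(events, windows, myotube_id = "myotube",
                               group = c("treated", "sham")) {
  group <- match.arg(group)
  events <- as.data.frame(events)
  if (!all(c("time_s", "window") %in% names(events)))
    stop("events must have columns time_s and window")
  if (is.null(events$partial)) events$partial <- rep(FALSE, nrow(events))
  events$partial <- as.logical(events$partial)
  if (is.null(names(windows)) || any(!nzchar(names(windows))))
    stop("windows must be a named vector of durations")
  if (any(windows <= 0)) stop("window durations must be positive")
  if (any(!events$window %in% names(windows)))
    stop("event window label not declared in windows")
  for (w in names(windows)) {
    t <- events$time_s[events$window == w]
    if (length(t) && (min(t) < 0 || max(t) >= windows[[w]]))
      stop("event time outside window '", w, "'")
  }
  events <- events[order(match(events$window, names(windows)), events$time_s), ,
                   drop = FALSE]
  rownames(events) <- NULL
  structure(
    list(myotube_id = myotube_id, events = events,
         windows = windows, group = group),
    class = "contraction_series")
}

#' @export
print.contraction_series <- function(x, ...) {
  cat(sprintf("<contraction_series> %s (%s): %s\n", x$myotube_id, x$group,
              paste(sprintf("%s %d events/%gs", names(x$windows),
                            tabulate(match(x$events$window, names(x$windows)),
                                     length(x$windows)),
                            x$windows), collapse = ", ")))
  invisible(x)
}
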