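#' Whole-network firing rate
#'
#' Total number of recorded spikes across all electrodes divided by the
#' recording length.
#'
#' @param trains a \code{\link{spike_train_set}}.
#' @return firing rate in Hz.
#' @export
network_firing_rate <- function(trains) {
  stopifnot(inherits(trains, "spike_train_set"))
  n_spikes(trains) / trains$duration
}

#' Active electrodes of a recording
#'
#' Electrodes whose individual firing rate is at least \code{min_rate_hz}.
#' This recording-level set is the denominator of the burst
#' participation-pruning rule.
#'
#' @param trains a \code{\link{spike_train_set}}.
#' @param min_rate_hz per-electrode rate threshold in Hz (>= 0); the rule is
#'   inclusive (rate == threshold counts as active).
#' @return character vector of active electrode ids.
#' @export
active_electrodes <- function(trains, min_rate_hz = 0.1) {
  stopifnot(inherits(trains, "spike_train_set"))
  if (min_rate_hz < 0) stop("min_rate_hz must be >= 0")
  rates <- lengths(trains$trains) / trains$duration
  names(trains$trains)[rates >= min_rate_hz]
}

#' Bin spike counts into a population firing-rate histogram
#'
#' Bins are half-open \code{[i*bin_s, (i+1)*bin_s)} covering the whole
#' recording. Returns the network histogram (total spikes per bin) plus a
#' per-electrode-per-bin activity flag (at least one spike in the bin). The
#' histogram sums to the total spike count.
#'
#' @param trains a \code{\link{spike_train_set}}.
#' @param bin_s bin width in seconds (> 0); default 0.05 (50 ms).
#' @return object of class \code{spike_histogram}: list with \code{counts}
#'   (integer vector, one per bin), \code{flags} (logical matrix, electrodes
#'   x bins), \code{bin_s}, \code{n_bins}, \code{duration},
#'   \code{electrode_ids}.
#' @export
bin_spike_counts <- function(trains, bin_s = 0.05) {
  stopifnot(inherits(trains, "spike_train_set"))
  if (bin_s <= 0) stop("bin_s must be > 0")
  n_bins <- ceiling(trains$duration / bin_s)
  ids <- names(trains$trains)
  flags <- matrix(FALSE, nrow = length(ids), ncol = n_bins,
                  dimnames = list(ids, NULL))
  counts <- integer(n_bins)
  for (id in ids) {
    t <- trains$trains[[id]]
    if (!length(t)) next
    # spikes exactly at t = duration fall in the final bin
    b <- pmin(floor(t / bin_s) + 1L, n_bins)
    tab <- tabulate(b, n_bins)
    counts <- counts + tab
    flags[id, ] <- tab > 0L
  }
  structure(
    list(counts = counts, flags = flags, bin_s = bin_s, n_bins = n_bins,
         duration = trains$duration, electrode_ids = ids),
    class = "spike_histogram")
}

#' Detect network bursts from a binned firing-rate histogram
#'
#' Three-step rule: (1) mark bins whose spike count strictly exceeds the
#' mean bin count plus \code{threshold_sd} SDs (mean and SD over all bins of
#' the recording, empty bins included); (2) unmark bins in which fewer than
#' \code{min_participation} of the active electrodes fired; (3) merge runs
#' of adjacent marked bins into single, longer bursts. Per-burst spike
#' counts and the union of participating electrodes are reported.
#'
#' @param hist a \code{spike_histogram} from \code{\link{bin_spike_counts}}.
#' @param active_set character vector of active electrode ids (see
#'   \code{\link{active_electrodes}}); an empty set prunes every candidate
#'   bin and yields an empty burst set with a warning.
#' @param threshold_sd SD multiplier of the histogram threshold; default 5.
#' @param min_participation minimum fraction of active electrodes firing in
#'   a bin; pruning is strict (exactly the fraction survives); default 0.20.
#' @return a \code{\link{burst_set}}.
#' @export
detect_network_bursts <- function(hist, active_set, threshold_sd = 5,
                                  min_participation = 0.20) {
  stopifnot(inherits(hist, "spike_histogram"))
  counts <- hist$counts
  thr <- mean(counts) + threshold_sd * sd(counts)
  marked <- counts > thr
  if (any(marked)) {
    if (length(active_set) == 0L) {
      warning("empty active set: every candidate bin pruned")
      marked[] <- FALSE
    } else {
      act <- hist$flags[intersect(active_set, hist$electrode_ids), ,
                        drop = FALSE]
      frac <- colSums(act) / length(active_set)
      marked <- marked & frac >= min_participation
    }
  }
  runs <- rle(marked)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  b_start <- starts[keep]
  b_end <- ends[keep]
  bursts <- data.frame(
    start_s = (b_start - 1L) * hist$bin_s,
    end_s = b_end * hist$bin_s,
    spike_count = vapply(seq_along(b_start), function(k)
      sum(counts[b_start[k]:b_end[k]]), numeric(1)))
  participants <- lapply(seq_along(b_start), function(k) {
    f <- hist$flags[, b_start[k]:b_end[k], drop = FALSE]
    hist$electrode_ids[rowSums(f) > 0L]
  })
  burst_set(bursts, participants, bin_s = hist$bin_s,
            threshold_sd = threshold_sd,
            min_participation = min_participation)
}

#' Convenience wrapper: histogram, active set and burst detection in one call
#'
#' @param trains a \code{\link{spike_train_set}}.
#' @param bin_s histogram bin width in seconds.
#' @param threshold_sd histogram threshold SD multiplier.
#' @param min_participation participation-pruning fraction.
#' @param active_min_rate_hz per-electrode rate defining the active set.
#' @return a \code{\link{burst_set}}.
#' @export
find_network_bursts <- function(trains, bin_s = 0.05, threshold_sd = 5,
                                min_participation = 0.20,
                                active_min_rate_hz = 0.1) {
  hist <- bin_spike_counts(trains, bin_s = bin_s)
  act <- active_electrodes(trains, min_rate_hz = active_min_rate_hz)
  detect_network_bursts(hist, act, threshold_sd = threshold_sd,
                        min_participation = min_participation)
}

#' Fraction of spikes inside network bursts
#'
#' Proportion of all recorded spikes whose time falls inside any detected
#' burst interval \code{[start_s, end_s)}; 0 when there are no spikes or no
#' bursts. A synchronization measure of the network.
#'
#' @param trains a \code{\link{spike_train_set}}.
#' @param bursts a \code{\link{burst_set}}.
#' @return fraction in [0, 1].
#' @export
burst_spike_fraction <- function(trains, bursts) {
  stopifnot(inherits(trains, "spike_train_set"), inherits(bursts, "burst_set"))
  total <- n_spikes(trains)
  if (total == 0L || nrow(bursts$bursts) == 0L) return(0)
  all_t <- unlist(trains$trains, use.names = FALSE)
  inside <- rep(FALSE, length(all_t))
  for (k in seq_len(nrow(bursts$bursts))) {
    inside <- inside |
      (all_t >= bursts$bursts$start_s[k] & all_t < bursts$bursts$end_s[k])
  }
  sum(inside) / total
}

#' Maturity stage of a culture by days in vitro
#'
#' Young networks span 15--35 DIV, middle-aged 42--56 DIV, old 63--70 DIV.
#' Days outside those ranges (including the gaps 36--41 and 57--62) are
#' \code{"unstaged"} rather than assigned to the nearest stage.
#'
#' @param div days in vitro (vectorised, integer >= 0).
#' @return character vector: \code{"young"}, \code{"middle_aged"},
#'   \code{"old"} or \code{"unstaged"}.
#' @export
classify_stage <- function(div) {
  if (any(div < 0)) stop("div must be >= 0")
  out <- rep("unstaged", length(div))
  out[div >= 15 & div <= 35] <- "young"
  out[div >= 42 & div <= 56] <- "middle_aged"
  out[div >= 63 & div <= 70] <- "old"
  out
}

#' Whole-recording activity summary
#'
#' @param trains a \code{\link{spike_train_set}}.
#' @param div days in vitro; taken from \code{trains} when absent there.
#' @param bin_s,threshold_sd,min_participation,active_min_rate_hz burst
#'   detection settings (see \code{\link{find_network_bursts}}).
#' @return object of class \code{network_summary}: firing rate (Hz), burst
#'   fraction, burst count, active-electrode count, DIV and stage.
#' @export
network_summary <- function(trains, div = NULL, bin_s = 0.05,
                            threshold_sd = 5, min_participation = 0.20,
                            active_min_rate_hz = 0.1) {
  stopifnot(inherits(trains, "spike_train_set"))
  if (is.null(div)) div <- trains$div
  bursts <- find_network_bursts(trains, bin_s = bin_s,
                                threshold_sd = threshold_sd,
                                min_participation = min_participation,
                                active_min_rate_hz = active_min_rate_hz)
  structure(
    list(firing_rate_hz = network_firing_rate(trains),
         burst_fraction = burst_spike_fraction(trains, bursts),
         n_bursts = n_bursts(bursts),
         n_active_electrodes =
           length(active_electrodes(trains, active_min_rate_hz)),
         div = div,
         stage = if (is.null(div)) "unstaged" else classify_stage(div),
         bursts = bursts),
    class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    "<network_summary> %.4g Hz network firing rate, %d bursts, burst fraction %.3f, %d active electrodes%s (%s)\n",
    x$firing_rate_hz, x$n_bursts, x$burst_fraction, x$n_active_electrodes,
    if (!is.null(x$div)) sprintf(", DIV %s", x$div) else "", x$stage))
  invisible(x)
}

#' Low-activity exclusion rule
#'
#' Recordings from very quiet networks are excluded from further analysis.
#' A recording is excluded when its network firing rate is strictly below
#' \code{min_rate_hz}; a rate exactly at the threshold is retained.
#'
#' @param summary a \code{network_summary} or a bare firing rate in Hz.
#' @param min_rate_hz exclusion threshold in Hz; default 0.05.
#' @return logical: \code{TRUE} means exclude.
#' @export
exclude_low_activity <- function(summary, min_rate_hz = 0.05) {
  rate <- if (inherits(summary, "network_summary")) summary$firing_rate_hz
          else as.numeric(summary)
  rate < min_rate_hz
}
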