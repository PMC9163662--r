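#' Butterworth bandpass filter settings
#'
#' Fixed-design Butterworth bandpass used before spike detection; the
#' defaults are a 4th-order design with corners at 300 and 3,000 Hz.
#'
#' @param order filter order of the bandpass design (pole pairs), >= 1.
#' @param low_hz,high_hz lower and upper corner frequencies in Hz,
#'   0 < low_hz < high_hz.
#' @return object of class \code{filter_settings}.
#' @export
filter_settings <- function(order = 4, low_hz = 300, high_hz = 3000) {
  if (order < 1) stop("filter order must be >= 1")
  if (low_hz <= 0 || high_hz <= low_hz)
    stop("need 0 < low_hz < high_hz (got ", low_hz, ", ", high_hz, ")")
  structure(list(order = order, low_hz = low_hz, high_hz = high_hz,
                 design = "butterworth_bandpass"),
            class = "filter_settings")
}

butter_design <- function(settings, fs) {
  if (fs <= 2 * settings$high_hz)
    stop("upper corner ", settings$high_hz,
         " Hz violates Nyquist for fs = ", fs, " Hz")
  signal::butter(settings$order,
                 c(settings$low_hz, settings$high_hz) / (fs / 2),
                 type = "pass")
}

#' Bandpass-filter a raw recording
#'
#' Applies the configured Butterworth bandpass to every electrode. By
#' default the filter is applied forward and backward (zero-phase), so spike
#' timestamps are not delayed; the effective magnitude response is then the
#' square of the single-pass design (see \code{\link{filter_gain}}).
#'
#' @param recording a \code{\link{raw_recording}}.
#' @param settings a \code{\link{filter_settings}}.
#' @param zero_phase logical; forward-backward filtering (default) versus a
#'   single causal pass.
#' @return a filtered \code{raw_recording} of identical shape.
#' @export
bandpass_filter <- function(recording, settings = filter_settings(),
                            zero_phase = TRUE) {
  stopifnot(inherits(recording, "raw_recording"))
  bf <- butter_design(settings, recording$fs)
  out <- recording$samples
  for (j in seq_len(ncol(out))) {
    out[, j] <- if (zero_phase) signal::filtfilt(bf, recording$samples[, j])
                else as.numeric(signal::filter(bf, recording$samples[, j]))
  }
  raw_recording(out, fs = recording$fs,
                electrode_ids = recording$electrode_ids)
}

#' Analytic magnitude response of the configured bandpass
#'
#' Evaluates the designed digital filter's transfer function at the given
#' frequencies. With \code{zero_phase = TRUE} the returned gain is the
#' squared single-pass magnitude, matching what
#' \code{\link{bandpass_filter}} actually applies.
#'
#' @param f_hz frequencies in Hz (vectorised).
#' @param settings a \code{\link{filter_settings}}.
#' @param fs sampling rate in Hz.
#' @param zero_phase match the filtering mode of
#'   \code{\link{bandpass_filter}}.
#' @return numeric vector of amplitude gains.
#' @export
filter_gain <- function(f_hz, settings = filter_settings(), fs = 10000,
                        zero_phase = TRUE) {
  bf <- butter_design(settings, fs)
  g <- vapply(f_hz, function(f) {
    w <- 2 * pi * f / fs
    num <- sum(bf$b * exp(-1i * w * (seq_along(bf$b) - 1)))
    den <- sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1)))
    Mod(num / den)
  }, numeric(1))
  if (zero_phase) g^2 else g
}

#' Detect spikes by amplitude threshold on a filtered recording
#'
#' Per electrode, the mean and SD of the whole filtered trace are computed
#' and a spike is emitted wherever the trace deviates from the mean by more
#' than \code{threshold_sd} SDs. Crossing samples within \code{dead_time} of
#' the previous crossing are collapsed into the ongoing event, so each
#' excursion (however long, and including after-lobes chained within the
#' dead time) yields one timestamp: the time of its first threshold-crossing
#' sample. This keeps one event per action potential.
#'
#' @param filtered a bandpass-filtered \code{\link{raw_recording}}.
#' @param threshold_sd SD multiplier (> 0); default 7.
#' @param dead_time refractory period after each detection, in seconds.
#' @param polarity \code{"both"} (absolute deviation from the mean, the
#'   default) or \code{"negative"} (negative excursions only).
#' @param robust_sd estimate the SD as \code{mad()} instead of \code{sd()};
#'   off by default (plain full-trace SD).
#' @param div optional days-in-vitro metadata attached to the result.
#' @return a \code{\link{spike_train_set}}.
#' @export
detect_spikes <- function(filtered, threshold_sd = 7, dead_time = 0.001,
                          polarity = c("both", "negative"),
                          robust_sd = FALSE, div = NULL) {
  stopifnot(inherits(filtered, "raw_recording"))
  if (threshold_sd <= 0) stop("threshold_sd must be > 0")
  polarity <- match.arg(polarity)
  fs <- filtered$fs
  dead_samples <- round(dead_time * fs)
  trains <- lapply(seq_len(ncol(filtered$samples)), function(j) {
    x <- filtered$samples[, j]
    mu <- mean(x)
    s <- if (robust_sd) stats::mad(x) else sd(x)
    if (!is.finite(s) || s == 0) {
      warning("electrode ", filtered$electrode_ids[j],
              ": constant trace (SD = 0), no spikes detected")
      return(numeric(0))
    }
    dev <- if (polarity == "both") abs(x - mu) else mu - x
    idx <- which(dev > threshold_sd * s)
    if (!length(idx)) return(numeric(0))
    # new event when the gap from the previous crossing exceeds the dead time
    starts <- c(TRUE, diff(idx) > dead_samples)
    (idx[starts] - 1L) / fs
  })
  names(trains) <- filtered$electrode_ids
  spike_train_set(trains, duration = filtered$duration, fs = fs,
                  div = div, threshold_sd = threshold_sd)
}
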