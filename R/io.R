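sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write / read a raw recording as wide CSV
#'
#' The fixture format is a wide CSV whose first column is \code{time_s}
#' followed by one column per electrode (voltages in uV). A JSON sidecar
#' (\code{<path>.json}) records the sampling rate and electrode ids; when it
#' is absent on read, the sampling rate is inferred from the time column.
#'
#' @param recording a \code{\link{raw_recording}}.
#' @param path CSV file path.
#' @return \code{write_raw_csv} returns \code{path} invisibly;
#'   \code{read_raw_csv} returns a \code{\link{raw_recording}}.
#' @export
write_raw_csv <- function(recording, path) {
  stopifnot(inherits(recording, "raw_recording"))
  dt <- data.table::data.table(
    time_s = (seq_len(nrow(recording$samples)) - 1L) / recording$fs)
  for (id in recording$electrode_ids)
    dt[[id]] <- recording$samples[, id]
  data.table::fwrite(dt, path)
  write_sidecar(list(fs = recording$fs,
                     electrode_ids = recording$electrode_ids), path)
  invisible(path)
}

#' @rdname write_raw_csv
#' @export
read_raw_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path)
  if (names(dt)[1L] != "time_s")
    stop("first column must be time_s, got '", names(dt)[1L], "'")
  meta <- read_sidecar(path)
  fs <- if (!is.null(meta$fs)) meta$fs
        else 1 / stats::median(diff(dt$time_s))
  ids <- setdiff(names(dt), "time_s")
  x <- as.matrix(dt[, ids, with = FALSE])
  for (id in ids) {
    if (anyNA(x[, id]))
      stop("channel ", id, " has missing samples (unequal channel lengths?)")
  }
  message("read raw recording: ", length(ids), " electrodes at ", fs, " Hz")
  raw_recording(x, fs = fs, electrode_ids = ids)
}

#' Write / read spike trains as CSV
#'
#' Long CSV with columns \code{electrode_id}, \code{time_s}; a JSON sidecar
#' carries the recording duration and detection settings. Electrodes with no
#' spikes are preserved through the sidecar's electrode list. On read,
#' unsorted times are sorted with a warning, duplicate
#' (electrode, time) rows are dropped with a message, and negative times are
#' rejected.
#'
#' @param trains a \code{\link{spike_train_set}}.
#' @param path CSV file path.
#' @param duration recording duration in seconds, required on read when no
#'   sidecar is present.
#' @return \code{write_spikes_csv} returns \code{path} invisibly;
#'   \code{read_spikes_csv} returns a \code{\link{spike_train_set}}.
#' @export
write_spikes_csv <- function(trains, path) {
  stopifnot(inherits(trains, "spike_train_set"))
  dt <- data.table::data.table(
    electrode_id = rep(names(trains$trains), lengths(trains$trains)),
    time_s = unlist(trains$trains, use.names = FALSE))
  data.table::fwrite(dt, path)
  write_sidecar(list(duration = trains$duration, fs = trains$fs,
                     div = trains$div, threshold_sd = trains$threshold_sd,
                     electrode_ids = names(trains$trains)), path)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path, duration = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = "electrode_id"))
  if (!all(c("electrode_id", "time_s") %in% names(dt)))
    stop("expected columns electrode_id, time_s")
  meta <- read_sidecar(path)
  if (is.null(duration)) duration <- meta$duration
  if (is.null(duration))
    stop("recording duration unknown: pass duration= or provide the sidecar")
  if (nrow(dt) && any(dt$time_s < 0)) stop("negative spike times in ", path)
  ids <- if (!is.null(meta$electrode_ids)) meta$electrode_ids
         else sort(unique(dt$electrode_id))
  ndup <- nrow(dt) - data.table::uniqueN(dt)
  if (ndup > 0)
    message("dropped ", ndup, " duplicate (electrode, time) rows")
  trains <- lapply(ids, function(id) {
    t <- dt$time_s[dt$electrode_id == id]
    if (is.unsorted(t)) warning("unsorted spike times on ", id, "; sorting")
    t
  })
  names(trains) <- ids
  spike_train_set(trains, duration = duration, fs = meta$fs,
                  div = meta$div, threshold_sd = meta$threshold_sd)
}

#' Write / read contraction event series as CSV
#'
#' Long CSV with columns \code{myotube_id}, \code{time_s}, \code{window},
#' \code{partial}; the JSON sidecar carries the window durations and the
#' experimental group.
#'
#' @param series a \code{\link{contraction_series}}.
#' @param path CSV file path.
#' @param windows named durations (s), required on read when no sidecar.
#' @param group experimental group, used when no sidecar is present.
#' @return \code{write_events_csv} returns \code{path} invisibly;
#'   \code{read_events_csv} returns a \code{\link{contraction_series}}.
#' @export
write_events_csv <- function(series, path) {
  stopifnot(inherits(series, "contraction_series"))
  dt <- data.table::data.table(
    myotube_id = series$myotube_id,
    time_s = series$events$time_s,
    window = series$events$window,
    partial = series$events$partial)
  data.table::fwrite(dt, path)
  write_sidecar(list(myotube_id = series$myotube_id,
                     windows = as.list(series$windows),
                     group = series$group), path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path, windows = NULL, group = "treated") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path)
  if (!all(c("myotube_id", "time_s", "window") %in% names(dt)))
    stop("expected columns myotube_id, time_s, window")
  meta <- read_sidecar(path)
  if (is.null(windows)) windows <- unlist(meta$windows)
  if (is.null(windows)) stop("window durations unknown: pass windows=")
  if (nrow(dt) && any(dt$time_s < 0)) stop("negative event times in ", path)
  if (!is.null(meta$group)) group <- meta$group
  id <- if (!is.null(meta$myotube_id)) meta$myotube_id
        else if (nrow(dt)) dt$myotube_id[1L] else "myotube"
  contraction_series(
    data.frame(time_s = dt$time_s, window = dt$window,
               partial = if (!is.null(dt$partial)) dt$partial else FALSE),
    windows = windows, myotube_id = id, group = group)
}

#' Write / read generator ground truth as JSON
#'
#' @param truth a \code{\link{ground_truth}}.
#' @param path JSON file path.
#' @return \code{write_ground_truth} returns \code{path} invisibly;
#'   \code{read_ground_truth} returns a \code{\link{ground_truth}}.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  epochs <- x$true_burst_epochs
  if (!is.null(epochs) && is.data.frame(epochs) && !is.null(epochs$participants))
    epochs$participants <- lapply(epochs$participants, as.character)
  ground_truth(true_spike_times = x$true_spike_times,
               true_burst_epochs = epochs,
               true_rates = x$true_rates,
               seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}
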