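check_range <- function(value, name, min = -Inf, max = Inf,
                        strict_min = FALSE) {
  ok <- is.numeric(value) && length(value) == 1L && is.finite(value) &&
    (if (strict_min) value > min else value >= min) && value <= max
  if (!ok)
    stop("config parameter '", name, "' out of range (got ", value,
         ", need ", if (strict_min) "> " else ">= ", min,
         if (is.finite(max)) paste0(" and <= ", max) else "", ")",
         call. = FALSE)
  value
}

#' Pipeline configuration
#'
#' Validated settings for \code{\link{run_pipeline}}. Defaults are the
#' analysis parameters of the reference protocol: 4th-order 300--3,000 Hz
#' bandpass, 7-SD spike threshold with 1-ms dead time, 50-ms burst bins with
#' a 5-SD threshold and 20 percent participation pruning, 10-min assay
#' windows with 30-s bins. Unknown arguments are rejected.
#'
#' @param seed integer seed driving every simulated input.
#' @param raw path to a raw-recording CSV, a \code{raw_recording}, or
#'   \code{NULL}.
#' @param spikes path to a spike CSV, a \code{spike_train_set}, or
#'   \code{NULL}; ignored when \code{raw} is given (spikes are detected).
#' @param events path to an event CSV, a \code{contraction_series}, or
#'   \code{NULL}.
#' @param simulate \code{NULL}, or a list with optional elements
#'   \code{trains} (arguments to \code{\link{gen_spike_trains}}) and
#'   \code{contractions} (arguments to
#'   \code{\link{gen_contraction_series}}); simulated inputs fill whichever
#'   of \code{raw}/\code{spikes}/\code{events} are NULL.
#' @param filter a \code{\link{filter_settings}}.
#' @param detection list: \code{threshold_sd} (> 0), \code{dead_time} (>= 0 s).
#' @param burst list: \code{bin_s} (> 0), \code{threshold_sd} (> 0),
#'   \code{min_participation} in [0, 1], \code{active_min_rate_hz} (>= 0).
#' @param assay list: \code{window_s} (> 0), \code{bin_s} (> 0),
#'   \code{change_tol} (>= 0).
#' @param exclusion list: \code{min_rate_hz} (>= 0).
#' @param div days in vitro of the recording, or \code{NULL}.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, raw = NULL, spikes = NULL,
                            events = NULL, simulate = NULL,
                            filter = filter_settings(),
                            detection = list(), burst = list(),
                            assay = list(), exclusion = list(),
                            div = NULL) {
  merge_defaults <- function(given, defaults, block) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown))
      stop("unknown config key", if (length(unknown) > 1) "s", " in '",
           block, "': ", paste(unknown, collapse = ", "), call. = FALSE)
    utils::modifyList(defaults, given)
  }
  detection <- merge_defaults(detection,
                              list(threshold_sd = 7, dead_time = 0.001),
                              "detection")
  burst <- merge_defaults(burst,
                          list(bin_s = 0.05, threshold_sd = 5,
                               min_participation = 0.20,
                               active_min_rate_hz = 0.1), "burst")
  assay <- merge_defaults(assay,
                          list(window_s = 600, bin_s = 30, change_tol = 10),
                          "assay")
  exclusion <- merge_defaults(exclusion, list(min_rate_hz = 0.05),
                              "exclusion")
  stopifnot(inherits(filter, "filter_settings"))
  check_range(detection$threshold_sd, "detection.threshold_sd", 0,
              strict_min = TRUE)
  check_range(detection$dead_time, "detection.dead_time", 0)
  check_range(burst$bin_s, "burst.bin_s", 0, strict_min = TRUE)
  check_range(burst$threshold_sd, "burst.threshold_sd", 0, strict_min = TRUE)
  check_range(burst$min_participation, "burst.min_participation", 0, 1)
  check_range(burst$active_min_rate_hz, "burst.active_min_rate_hz", 0)
  check_range(assay$window_s, "assay.window_s", 0, strict_min = TRUE)
  check_range(assay$bin_s, "assay.bin_s", 0, strict_min = TRUE)
  check_range(assay$change_tol, "assay.change_tol", 0)
  check_range(exclusion$min_rate_hz, "exclusion.min_rate_hz", 0)
  structure(
    list(seed = as.integer(seed), raw = raw, spikes = spikes,
         events = events, simulate = simulate, filter = filter,
         detection = detection, burst = burst, assay = assay,
         exclusion = exclusion, div = div),
    class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full simulate / detect / analyze / assay pipeline
#'
#' Executes the stages in order on the configured inputs (loading files,
#' taking in-memory objects, or simulating what is missing), writes all
#' intermediate artifacts plus a single JSON report and a run log to
#' \code{out_dir}, and returns the report. Reruns with an identical
#' configuration produce byte-identical reports.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory, created if needed; \code{NULL} skips all
#'   file output.
#' @param quiet suppress progress messages to stderr.
#' @return the report as a named list (settings, network activity summary,
#'   assay results, ground truth where simulated).
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  say("run_pipeline: seed = ", config$seed)

  truth <- list()
  raw <- config$raw
  spikes <- config$spikes
  events <- config$events

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (is.null(raw) && is.null(spikes) && !is.null(sim$trains)) {
      say("stage simulate: spike trains")
      g <- run_stage("simulate", do.call(gen_spike_trains,
                                         c(sim$trains, list(seed = config$seed))))
      spikes <- g$trains
      truth$trains <- g$truth
    }
    if (is.null(raw) && !is.null(sim$raw)) {
      say("stage simulate: raw recording")
      g <- run_stage("simulate", do.call(gen_raw_recording,
                                         c(sim$raw, list(seed = config$seed))))
      raw <- g$recording
      truth$raw <- g$truth
    }
    if (is.null(events) && !is.null(sim$contractions)) {
      say("stage simulate: contraction series")
      g <- run_stage("simulate",
                     do.call(gen_contraction_series,
                             c(sim$contractions, list(seed = config$seed))))
      events <- g$series
      truth$contractions <- g$truth
    }
  }

  if (is.character(raw)) raw <- run_stage("read_raw", read_raw_csv(raw))
  if (is.character(spikes))
    spikes <- run_stage("read_spikes", read_spikes_csv(spikes))
  if (is.character(events))
    events <- run_stage("read_events", read_events_csv(events))

  report <- list(settings = list(
    seed = config$seed,
    filter = unclass(config$filter)[c("order", "low_hz", "high_hz")],
    detection = config$detection, burst = config$burst,
    assay = config$assay, exclusion = config$exclusion))

  if (!is.null(raw)) {
    say("stage filter: Butterworth bandpass ", config$filter$low_hz, "-",
        config$filter$high_hz, " Hz, order ", config$filter$order)
    filtered <- run_stage("filter", bandpass_filter(raw, config$filter))
    say("stage detect: threshold ", config$detection$threshold_sd,
        " SD, dead time ", config$detection$dead_time, " s")
    spikes <- run_stage("detect", detect_spikes(
      filtered, threshold_sd = config$detection$threshold_sd,
      dead_time = config$detection$dead_time, div = config$div))
  }

  if (!is.null(spikes)) {
    if (!is.null(out_dir))
      write_spikes_csv(spikes, file.path(out_dir, "spikes.csv"))
    say("stage analyze: network activity")
    summ <- run_stage("analyze", network_summary(
      spikes, div = config$div, bin_s = config$burst$bin_s,
      threshold_sd = config$burst$threshold_sd,
      min_participation = config$burst$min_participation,
      active_min_rate_hz = config$burst$active_min_rate_hz))
    report$network <- list(
      total_spikes = n_spikes(spikes),
      firing_rate_hz = summ$firing_rate_hz,
      n_bursts = summ$n_bursts,
      burst_fraction = summ$burst_fraction,
      n_active_electrodes = summ$n_active_electrodes,
      div = summ$div, stage = summ$stage,
      excluded = exclude_low_activity(summ, config$exclusion$min_rate_hz))
    if (!is.null(out_dir)) {
      b <- summ$bursts$bursts
      b$n_electrodes <- lengths(summ$bursts$participants)
      data.table::fwrite(b, file.path(out_dir, "bursts.tsv"), sep = "\t")
    }
  }

  if (!is.null(events)) {
    say("stage assay: contraction quantification")
    res <- run_stage("assay", assay_result(
      events, window_s = config$assay$window_s, bin_s = config$assay$bin_s,
      change_tol = config$assay$change_tol))
    report$assay <- unclass(res)
    if (!is.null(out_dir)) {
      data.table::fwrite(
        data.table::data.table(
          bin_start_s = (seq_along(res$binned_pre) - 1L) * res$bin_s,
          pre = res$binned_pre, post = res$binned_post),
        file.path(out_dir, "contraction_bins.csv"))
      write_events_csv(events, file.path(out_dir, "contractions.csv"))
    }
  }

  if (length(truth)) {
    report$ground_truth <- list(
      n_planted_bursts = if (!is.null(truth$trains$true_burst_epochs))
        nrow(truth$trains$true_burst_epochs) else NULL,
      rates = c(truth$trains$true_rates, truth$contractions$true_rates))
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
    say("report written to ", file.path(out_dir, "report.json"))
  }
  report
}
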