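events_in_window <- function(series, window, include_partial = FALSE) {
  stopifnot(inherits(series, "contraction_series"))
  if (!window %in% names(series$windows))
    stop("window '", window, "' not present (have: ",
         paste(names(series$windows), collapse = ", "), ")")
  e <- series$events[series$events$window == window, , drop = FALSE]
  if (!include_partial) e <- e[!e$partial, , drop = FALSE]
  e$time_s
}

#' Pre-experiment selection criterion for a myotube
#'
#' A myotube qualifies for the blockade experiment when, over a 5-min
#' baseline observation, it shows more than 1 contraction per minute on
#' average (strictly more than \code{obs_minutes} events in total) AND at
#' least 1 contraction in every minute.
#'
#' @param series a \code{\link{contraction_series}}.
#' @param window window holding the baseline observation; default
#'   \code{"pre"}.
#' @param obs_minutes length of the observation in minutes; the window must
#'   be at least this long.
#' @return logical: \code{TRUE} when the myotube passes selection.
#' @export
passes_selection <- function(series, window = "pre", obs_minutes = 5) {
  t <- events_in_window(series, window)
  if (series$windows[[window]] < obs_minutes * 60)
    stop("window '", window, "' (", series$windows[[window]],
         " s) is shorter than the ", obs_minutes, "-min observation")
  t <- t[t < obs_minutes * 60]
  per_min <- tabulate(floor(t / 60) + 1L, obs_minutes)
  sum(per_min) > obs_minutes && all(per_min >= 1L)
}

#' Count contractions in an analysis window
#'
#' Number of full contractions in \code{[0, length_s)} of the named window
#' (half-open, so an event exactly at \code{length_s} is not counted).
#' Partial contractions are tallied separately and never merged into this
#' count.
#'
#' @param series a \code{\link{contraction_series}}.
#' @param window window name, e.g. \code{"pre"} or \code{"post"}.
#' @param length_s analysis span in seconds; default 600 (10 min).
#' @param partial count partial instead of full contractions.
#' @return integer event count.
#' @export
count_window <- function(series, window, length_s = 600, partial = FALSE) {
  t <- if (partial) {
    e <- series$events[series$events$window == window & series$events$partial, ,
                       drop = FALSE]
    if (!window %in% names(series$windows))
      stop("window '", window, "' not present")
    e$time_s
  } else events_in_window(series, window)
  sum(t >= 0 & t < length_s)
}

#' Bin contractions of one window into fixed intervals
#'
#' Half-open bins of width \code{bin_s} spanning the whole window; the
#' binned counts sum to \code{\link{count_window}} over the same span.
#'
#' @param series a \code{\link{contraction_series}}.
#' @param window window name.
#' @param bin_s bin width in seconds (> 0); default 30.
#' @return integer vector of per-bin counts.
#' @export
bin_contractions <- function(series, window, bin_s = 30) {
  if (bin_s <= 0) stop("bin_s must be > 0")
  t <- events_in_window(series, window)
  n_bins <- ceiling(series$windows[[window]] / bin_s)
  tabulate(floor(t / bin_s) + 1L, n_bins)
}

#' Percent reduction of contraction count after an intervention
#'
#' \code{100 * (1 - post_count / pre_count)}; at most 100 (all activity
#' abolished) and negative when activity increases.
#'
#' @param pre_count,post_count event counts of the matched pre and post
#'   analysis windows; \code{pre_count} must be positive.
#' @return percent reduction.
#' @export
percent_reduction <- function(pre_count, post_count) {
  if (any(pre_count <= 0))
    stop("percent reduction is undefined for pre_count = 0")
  100 * (1 - post_count / pre_count)
}

#' Classify the contractile response to an intervention
#'
#' \code{"abolished"} requires a post count of exactly zero;
#' \code{"reduced"} / \code{"increased"} when the percent reduction exceeds
#' \code{change_tol} in either direction; otherwise \code{"unchanged"}.
#'
#' @param pre_count,post_count event counts (pre_count > 0).
#' @param abolish_requires_zero logical; when \code{FALSE}, a 100 percent
#'   reduction classifies as abolished even if derived from rounded counts.
#' @param change_tol percent-change band treated as unchanged; default 10.
#' @return one of \code{"abolished"}, \code{"reduced"}, \code{"unchanged"},
#'   \code{"increased"}.
#' @export
classify_response <- function(pre_count, post_count,
                              abolish_requires_zero = TRUE,
                              change_tol = 10) {
  red <- percent_reduction(pre_count, post_count)
  abolished <- if (abolish_requires_zero) post_count == 0 else red >= 100
  if (abolished) "abolished"
  else if (red > change_tol) "reduced"
  else if (red < -change_tol) "increased"
  else "unchanged"
}

#' Full assay result for one myotube
#'
#' Combines windowed counts, percent reduction, response classification and
#' the binned 30-s time courses for the pre and post windows. Partial
#' contractions, when flagged in the series, appear as separate tallies.
#'
#' @param series a \code{\link{contraction_series}} with \code{pre} and
#'   \code{post} windows.
#' @param window_s analysis-window span in seconds; default 600.
#' @param bin_s time-course bin width in seconds; default 30.
#' @param change_tol percent band for \code{\link{classify_response}}.
#' @return object of class \code{assay_result}.
#' @export
assay_result <- function(series, window_s = 600, bin_s = 30,
                         change_tol = 10) {
  pre <- count_window(series, "pre", window_s)
  post <- count_window(series, "post", window_s)
  structure(
    list(myotube_id = series$myotube_id, group = series$group,
         pre_count = pre, post_count = post,
         pre_partial = count_window(series, "pre", window_s, partial = TRUE),
         post_partial = count_window(series, "post", window_s, partial = TRUE),
         percent_reduction = if (pre > 0) percent_reduction(pre, post)
                             else NA_real_,
         response_class = if (pre > 0)
           classify_response(pre, post, change_tol = change_tol)
         else NA_character_,
         binned_pre = bin_contractions(series, "pre", bin_s),
         binned_post = bin_contractions(series, "post", bin_s),
         bin_s = bin_s, window_s = window_s),
    class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf(
    "<assay_result> %s (%s): %d -> %d contractions per %g min (%s%s)\n",
    x$myotube_id, x$group, x$pre_count, x$post_count, x$window_s / 60,
    if (is.na(x$percent_reduction)) "no baseline"
    else sprintf("%.1f%% reduction, ", x$percent_reduction),
    if (is.na(x$response_class)) "" else x$response_class))
  invisible(x)
}
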