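# Single-trace induction features with explicit censoring.  A trace that
# never crosses the activation threshold, shows no qualifying peak, or
# ends before the half-decay point contributes a censor reason instead of
# a value, so histogram counts stay interpretable.

# centered moving average with shrinking windows at the edges
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  if (window %% 2L == 0L) stop("smooth window must be odd", call. = FALSE)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), 0)
}

crossing_index <- function(fluor, threshold) {
  idx <- which(fluor >= threshold)
  if (length(idx)) idx[1L] else NA_integer_
}

#' Threshold-crossing time of a fluorescence trace
#'
#' Time of the first frame at which fluorescence reaches the activation
#' threshold (no interpolation: crossing times are reported at frame
#' resolution).  Cells already above threshold at the first frame -- as
#' seen for cells loaded from stationary-phase cultures -- cross at time
#' of the first frame.
#'
#' @param trace a [lineage_trace()].
#' @param threshold fluorescence threshold in AU (default 1000).
#' @return Crossing time in minutes, or `NA` (censored: never crossed).
#' @export
#' @examples
#' tr <- lineage_trace("a", c(0, 10, 20), c(2, 2, 2), c(500, 800, 1200))
#' threshold_crossing_time(tr)
threshold_crossing_time <- function(trace, threshold = 1000) {
  stopifnot(inherits(trace, "lineage_trace"))
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (length(trace$times) == 0L)
    stop("invalid trace: empty", call. = FALSE)
  ci <- crossing_index(trace$fluorescence, threshold)
  if (is.na(ci)) NA_real_ else trace$times[ci]
}

#' Maximal rate of fluorescence increase
#'
#' The maximum forward finite difference `(F[i+1] - F[i]) / frame_interval`
#' over the trace, after optional centered moving-average smoothing.
#' Defined only for traces that cross the activation threshold; censored
#' otherwise, and censored when no positive increase exists.
#'
#' @param trace a [lineage_trace()].
#' @param threshold activation threshold in AU.
#' @param smooth_window odd moving-average width in frames (1 = raw, the
#'   default); widths of 3-5 suppress measurement-noise spikes on noisy
#'   traces.
#' @return Rate in AU/min, or `NA` when censored.
#' @export
max_induction_rate <- function(trace, threshold = 1000, smooth_window = 1L) {
  stopifnot(inherits(trace, "lineage_trace"))
  if (length(trace$times) < 2L)
    stop("invalid trace: need at least 2 frames", call. = FALSE)
  ci <- crossing_index(trace$fluorescence, threshold)
  if (is.na(ci)) return(NA_real_)
  f <- moving_average(trace$fluorescence, smooth_window)
  dt <- trace_frame_interval(trace)
  r <- max(diff(f)) / dt
  if (r > 0) r else NA_real_
}

# peak prominence: height above the higher of the two bases, where each
# base is the minimum between the peak and the nearest higher sample on
# that side (or the trace end)
peak_prominence <- function(f, i) {
  n <- length(f)
  left_min <- f[i]
  j <- i - 1L
  while (j >= 1L && f[j] <= f[i]) { left_min <- min(left_min, f[j]); j <- j - 1L }
  if (j < 1L && i == 1L) left_min <- f[i]
  right_min <- f[i]
  j <- i + 1L
  while (j <= n && f[j] <= f[i]) { right_min <- min(right_min, f[j]); j <- j + 1L }
  f[i] - max(left_min, right_min)
}

#' First fluorescence peak after threshold crossing
#'
#' The first local maximum at or after the crossing frame whose prominence
#' is at least `prominence_fraction` of the trace's dynamic range
#' (`max(F) - F0_est`, with `F0_est` the median fluorescence before the
#' crossing).  Prominence filtering keeps measurement-noise blips from
#' terminating a pulse early.  The amplitude is the absolute fluorescence
#' at the peak frame.
#'
#' @param trace a [lineage_trace()].
#' @param threshold activation threshold in AU.
#' @param prominence_fraction minimum prominence as a fraction of the
#'   dynamic range (default 0.1).
#' @return A list with `peak_time` (min), `peak_amplitude` (AU) and
#'   `censored` (`NA` or one of `"never_crossed"`, `"no_peak"`).
#' @export
first_peak_amplitude <- function(trace, threshold = 1000,
                                 prominence_fraction = 0.1) {
  stopifnot(inherits(trace, "lineage_trace"))
  f <- trace$fluorescence
  n <- length(f)
  ci <- crossing_index(f, threshold)
  if (is.na(ci))
    return(list(peak_time = NA_real_, peak_amplitude = NA_real_,
                censored = "never_crossed"))
  f0_est <- if (ci > 1L) median(f[seq_len(ci - 1L)]) else min(f)
  min_prom <- prominence_fraction * (max(f) - f0_est)
  for (i in ci:n) {
    left_ok <- i == 1L || f[i] >= f[i - 1L]
    right_ok <- i < n && f[i] >= f[i + 1L]
    strict <- (i > 1L && f[i] > f[i - 1L]) || (i < n && f[i] > f[i + 1L])
    if (left_ok && right_ok && strict && peak_prominence(f, i) >= min_prom)
      return(list(peak_time = trace$times[i], peak_amplitude = f[i],
                  censored = NA_character_))
  }
  list(peak_time = NA_real_, peak_amplitude = NA_real_, censored = "no_peak")
}

#' Half-time of fluorescence decay after the peak
#'
#' Elapsed time from the peak until fluorescence first falls to
#' `baseline + 0.5 * (peak_amplitude - baseline)`, with linear
#' interpolation between the bracketing frames.  Halving is measured
#' relative to the pre-induction baseline because a stable reporter is
#' diluted by growth but never returns to zero within a movie.
#'
#' @param trace a [lineage_trace()].
#' @param peak_time,peak_amplitude the peak from [first_peak_amplitude()].
#' @param baseline pre-induction baseline fluorescence in AU; must be
#'   below `peak_amplitude`.
#' @return Half-decay time in minutes, or `NA` (censored:
#'   decay unfinished at trace end).
#' @export
decay_half_time <- function(trace, peak_time, peak_amplitude, baseline) {
  stopifnot(inherits(trace, "lineage_trace"))
  if (!is.finite(peak_time) || !is.finite(peak_amplitude))
    stop("invalid arguments: peak must be present", call. = FALSE)
  if (baseline >= peak_amplitude)
    stop("invalid arguments: baseline must be below peak_amplitude",
         call. = FALSE)
  target <- baseline + 0.5 * (peak_amplitude - baseline)
  pi_idx <- which(trace$times >= peak_time)[1L]
  if (is.na(pi_idx)) stop("invalid arguments: peak_time beyond trace",
                          call. = FALSE)
  f <- trace$fluorescence
  below <- which(f <= target & seq_along(f) > pi_idx)
  if (!length(below)) return(NA_real_)
  j <- below[1L]
  # linear interpolation between the bracketing frames
  t_half <- if (f[j - 1L] > target) {
    trace$times[j - 1L] + (f[j - 1L] - target) / (f[j - 1L] - f[j]) *
      (trace$times[j] - trace$times[j - 1L])
  } else trace$times[j - 1L]
  t_half - peak_time
}

#' Extract all induction features from one trace
#'
#' Bundles [threshold_crossing_time()], [max_induction_rate()],
#' [first_peak_amplitude()] and [decay_half_time()] with consistent
#' censoring: a trace contributes each feature at most once, and every
#' censored feature carries a reason (`never_crossed`, `no_peak`,
#' `decay_unfinished`, `trace_too_short`, `no_rise`).
#'
#' @param trace a [lineage_trace()].
#' @param threshold activation threshold in AU (default 1000).
#' @param smooth_window passed to [max_induction_rate()].
#' @param prominence_fraction passed to [first_peak_amplitude()].
#' @return One-row data frame of class `trace_features` with columns
#'   `trap_id`, `strain`, `crossing_time`, `max_rate`, `peak_time`,
#'   `peak_amplitude`, `decay_half_time`, `censor_reasons` (comma-joined,
#'   empty when fully observed).
#' @export
trace_features <- function(trace, threshold = 1000, smooth_window = 1L,
                           prominence_fraction = 0.1) {
  stopifnot(inherits(trace, "lineage_trace"))
  reasons <- character(0)
  out <- list(crossing_time = NA_real_, max_rate = NA_real_,
              peak_time = NA_real_, peak_amplitude = NA_real_,
              decay_half_time = NA_real_)
  if (length(trace$times) < 2L) {
    reasons <- "trace_too_short"
  } else {
    out$crossing_time <- threshold_crossing_time(trace, threshold)
    if (is.na(out$crossing_time)) {
      reasons <- "never_crossed"
    } else {
      out$max_rate <- max_induction_rate(trace, threshold, smooth_window)
      if (is.na(out$max_rate)) reasons <- c(reasons, "no_rise")
      pk <- first_peak_amplitude(trace, threshold, prominence_fraction)
      if (is.na(pk$censored)) {
        out$peak_time <- pk$peak_time
        out$peak_amplitude <- pk$peak_amplitude
        ci <- crossing_index(trace$fluorescence, threshold)
        f0_est <- if (ci > 1L) median(trace$fluorescence[seq_len(ci - 1L)])
                  else min(trace$fluorescence)
        if (f0_est >= pk$peak_amplitude) f0_est <- 0
        out$decay_half_time <- decay_half_time(trace, pk$peak_time,
                                               pk$peak_amplitude, f0_est)
        if (is.na(out$decay_half_time))
          reasons <- c(reasons, "decay_unfinished")
      } else {
        reasons <- c(reasons, pk$censored)
      }
    }
  }
  res <- data.frame(trap_id = trace$trap_id, strain = trace$strain_label,
                    crossing_time = out$crossing_time,
                    max_rate = out$max_rate,
                    peak_time = out$peak_time,
                    peak_amplitude = out$peak_amplitude,
                    decay_half_time = out$decay_half_time,
                    censor_reasons = paste(reasons, collapse = ","),
                    stringsAsFactors = FALSE)
  class(res) <- c("trace_features", "data.frame")
  res
}

#' @rdname trace_features
#' @param traces a list of [lineage_trace()] objects.
#' @return `extract_trace_features()`: a data frame with one row per trace.
#' @export
extract_trace_features <- function(traces, threshold = 1000,
                                   smooth_window = 1L,
                                   prominence_fraction = 0.1) {
  stopifnot(length(traces) >= 1L)
  out <- do.call(rbind, lapply(traces, trace_features, threshold = threshold,
                               smooth_window = smooth_window,
                               prominence_fraction = prominence_fraction))
  rownames(out) <- NULL
  out
}

#' Time-resolved fraction of threshold-positive cells
#'
#' At each acquisition time, the fraction of traces with fluorescence at
#' or above the threshold among traces that have data at that time, with
#' the cell count reported per frame.
#'
#' @param traces list of [lineage_trace()] objects.
#' @param threshold fluorescence threshold in AU (default 1000).
#' @return Data frame with columns `time_min`, `fraction`, `n_cells`.
#' @export
fraction_positive_over_time <- function(traces, threshold = 1000) {
  stopifnot(length(traces) >= 1L)
  all_times <- sort(unique(unlist(lapply(traces, `[[`, "times"))))
  pos <- matrix(NA, length(all_times), length(traces))
  for (k in seq_along(traces)) {
    tr <- traces[[k]]
    idx <- match(round(tr$times, 6), round(all_times, 6))
    pos[idx, k] <- tr$fluorescence >= threshold
  }
  n_cells <- rowSums(!is.na(pos))
  data.frame(time_min = all_times,
             fraction = ifelse(n_cells > 0, rowMeans(pos, na.rm = TRUE), NA),
             n_cells = n_cells)
}
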