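#' Detect division events from a length series
#'
#' A frame is flagged as the first frame after a division when the length
#' drops by more than `drop_fraction` relative to the previous frame.
#' Frame 1 is never flagged.
#'
#' @param lengths cell lengths in micrometres; all > 0.
#' @param drop_fraction relative drop that defines a division (default
#'   0.25, i.e. flag when `lengths[i] < 0.75 * lengths[i-1]`).
#' @return Logical vector of per-frame division flags.
#' @export
#' @examples
#' detect_divisions(c(2.0, 2.2, 1.1, 1.2))
detect_divisions <- function(lengths, drop_fraction = 0.25) {
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("invalid trace: lengths must be finite and > 0", call. = FALSE)
  n <- length(lengths)
  if (n < 2L) return(rep(FALSE, n))
  c(FALSE, lengths[-1L] < (1 - drop_fraction) * lengths[-n])
}

# least-squares slope of y on x (NA when < 2 points or degenerate x)
ls_slope <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  xm <- x - mean(x)
  denom <- sum(xm^2)
  if (denom == 0) return(NA_real_)
  sum(xm * (y - mean(y))) / denom
}

#' Instantaneous single-cell growth rate
#'
#' The fold rate of change in length: at each frame the least-squares
#' slope of log(length) against time over a centered window of `window`
#' frames, computed strictly within one inter-division segment (division
#' flags break segments).  Frames whose window would span a division or
#' the trace boundary use the one-sided window of available frames;
#' single-frame segments yield `NA`.  The estimate is invariant to
#' rescaling all lengths by a constant.
#'
#' @param trace a [lineage_trace()].
#' @param window odd window width in frames (default 3).
#' @return Numeric vector of per-frame rates (1/min), `NA` where undefined.
#' @export
#' @examples
#' tr <- lineage_trace("a", seq(0, 50, 10), 2 * exp(0.01 * seq(0, 50, 10)),
#'                     rep(100, 6))
#' instantaneous_growth_rate(tr)
instantaneous_growth_rate <- function(trace, window = 3L) {
  stopifnot(inherits(trace, "lineage_trace"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be odd and >= 1", call. = FALSE)
  n <- length(trace$times)
  if (n < 2L) stop("invalid trace: need at least 2 frames", call. = FALSE)
  if (any(trace$lengths <= 0))
    stop("invalid trace: non-positive lengths", call. = FALSE)
  logl <- log(trace$lengths)
  h <- (window - 1L) %/% 2L
  # segment id increments at each division flag
  seg <- cumsum(trace$division_flags)
  seg_start <- ave(seq_len(n), seg, FUN = min)
  seg_end <- ave(seq_len(n), seg, FUN = max)
  rate <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(seg_start[i], i - h)
    hi <- min(seg_end[i], i + h)
    if (hi > lo)
      rate[i] <- ls_slope(trace$times[lo:hi], logl[lo:hi])
  }
  rate
}

#' Population growth-rate profile
#'
#' Median and interquartile range of the instantaneous growth rate across
#' traces at each acquisition time, as displayed for mother-machine
#' experiments (the cell count per frame is reported alongside).
#'
#' @param traces list of [lineage_trace()] objects.
#' @param window passed to [instantaneous_growth_rate()].
#' @return A data frame of class `growth_rate_series` with columns
#'   `time_min`, `median_rate`, `q25`, `q75`, `n_cells`.
#' @export
growth_rate_series <- function(traces, window = 3L) {
  stopifnot(length(traces) >= 1L)
  all_times <- sort(unique(unlist(lapply(traces, `[[`, "times"))))
  mat <- matrix(NA_real_, length(all_times), length(traces))
  for (k in seq_along(traces)) {
    tr <- traces[[k]]
    idx <- match(round(tr$times, 6), round(all_times, 6))
    mat[idx, k] <- instantaneous_growth_rate(tr, window)
  }
  qs <- t(apply(mat, 1L, function(r)
    if (all(is.na(r))) c(NA_real_, NA_real_, NA_real_)
    else quantile(r, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)))
  out <- data.frame(time_min = all_times,
                    median_rate = qs[, 2L], q25 = qs[, 1L], q75 = qs[, 3L],
                    n_cells = rowSums(!is.na(mat)))
  class(out) <- c("growth_rate_series", "data.frame")
  out
}
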