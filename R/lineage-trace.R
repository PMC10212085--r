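#' Construct a single mother-cell lineage trace
#'
#' A `lineage_trace` holds one mother cell's time series from a dead-end
#' mother-machine trap: cell length, per-cell reporter fluorescence, and
#' division events.  Daughter cells are washed away at division, so the
#' trace follows a single cell through many division cycles.
#'
#' @param trap_id identifier (coerced to character).
#' @param times acquisition times in minutes; strictly increasing, uniform
#'   spacing.
#' @param lengths cell length in micrometres per frame; all > 0.
#' @param fluorescence per-cell reporter fluorescence in AU per frame;
#'   all >= 0.
#' @param division_flags logical per frame; `TRUE` on the first frame after
#'   a division.  Frame 1 is never flagged.
#' @param strain_label free-text strain label.
#' @return A list of class `lineage_trace`.
#' @export
#' @examples
#' tr <- lineage_trace("t1", times = c(0, 10, 20),
#'                     lengths = c(2, 2.4, 1.3),
#'                     fluorescence = c(100, 110, 120),
#'                     division_flags = c(FALSE, FALSE, TRUE))
lineage_trace <- function(trap_id, times, lengths, fluorescence,
                          division_flags = NULL, strain_label = "unknown") {
  n <- length(times)
  if (n < 1L) stop("invalid trace: no frames", call. = FALSE)
  if (length(lengths) != n || length(fluorescence) != n)
    stop("invalid trace: lengths/fluorescence must match times", call. = FALSE)
  if (is.null(division_flags)) division_flags <- rep(FALSE, n)
  if (length(division_flags) != n)
    stop("invalid trace: division_flags must match times", call. = FALSE)
  if (n > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("invalid trace: times must be strictly increasing",
                           call. = FALSE)
    if (max(abs(dt - dt[1L])) > 0.01 * dt[1L])
      stop("invalid trace: non-uniform frame spacing (beyond 1%)", call. = FALSE)
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("invalid trace: lengths must be finite and > 0", call. = FALSE)
  if (any(!is.finite(fluorescence)) || any(fluorescence < 0))
    stop("invalid trace: fluorescence must be finite and >= 0", call. = FALSE)
  division_flags[1L] <- FALSE
  structure(
    list(trap_id = as.character(trap_id),
         times = as.numeric(times),
         lengths = as.numeric(lengths),
         fluorescence = as.numeric(fluorescence),
         division_flags = as.logical(division_flags),
         strain_label = as.character(strain_label)),
    class = "lineage_trace")
}

#' @export
print.lineage_trace <- function(x, ...) {
  cat("<lineage_trace>", x$trap_id, sprintf("(%s)", x$strain_label),
      length(x$times), "frames,",
      sum(x$division_flags), "divisions, F range",
      sprintf("[%.3g, %.3g] AU\n", min(x$fluorescence), max(x$fluorescence)))
  invisible(x)
}

#' @export
length.lineage_trace <- function(x) length(x$times)

trace_frame_interval <- function(trace) {
  if (length(trace$times) < 2L) return(NA_real_)
  trace$times[2L] - trace$times[1L]
}

#' Convert lineage traces to/from a tidy data frame
#'
#' One row per (trap, frame) with columns `trap_id`, `time_min`,
#' `length_um`, `fluor_au`, `division` (0/1) and `strain`.
#'
#' @param traces a list of [lineage_trace()] objects.
#' @return `traces_to_df()`: a `data.frame`; `df_to_traces()`: a list of
#'   `lineage_trace`.
#' @export
traces_to_df <- function(traces) {
  stopifnot(length(traces) >= 1L)
  dt <- data.table::rbindlist(lapply(traces, function(tr) {
    data.table::data.table(
      trap_id = tr$trap_id, time_min = tr$times, length_um = tr$lengths,
      fluor_au = tr$fluorescence, division = as.integer(tr$division_flags),
      strain = tr$strain_label)
  }))
  data.table::setDF(dt)
  dt
}

#' @rdname traces_to_df
#' @param df a data frame with at least `trap_id`, `time_min`, `length_um`,
#'   `fluor_au`; `division` and `strain` are optional (missing division
#'   flags are reconstructed with [detect_divisions()]).
#' @export
df_to_traces <- function(df) {
  required <- c("trap_id", "time_min", "length_um", "fluor_au")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  has_div <- "division" %in% names(df)
  has_strain <- "strain" %in% names(df)
  split_idx <- split(seq_len(nrow(df)), df$trap_id)
  # preserve first-appearance order of traps
  first <- vapply(split_idx, min, 0L)
  split_idx <- split_idx[order(first)]
  lapply(split_idx, function(idx) {
    sub <- df[idx, , drop = FALSE]
    sub <- sub[order(sub$time_min), , drop = FALSE]
    flags <- if (has_div) as.logical(sub$division) else
      detect_divisions(sub$length_um)
    lineage_trace(
      trap_id = sub$trap_id[1L], times = sub$time_min,
      lengths = sub$length_um, fluorescence = sub$fluor_au,
      division_flags = flags,
      strain_label = if (has_strain) sub$strain[1L] else "unknown")
  })
}
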