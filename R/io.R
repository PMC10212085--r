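# CSV interchange.  Tidy layout, one observation per row, UTF-8, header
# row, '.' decimal separator.  Doubles are written with 17 significant
# digits, which round-trips IEEE doubles exactly, so write -> read is
# lossless.

# exact decimal representation of doubles (17 significant digits)
fmt_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

#' Write and read lineage traces as tidy CSV
#'
#' One row per (trap, frame): `trap_id`, `time_min`, `length_um`,
#' `fluor_au`, `division` (0/1), `strain`.  `read_traces()` accepts files
#' lacking the `division` column (flags are then reconstructed with
#' [detect_divisions()]) and validates uniform frame spacing per trace
#' (to within 1%).
#'
#' @param traces list of [lineage_trace()] objects.
#' @param path CSV file path.
#' @return `read_traces()`: a list of `lineage_trace`, grouped by trap and
#'   sorted by time; `write_traces()`: the path, invisibly.
#' @export
write_traces <- function(traces, path) {
  df <- traces_to_df(traces)
  for (col in c("time_min", "length_um", "fluor_au"))
    df[[col]] <- fmt_double(df[[col]])
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, data.table = FALSE,
                          colClasses = list(character = "trap_id"))
  df_to_traces(df)
}

#' Write and read population samples as CSV
#'
#' One row per cell: `replicate_id`, `strain`, `fluor_au`.
#'
#' @param samples list of [population_sample()] objects.
#' @param path CSV file path.
#' @return `read_population()`: a list of `population_sample`;
#'   `write_population()`: the path, invisibly.
#' @export
write_population <- function(samples, path) {
  if (inherits(samples, "population_sample")) samples <- list(samples)
  dt <- data.table::rbindlist(lapply(samples, function(s)
    data.table::data.table(replicate_id = s$replicate_id,
                           strain = s$strain_label,
                           fluor_au = fmt_double(s$fluorescence))))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, data.table = FALSE,
                          colClasses = list(character = "replicate_id"))
  required <- c("replicate_id", "fluor_au")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  has_strain <- "strain" %in% names(df)
  split_idx <- split(seq_len(nrow(df)), df$replicate_id)
  first <- vapply(split_idx, min, 0L)
  split_idx <- split_idx[order(first)]
  lapply(split_idx, function(idx) {
    sub <- df[idx, , drop = FALSE]
    population_sample(sub$replicate_id[1L], sub$fluor_au,
                      if (has_strain) sub$strain[1L] else "unknown")
  })
}
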