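#' Describe the on-disk layout of a delimited potentiostat export
#'
#' A dialect declares how a delimited text file maps onto the canonical
#' trace: which columns hold which channels, their units, and the reference
#' electrode the potentials were recorded against. The reference offset has
#' no default when a potential column is declared: the physical reference is
#' never guessed, so a file recorded vs Ag/AgCl cannot silently masquerade
#' as SHE.
#'
#' @param sep field separator, `","` or `"\t"`.
#' @param time_col,current_col names of the mandatory columns.
#' @param potential_col,stimulus_col optional channel column names.
#' @param time_unit `"s"`, `"ms"`, or `"min"`.
#' @param current_unit `"uA"`, `"nA"`, or `"mA"`.
#' @param potential_unit `"mV"` or `"V"`.
#' @param ref_offset_mV additive offset (mV) converting the file's potentials
#'   to the SHE scale (e.g. +197 for Ag/AgCl 3 M KCl). Required whenever
#'   `potential_col` is given; use 0 for files already on the SHE scale.
#' @param comment_char lines starting with this character are skipped.
#'
#' @return A list of class `trace_dialect`.
#' @export
trace_dialect <- function(sep = ",", time_col = "time", current_col = "current",
                          potential_col = NULL, stimulus_col = NULL,
                          time_unit = "s", current_unit = "uA",
                          potential_unit = "mV", ref_offset_mV = NULL,
                          comment_char = "#") {
  if (!sep %in% c(",", "\t")) stop("sep must be ',' or tab", call. = FALSE)
  if (!is.null(potential_col) && is.null(ref_offset_mV)) {
    stop("a dialect declaring a potential column must state ref_offset_mV ",
         "(0 for files already vs SHE)", call. = FALSE)
  }
  time_unit <- match.arg(time_unit, c("s", "ms", "min"))
  current_unit <- match.arg(current_unit, c("uA", "nA", "mA"))
  potential_unit <- match.arg(potential_unit, c("mV", "V"))
  structure(list(sep = sep, time_col = time_col, current_col = current_col,
                 potential_col = potential_col, stimulus_col = stimulus_col,
                 time_unit = time_unit, current_unit = current_unit,
                 potential_unit = potential_unit,
                 ref_offset_mV = ref_offset_mV,
                 comment_char = comment_char),
            class = "trace_dialect")
}

time_factor <- c(s = 1, ms = 1e-3, min = 60)
current_factor <- c(uA = 1, nA = 1e-3, mA = 1e3)
potential_factor <- c(mV = 1, V = 1e3)

#' Read a delimited potentiostat export into a canonical trace
#'
#' Parses a delimited text file and returns the trace in canonical units
#' (seconds, microamperes, mV vs SHE). The dialect's reference offset is
#' added to the potential channel so downstream code only ever sees the SHE
#' scale.
#'
#' @param source path to a delimited text file (or a connection).
#' @param dialect a [trace_dialect()] describing the layout.
#' @param metadata optional [experiment_metadata()] to attach.
#'
#' @return A [ts_trace()].
#' @export
read_trace <- function(source, dialect = trace_dialect(), metadata = NULL) {
  stopifnot(inherits(dialect, "trace_dialect"))
  df <- utils::read.table(source, header = TRUE, sep = dialect$sep,
                          comment.char = dialect$comment_char,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(dialect$time_col, dialect$current_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("format error: required column(s) %s not found in header",
                 paste(sQuote(missing_cols), collapse = ", ")), call. = FALSE)
  }
  time <- df[[dialect$time_col]] * time_factor[[dialect$time_unit]]
  bad <- which(diff(time) <= 0)
  if (length(bad)) {
    stop(sprintf("data error: time not strictly increasing at row %d",
                 bad[1] + 1L), call. = FALSE)
  }
  current <- df[[dialect$current_col]] * current_factor[[dialect$current_unit]]
  potential <- NULL
  if (!is.null(dialect$potential_col) &&
      dialect$potential_col %in% names(df)) {
    potential <- df[[dialect$potential_col]] *
      potential_factor[[dialect$potential_unit]] + dialect$ref_offset_mV
  }
  stimulus <- NULL
  if (!is.null(dialect$stimulus_col) && dialect$stimulus_col %in% names(df)) {
    stimulus <- df[[dialect$stimulus_col]]
  }
  if (is.null(metadata)) {
    metadata <- experiment_metadata(
      reference_electrode_offset = dialect$ref_offset_mV %||% 0)
  }
  ts_trace(time, current, potential = potential, stimulus = stimulus,
           metadata = metadata)
}

#' Write a trace to delimited text
#'
#' Writes the canonical channels so that re-reading with the same dialect
#' reproduces them to numeric-text precision. Potentials are converted back
#' to the dialect's raw reference scale (the inverse of [read_trace()]), and
#' optional channels absent from the trace are omitted from the file.
#'
#' @param trace a [ts_trace()].
#' @param sink output file path.
#' @param dialect a [trace_dialect()]; its unit and reference declarations
#'   are applied in reverse.
#' @return Invisibly, `sink`.
#' @export
write_trace <- function(trace, sink, dialect = trace_dialect()) {
  stopifnot(inherits(trace, "ts_trace"), inherits(dialect, "trace_dialect"))
  if (nrow(trace) == 0L) stop("cannot write an empty trace", call. = FALSE)
  out <- data.frame(check.names = FALSE,
    a = trace$time / time_factor[[dialect$time_unit]],
    b = trace$current / current_factor[[dialect$current_unit]])
  names(out) <- c(dialect$time_col, dialect$current_col)
  if (!is.null(trace$potential)) {
    if (is.null(dialect$potential_col)) {
      stop("trace has a potential channel but the dialect declares no ",
           "potential column", call. = FALSE)
    }
    out[[dialect$potential_col]] <-
      (trace$potential - dialect$ref_offset_mV) /
      potential_factor[[dialect$potential_unit]]
  }
  if (!is.null(trace$stimulus)) {
    col <- dialect$stimulus_col %||% "stimulus"
    out[[col]] <- trace$stimulus
  }
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     file = sink, sep = dialect$sep, quote = FALSE,
                     row.names = FALSE)
  invisible(sink)
}

#' Resample a trace onto a uniform time grid
#'
#' Linear interpolation of every channel onto a uniform grid spanning the
#' original time range. Metadata is preserved. Exact for signals that are
#' piecewise linear between the original samples.
#'
#' @param trace a [ts_trace()].
#' @param dt target sampling interval in seconds (> 0, smaller than the
#'   trace span).
#' @return A [ts_trace()] sampled every `dt` seconds.
#' @export
resample_uniform <- function(trace, dt) {
  stopifnot(inherits(trace, "ts_trace"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a positive scalar", call. = FALSE)
  }
  if (nrow(trace) < 2L) stop("trace must contain at least 2 samples",
                             call. = FALSE)
  span <- diff(range(trace$time))
  if (dt > span) stop("dt exceeds the trace time span", call. = FALSE)
  grid <- seq(min(trace$time), max(trace$time), by = dt)
  interp <- function(v) stats::approx(trace$time, v, xout = grid)$y
  ts_trace(grid, interp(trace$current),
           potential = if (!is.null(trace$potential)) interp(trace$potential),
           stimulus = if (!is.null(trace$stimulus)) interp(trace$stimulus),
           metadata = trace_metadata(trace))
}
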