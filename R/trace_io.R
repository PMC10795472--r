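# On-disk formats: traces as two-column CSV (time_s, current_pA) or a packed
# binary container for large recordings; event tables and ground truth as TSV;
# run configuration as flat key = value text. Metadata travels in a sidecar
# config file next to the trace.

#' Construct a current trace
#'
#' A uniformly sampled single-channel current recording. Currents are stored
#' signed in picoamperes; blockades are decreases from a positive open-pore
#' baseline toward zero.
#'
#' @param samples Numeric vector of current values (pA). Must be finite and
#'   non-empty.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param start_time Acquisition start time in seconds (default 0).
#' @param metadata Named list of free-form metadata (e.g. voltage_mV, buffer).
#' @return An object of class `current_trace`.
#' @examples
#' tr <- current_trace(rnorm(1000, 72, 1.5), sampling_rate = 10000)
#' tr
#' @export
current_trace <- function(samples, sampling_rate, start_time = 0,
                          metadata = list()) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("empty trace: need at least one sample")
  if (!all(is.finite(samples))) {
    stop("trace samples must be finite; first bad index: ",
         which(!is.finite(samples))[1])
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number (Hz)")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 start_time = start_time, metadata = metadata),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("<current_trace> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sampling_rate, dur))
  cat(sprintf("  current: mean %.2f pA, range [%.2f, %.2f] pA\n",
              mean(x$samples), min(x$samples), max(x$samples)))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.current_trace <- function(x) length(x$samples)

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".cfg")

#' Read a current trace from disk
#'
#' CSV traces are two columns (`time_s`, `current_pA`); the sampling rate is
#' taken from a sidecar config (`<name>.cfg`), from `sampling_rate`, or
#' inferred from the time column. Binary traces (`format = "bin"`) are the
#' packed container written by [write_trace()]. If the baseline polarity is
#' negative (median current below zero) the trace is flipped at read time and
#' `polarity_flipped = TRUE` is recorded in the metadata.
#'
#' @param path File to read.
#' @param format `"csv"` or `"bin"`; default guessed from the file extension.
#' @param sampling_rate Optional sampling rate (Hz) overriding file metadata.
#' @return A [current_trace()].
#' @export
read_trace <- function(path, format = c("auto", "csv", "bin"),
                       sampling_rate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bin$", path, ignore.case = TRUE)) "bin" else "csv"
  }
  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- read_run_config(sc)

  if (format == "bin") {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", 8L)
    if (!identical(rawToChar(magic), "PORETRC1")) {
      stop("not a porePTM binary trace: ", path)
    }
    hdr <- readBin(con, "double", 3L)
    n <- as.integer(hdr[3])
    samples <- readBin(con, "double", n)
    rate <- if (!is.null(sampling_rate)) sampling_rate else hdr[1]
    tr <- current_trace(samples, rate, start_time = hdr[2], metadata = meta)
    return(normalize_polarity(tr))
  }

  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty trace: ", path, " has a header but no rows")
  cur_col <- if ("current_pA" %in% names(df)) "current_pA" else names(df)[ncol(df)]
  cur <- suppressWarnings(as.numeric(df[[cur_col]]))
  if (anyNA(cur)) {
    stop("non-numeric current value at row ", which(is.na(cur))[1],
         " of ", path)
  }
  rate <- sampling_rate
  if (is.null(rate) && !is.null(meta$sampling_rate_Hz)) {
    rate <- as.numeric(meta$sampling_rate_Hz)
  }
  start_time <- 0
  if ("time_s" %in% names(df) && nrow(df) >= 2L) {
    tcol <- suppressWarnings(as.numeric(df$time_s))
    if (anyNA(tcol)) {
      stop("non-numeric time value at row ", which(is.na(tcol))[1], " of ", path)
    }
    start_time <- tcol[1]
    if (is.null(rate)) rate <- 1 / stats::median(diff(tcol))
  }
  if (is.null(rate)) {
    stop("missing sampling rate: supply `sampling_rate`, a sidecar config, ",
         "or a time_s column in ", path)
  }
  normalize_polarity(current_trace(cur, rate, start_time, meta))
}

normalize_polarity <- function(tr) {
  if (stats::median(tr$samples) < 0) {
    tr$samples <- -tr$samples
    tr$metadata$polarity_flipped <- TRUE
  }
  tr
}

#' Write a current trace to disk
#'
#' @param trace A [current_trace()].
#' @param path Output file.
#' @param format `"csv"` (two columns, full double precision) or `"bin"`
#'   (packed binary, suitable for long recordings).
#' @param sidecar Write metadata (including the sampling rate) to a sidecar
#'   config file next to the trace (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("csv", "bin"), sidecar = TRUE) {
  stopifnot(inherits(trace, "current_trace"))
  format <- match.arg(format)
  if (format == "bin") {
    con <- file(path, "wb")
    writeBin(charToRaw("PORETRC1"), con)
    writeBin(as.double(c(trace$sampling_rate, trace$start_time,
                         length(trace$samples))), con)
    writeBin(as.double(trace$samples), con)
    close(con)
  } else {
    tt <- trace$start_time + (seq_along(trace$samples) - 1L) / trace$sampling_rate
    lines <- c("time_s,current_pA",
               paste(sprintf("%.17g", tt), sprintf("%.17g", trace$samples),
                     sep = ","))
    writeLines(lines, path)
  }
  if (sidecar) {
    meta <- trace$metadata
    meta$sampling_rate_Hz <- trace$sampling_rate
    meta$start_time_s <- trace$start_time
    write_run_config(meta, sidecar_path(path))
  }
  invisible(path)
}

# --- event tables -----------------------------------------------------------

event_table_required <- c("event_id", "trace_id", "start_index", "end_index",
                          "dwell_ms", "mean_residual_pA", "rel_current_pct",
                          "rel_sigma", "n_extrema")
event_table_optional <- c("label", "prediction", "assessment_score")

#' Validate an event table
#'
#' Checks the column schema and row invariants of an event table: required
#' numeric columns present, `start_index < end_index`, positive dwell times,
#' non-negative relative currents, and optional columns (`label`,
#' `prediction`, `assessment_score`) either fully present or absent — a
#' column with a mix of values and missing entries is rejected.
#'
#' @param events A data frame conforming to the event-table schema.
#' @return `events`, invisibly, if valid; otherwise an error naming the
#'   offending column.
#' @export
validate_event_table <- function(events) {
  stopifnot(is.data.frame(events))
  missing_cols <- setdiff(event_table_required, names(events))
  if (length(missing_cols)) {
    stop("event table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(events) == 0L) return(invisible(events))
  for (cn in setdiff(event_table_required, c("event_id", "trace_id"))) {
    if (!is.numeric(events[[cn]])) stop("column ", cn, " must be numeric")
  }
  if (any(events$start_index >= events$end_index)) {
    stop("column start_index: start_index must be < end_index")
  }
  if (any(events$dwell_ms <= 0)) stop("column dwell_ms: must be > 0")
  if (any(events$rel_current_pct < 0)) stop("column rel_current_pct: must be >= 0")
  for (cn in intersect(event_table_optional, names(events))) {
    nas <- is.na(events[[cn]])
    if (any(nas) && !all(nas)) {
      stop("column ", cn, ": optional columns must be fully present or absent, ",
           "found ", sum(nas), " missing of ", nrow(events))
    }
  }
  invisible(events)
}

#' Write / read an event table as TSV
#'
#' Numeric columns are serialized with 12 significant digits, so a write/read
#' round trip is lossless well past 9 significant digits.
#'
#' @param events A valid event table (see [validate_event_table()]).
#' @param path TSV file path.
#' @return `write_event_table` returns `path` invisibly; `read_event_table`
#'   returns the validated data frame.
#' @export
write_event_table <- function(events, path) {
  validate_event_table(events)
  out <- events
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) out[[cn]] <- sprintf("%.12g", out[[cn]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    for (cn in intersect(c(event_table_required[-(1:2)], "assessment_score"),
                         names(df))) {
      df[[cn]] <- as.numeric(df[[cn]])
    }
    df$start_index <- as.integer(round(df$start_index))
    df$end_index <- as.integer(round(df$end_index))
    df$n_extrema <- as.integer(round(df$n_extrema))
  }
  validate_event_table(df)
  df
}

# --- run configuration ------------------------------------------------------

#' Flat key/value run configuration files
#'
#' One `key = value` pair per line; `#` starts a comment. Values that parse
#' as numbers are returned numeric.
#'
#' @param config Named list of scalar values.
#' @param path File path.
#' @return `read_run_config` returns a named list.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config))
  keys <- names(config)
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }, character(1))
  writeLines(paste(keys, vals, sep = " = "), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
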