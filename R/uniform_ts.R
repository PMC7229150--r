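#' Uniformly sampled multichannel time series
#'
#' The universal currency of the pipeline: a gap-free, uniformly sampled
#' record of one or more sensor channels. `step` is the sampling interval in
#' the record's time unit (seconds for raw sensor records; whatever the
#' caller uses for simulated systems — see `time_unit`).
#'
#' @param values numeric vector or `n x c` matrix of samples (no missing
#'   values, `n >= 2`).
#' @param step positive sampling interval.
#' @param channels character vector of unique channel names; defaults to the
#'   matrix column names or `ch1, ch2, ...`.
#' @param start_time numeric or POSIXct start of the record (default 0).
#' @param time_unit label for the unit of `step` (default `"seconds"`).
#' @return an object of class `uniform_ts`.
#' @export
uniform_ts <- function(values, step, channels = NULL, start_time = 0,
                       time_unit = "seconds") {
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(channels)) {
    channels <- colnames(values)
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(values)))
  }
  if (length(channels) != ncol(values))
    stop("length(channels) must equal ncol(values)")
  if (anyDuplicated(channels))
    stop("channel names must be unique")
  if (!is.numeric(step) || length(step) != 1 || !is.finite(step) || step <= 0)
    stop("step must be a single positive number")
  if (nrow(values) < 2)
    stop("a uniform time series needs at least 2 samples")
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite with no missing entries")
  colnames(values) <- channels
  structure(
    list(values = values, step = as.numeric(step), channels = channels,
         start_time = start_time, time_unit = time_unit),
    class = "uniform_ts")
}

#' @export
print.uniform_ts <- function(x, ...) {
  cat(sprintf("<uniform_ts> %d samples x %d channel(s) [%s], step = %g %s\n",
              nrow(x$values), length(x$channels),
              paste(x$channels, collapse = ", "), x$step, x$time_unit))
  invisible(x)
}

#' Number of samples in a uniform time series
#' @param ts a `uniform_ts`.
#' @export
ut_n <- function(ts) nrow(ts$values)

#' Sample times of a uniform time series
#'
#' Times are relative to `start_time`, in units of `step`.
#' @param ts a `uniform_ts`.
#' @export
ut_time <- function(ts) (seq_len(ut_n(ts)) - 1) * ts$step

#' Extract one channel as a numeric vector
#' @param ts a `uniform_ts`.
#' @param channel channel name or column index.
#' @export
ut_channel <- function(ts, channel) {
  if (is.character(channel) && !(channel %in% ts$channels))
    stop(sprintf("unknown channel '%s' (available: %s)", channel,
                 paste(ts$channels, collapse = ", ")))
  as.numeric(ts$values[, channel])
}

#' Keep a subset of channels
#' @param ts a `uniform_ts`.
#' @param channels channel names to retain.
#' @export
ut_select <- function(ts, channels) {
  miss <- setdiff(channels, ts$channels)
  if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))
  uniform_ts(ts$values[, channels, drop = FALSE], ts$step, channels,
             ts$start_time, ts$time_unit)
}

#' @export
as.data.frame.uniform_ts <- function(x, ...) {
  data.frame(time = ut_time(x), x$values, check.names = FALSE)
}

#' Write a sensor record to the canonical CSV format
#'
#' Header `time,<channels...>` with time in seconds from record start and an
#' ISO-8601 start time in a `# start=` comment line. If the series carries a
#' generator configuration (attribute set by the simulators), it is emitted
#' into a sidecar JSON file `<path>.json` for provenance.
#'
#' @param ts a `uniform_ts`.
#' @param path output file path.
#' @param sidecar write the provenance sidecar when a configuration is
#'   attached (default TRUE).
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(ts, path, sidecar = TRUE) {
  start <- ts$start_time
  start_str <- if (inherits(start, "POSIXt"))
    format(start, "%Y-%m-%dT%H:%M:%OS3%z") else as.character(start)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# start=%s", start_str), con)
  df <- as.data.frame(ts)
  names(df)[1] <- "time"
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  cfg <- attr(ts, "sim_config")
  if (sidecar && !is.null(cfg)) {
    jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read the canonical sensor CSV
#'
#' Validates uniform spacing (relative tolerance 1e-6 of the median step) and
#' rejects gaps or duplicated timestamps rather than imputing. Any column
#' beyond `time` is preserved as a channel.
#'
#' @param path CSV file written by [write_sensor_csv()] or of the same shape.
#' @return a `uniform_ts`.
#' @export
read_sensor_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  start_time <- 0
  if (startsWith(first, "# start=")) {
    raw <- sub("^# start=", "", first)
    num <- suppressWarnings(as.numeric(raw))
    start_time <- if (!is.na(num)) num else raw
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!"time" %in% names(df)) stop("sensor CSV must have a 'time' column")
  tm <- df$time
  if (nrow(df) < 2) stop("sensor record too short (need >= 2 rows)")
  dt <- diff(tm)
  step <- stats::median(dt)
  if (step <= 0) stop("non-increasing timestamps around row ",
                      which(dt <= 0)[1] + 1)
  bad <- which(abs(dt - step) > 1e-6 * step)
  if (length(bad)) {
    i <- bad[1]
    stop(sprintf(
      "non-uniform sampling: gap of %g between t=%g (row %d) and t=%g (row %d); expected step %g",
      dt[i], tm[i], i, tm[i + 1], i + 1, step))
  }
  vals <- as.matrix(df[, setdiff(names(df), "time"), drop = FALSE])
  uniform_ts(vals, step, start_time = start_time)
}
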