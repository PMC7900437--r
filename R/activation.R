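#' Activation-time series container
#'
#' Holds per-electrode local activation times (AT, ms) over an analysis
#' window. Each electrode's times must be strictly increasing and separated
#' by at least a refractory floor; all times must lie inside the window.
#'
#' @param events Data frame with columns `electrode` (integer id on `grid`)
#'   and `at_ms` (activation time, ms). Extra columns are kept.
#' @param grid An `electrode_grid` the electrode ids refer to.
#' @param window_ms Length-2 numeric `c(start, end)` of the analysis window
#'   in ms; default spans the observed times.
#' @param refractory_floor_ms Minimum allowed interval between successive
#'   activations at one electrode (ms). Default 40 ms, shorter than any
#'   plausible atrial refractory period.
#'
#' @return An object of class `activation_series`: list with `events`
#'   (sorted by electrode then time), `window_ms`, `refractory_floor_ms`.
#' @export
activation_series <- function(events, grid, window_ms = NULL,
                              refractory_floor_ms = 40) {
  stopifnot(is.data.frame(events), all(c("electrode", "at_ms") %in% names(events)))
  if (nrow(events)) {
    bad <- !(events$electrode %in% grid$electrodes$electrode)
    if (any(bad))
      stop("unknown electrode id(s): ",
           paste(unique(events$electrode[bad]), collapse = ", "))
    if (anyNA(events$at_ms) || any(!is.finite(events$at_ms)))
      stop("activation times must be finite")
  }
  events <- events[order(events$electrode, events$at_ms), , drop = FALSE]
  rownames(events) <- NULL
  if (is.null(window_ms)) {
    window_ms <- if (nrow(events)) range(events$at_ms) else c(0, 0)
  }
  stopifnot(length(window_ms) == 2, window_ms[2] >= window_ms[1])
  if (nrow(events)) {
    if (any(events$at_ms < window_ms[1] - 1e-9) ||
        any(events$at_ms > window_ms[2] + 1e-9))
      stop("activation times outside the analysis window")
    d <- diff(events$at_ms)
    same <- diff(events$electrode) == 0L
    if (any(same & d <= 0))
      stop("per-electrode activation times must be strictly increasing")
    if (any(same & d < refractory_floor_ms - 1e-9))
      stop("successive activations closer than the refractory floor (",
           refractory_floor_ms, " ms)")
  }
  structure(list(events = events, window_ms = as.numeric(window_ms),
                 refractory_floor_ms = refractory_floor_ms),
            class = "activation_series")
}

#' @export
print.activation_series <- function(x, ...) {
  cat(sprintf(
    "<activation_series> %d events at %d electrodes, window [%.1f, %.1f] ms\n",
    nrow(x$events), length(unique(x$events$electrode)),
    x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' @export
summary.activation_series <- function(object, ...) {
  ev <- object$events
  n_per <- if (nrow(ev)) table(ev$electrode) else integer(0)
  out <- list(n_events = nrow(ev),
              n_electrodes = length(n_per),
              window_ms = object$window_ms,
              median_events_per_electrode = if (length(n_per)) stats::median(as.integer(n_per)) else NA)
  class(out) <- "summary.activation_series"
  out
}

#' @export
print.summary.activation_series <- function(x, ...) {
  cat(sprintf("%d events / %d electrodes; window [%.1f, %.1f] ms; median %s events per electrode\n",
              x$n_events, x$n_electrodes, x$window_ms[1], x$window_ms[2],
              format(x$median_events_per_electrode)))
  invisible(x)
}

# split into per-electrode sorted time vectors (internal)
at_list <- function(series, grid) {
  out <- vector("list", grid$n_electrodes)
  sp <- split(series$events$at_ms, series$events$electrode)
  out[as.integer(names(sp))] <- sp
  out
}

#' Write and read activation maps as tidy CSV
#'
#' One row per activation event with columns
#' `electrode_id, row, col, x_mm, y_mm, region, at_ms` (UTF-8, '.' decimal).
#'
#' @param series An `activation_series`.
#' @param grid The `electrode_grid` the series refers to; used to emit
#'   coordinates on write and to validate electrode ids on read.
#' @param path CSV file path.
#' @param window_ms Optional analysis window passed to the rebuilt series
#'   (default: span of the stored times).
#' @return `read_activation_map` returns an `activation_series`;
#'   `write_activation_map` returns `path` invisibly.
#' @export
write_activation_map <- function(series, grid, path) {
  ev <- series$events
  m <- match(ev$electrode, grid$electrodes$electrode)
  out <- data.frame(
    electrode_id = ev$electrode,
    row = grid$electrodes$row[m], col = grid$electrodes$col[m],
    x_mm = grid$electrodes$x_mm[m], y_mm = grid$electrodes$y_mm[m],
    region = grid$electrodes$region[m],
    at_ms = ev$at_ms)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_activation_map
#' @export
read_activation_map <- function(path, grid, window_ms = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("electrode_id", "at_ms")
  if (!all(need %in% names(df)))
    stop("malformed activation map: need columns ",
         paste(need, collapse = ", "))
  if (!is.numeric(df$at_ms)) stop("malformed activation map: at_ms not numeric")
  activation_series(
    data.frame(electrode = as.integer(df$electrode_id), at_ms = df$at_ms),
    grid, window_ms = window_ms)
}

#' Unipolar electrogram recording container
#'
#' @param signal Numeric matrix, channels x samples, in mV; finite values
#'   only.
#' @param sampling_rate_hz Sampling rate (> 0); the mapping hardware default
#'   is 1039 Hz.
#' @param channel_map Integer vector, one electrode id per signal row
#'   (`NA` for the ventricular reference channel, if present).
#' @param reference_channel Row index of the ventricular reference channel,
#'   or `NULL`.
#' @return Object of class `egm_recording`.
#' @export
egm_recording <- function(signal, sampling_rate_hz = 1039,
                          channel_map = NULL, reference_channel = NULL) {
  signal <- as.matrix(signal)
  stopifnot(sampling_rate_hz > 0)
  if (any(!is.finite(signal))) stop("signal must contain finite values only")
  if (is.null(channel_map)) channel_map <- seq_len(nrow(signal))
  if (length(channel_map) != nrow(signal))
    stop("channel_map length must equal the channel count")
  if (!is.null(reference_channel)) {
    stopifnot(reference_channel >= 1, reference_channel <= nrow(signal))
    channel_map[reference_channel] <- NA_integer_
  }
  structure(list(signal = signal, sampling_rate_hz = sampling_rate_hz,
                 channel_map = as.integer(channel_map),
                 reference_channel = reference_channel),
            class = "egm_recording")
}

#' @export
print.egm_recording <- function(x, ...) {
  cat(sprintf("<egm_recording> %d channels x %d samples @ %g Hz (%.2f s)%s\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate_hz,
              ncol(x$signal) / x$sampling_rate_hz,
              if (!is.null(x$reference_channel))
                sprintf(", ventricular reference on channel %d",
                        x$reference_channel) else ""))
  invisible(x)
}

# time axis in ms for a recording (internal)
rec_time_ms <- function(rec) {
  (seq_len(ncol(rec$signal)) - 1) / rec$sampling_rate_hz * 1000
}

#' Write and read electrogram recordings
#'
#' The container is a raw channels x samples matrix (row-major float64,
#' little-endian, extension `.dat`, or CSV for small fixtures) plus a JSON
#' sidecar `<path>.json` holding `sampling_rate_hz`, dimensions,
#' `channel_map`, `reference_channel` and the storage format.
#'
#' @param rec An `egm_recording`.
#' @param path Path of the matrix file (`.dat` or `.csv`); the sidecar is
#'   written next to it as `<path>.json`.
#' @param format `"bin"` (float64, bit-exact round trip) or `"csv"`
#'   (plain-text, full precision via 17 significant digits).
#' @return `read_recording` returns an `egm_recording`; `write_recording`
#'   returns `path` invisibly.
#' @export
write_recording <- function(rec, path, format = c("bin", "csv")) {
  format <- match.arg(format)
  if (format == "bin") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(t(rec$signal)), con, size = 8, endian = "little")
  } else {
    utils::write.table(format(rec$signal, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       path, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  jsonlite::write_json(
    list(sampling_rate_hz = rec$sampling_rate_hz,
         n_channels = nrow(rec$signal), n_samples = ncol(rec$signal),
         channel_map = rec$channel_map,
         reference_channel = rec$reference_channel,
         format = format),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate_hz))
    stop("sidecar lacks sampling_rate_hz")
  if (identical(meta$format, "csv")) {
    sig <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(sig) <- NULL
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, "double", n = meta$n_channels * meta$n_samples,
                 size = 8, endian = "little")
    sig <- matrix(v, nrow = meta$n_channels, byrow = TRUE)
  }
  if (nrow(sig) != meta$n_channels || ncol(sig) != meta$n_samples)
    stop("signal dimensions disagree with sidecar")
  cm <- meta$channel_map
  if (is.null(cm)) cm <- seq_len(nrow(sig))
  n_mapped <- sum(!is.na(cm))
  n_ref <- if (is.null(meta$reference_channel)) 0L else 1L
  if (n_mapped + n_ref != nrow(sig) && n_mapped != nrow(sig))
    stop("channel/electrode mismatch between sidecar and signal")
  egm_recording(sig, meta$sampling_rate_hz, as.integer(cm),
                reference_channel = meta$reference_channel)
}
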