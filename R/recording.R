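#' Multichannel recording container
#'
#' The universal input of the pipeline: a `[n_channels x n_samples]` voltage
#' matrix in microvolts plus sampling rate and grid geometry.
#'
#' @param data numeric matrix `[n_channels x n_samples]`, microvolts.
#' @param fs sampling rate in Hz (the hardware default is 10 kHz per
#'   channel; analyses work at any rate above twice the band of interest).
#' @param geometry a [grid_geometry()]; its channel count must match
#'   `nrow(data)`.
#' @param t0 start time of the first sample in seconds (default 0).
#' @return An object of class `mc_recording`.
#' @export
mc_recording <- function(data, fs, geometry, t0 = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (nrow(data) != n_channels(geometry))
    stop(sprintf("data has %d channels but geometry declares %d",
                 nrow(data), n_channels(geometry)))
  bad <- which(!is.finite(data))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(data))
    stop(sprintf("non-finite sample at channel %d, sample %d", i[1], i[2]))
  }
  structure(list(data = data, fs = as.numeric(fs), geometry = geometry,
                 t0 = as.numeric(t0)),
            class = "mc_recording")
}

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf(
    "mc_recording: %d channels x %d samples @ %g Hz (%.3f s), t0 = %g s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$t0))
  print(x$geometry)
  invisible(x)
}

#' Time axis of a recording
#' @param rec an [mc_recording()].
#' @return numeric vector of sample times in seconds.
#' @export
rec_times <- function(rec) rec$t0 + (seq_len(ncol(rec$data)) - 1) / rec$fs

# CSV container: '#' comment lines carry fs/t0/geometry as JSON, then one
# row per channel. Values are printed with %.17g so doubles round-trip
# bit-exactly.

#' Write a recording to the CSV container
#'
#' Plain-text format: a `# cortiwave-recording` magic line, one `# meta`
#' line holding fs, t0 and the full geometry as JSON, then one CSV row per
#' channel. Doubles are printed with 17 significant digits so that
#' `load_recording(save_recording(x))` reproduces `x` bit-exactly.
#'
#' @param rec an [mc_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path) {
  stopifnot(inherits(rec, "mc_recording"))
  g <- rec$geometry
  meta <- jsonlite::toJSON(list(
    fs = rec$fs, t0 = rec$t0, n_rows = g$n_rows, n_cols = g$n_cols,
    pitch = g$pitch, channel_order = unname(g$channel_order),
    bad_channels = g$bad_channels), auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# cortiwave-recording v1", paste0("# meta ", meta)), con)
  rows <- apply(rec$data, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = ","))
  writeLines(rows, con)
  invisible(path)
}

#' Load a recording from the CSV container
#'
#' Validates the geometry metadata against the data: a channel-count
#' mismatch or any non-finite sample is a hard error (named by channel and
#' sample index), never silently repaired.
#'
#' @param path file written by [save_recording()].
#' @return An [mc_recording()].
#' @export
load_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "# cortiwave-recording"))
    stop("not a cortiwave recording file: ", path)
  meta_line <- grep("^# meta ", lines, value = TRUE)
  if (!length(meta_line)) stop("missing geometry metadata in ", path)
  meta <- jsonlite::fromJSON(sub("^# meta ", "", meta_line[1L]))
  geometry <- grid_geometry(meta$n_rows, meta$n_cols, meta$pitch,
                            channel_order = meta$channel_order,
                            bad_channels = meta$bad_channels)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) != n_channels(geometry))
    stop(sprintf("file has %d channel rows but geometry declares %d",
                 length(body), n_channels(geometry)))
  data <- do.call(rbind, lapply(strsplit(body, ",", fixed = TRUE), as.numeric))
  mc_recording(data, fs = meta$fs, geometry = geometry, t0 = meta$t0)
}

# internal: slice a recording to a sample range, preserving metadata
rec_slice <- function(rec, from, to) {
  mc_recording(rec$data[, from:to, drop = FALSE], rec$fs, rec$geometry,
               t0 = rec$t0 + (from - 1) / rec$fs)
}
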