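#' Electrode-grid geometry
#'
#' Describes a regular rectangular micro-ECoG array: grid dimensions,
#' electrode pitch, the mapping from channel index to grid position, and the
#' set of bad (e.g. high-impedance) channels that are excluded from all
#' downstream statistics rather than interpolated.
#'
#' Channels are numbered 1..`n_rows * n_cols`, row-major from the top-left
#' corner of the array by default; `channel_order` may supply any other
#' bijection onto the lattice.
#'
#' @param n_rows,n_cols grid dimensions (default 8 x 8, 64 channels).
#' @param pitch centre-to-centre electrode spacing in micrometres
#'   (default 500).
#' @param channel_order integer matrix `[n_channels x 2]` giving the
#'   (row, col) of each channel, or `NULL` for row-major order.
#' @param bad_channels integer vector of channel indices to exclude from
#'   analysis (default none).
#' @return An object of class `grid_geometry`.
#' @examples
#' geom <- grid_geometry()                   # 8 x 8, 500 um pitch
#' geom <- grid_geometry(bad_channels = c(3, 17, 42))
#' @export
grid_geometry <- function(n_rows = 8L, n_cols = 8L, pitch = 500,
                          channel_order = NULL, bad_channels = integer()) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, is.numeric(pitch), pitch > 0)
  n_ch <- n_rows * n_cols
  if (is.null(channel_order)) {
    channel_order <- cbind(row = rep(seq_len(n_rows), each = n_cols),
                           col = rep(seq_len(n_cols), times = n_rows))
  } else {
    channel_order <- as.matrix(channel_order)
    storage.mode(channel_order) <- "integer"
    colnames(channel_order) <- c("row", "col")
  }
  if (nrow(channel_order) != n_ch || ncol(channel_order) != 2L)
    stop("channel_order must be an [n_channels x 2] (row, col) matrix")
  lin <- (channel_order[, 1L] - 1L) * n_cols + channel_order[, 2L]
  if (anyDuplicated(lin) || any(channel_order[, 1L] < 1L) ||
      any(channel_order[, 1L] > n_rows) || any(channel_order[, 2L] < 1L) ||
      any(channel_order[, 2L] > n_cols))
    stop("channel_order must be a bijection onto the row/col lattice")
  bad_channels <- sort(unique(as.integer(bad_channels)))
  if (length(bad_channels) && (min(bad_channels) < 1L || max(bad_channels) > n_ch))
    stop("bad_channels outside 1..n_channels")
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch = as.numeric(pitch),
                 channel_order = channel_order, bad_channels = bad_channels),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d, pitch %g um, %d bad channel(s)\n",
              x$n_rows, x$n_cols, x$pitch, length(x$bad_channels)))
  invisible(x)
}

#' Total channel count of a geometry
#' @param geometry a [grid_geometry()].
#' @return integer count `n_rows * n_cols`.
#' @export
n_channels <- function(geometry) geometry$n_rows * geometry$n_cols

#' Good (analysable) channels of a geometry
#' @param geometry a [grid_geometry()].
#' @return integer vector of channel indices not flagged bad.
#' @export
good_channels <- function(geometry)
  setdiff(seq_len(n_channels(geometry)), geometry$bad_channels)

#' Physical electrode positions
#'
#' Coordinates in micrometres in the array frame: x increases with column
#' (leftwards column 1 is x = 0), y increases with row (top row 1 is y = 0).
#'
#' @param geometry a [grid_geometry()].
#' @return numeric matrix `[n_channels x 2]` with columns `x`, `y` (um).
#' @export
channel_positions <- function(geometry) {
  co <- geometry$channel_order
  cbind(x = (co[, "col"] - 1) * geometry$pitch,
        y = (co[, "row"] - 1) * geometry$pitch)
}

#' Arrange a per-channel vector on the electrode grid
#'
#' Places `values[k]` at the (row, col) lattice position of channel `k`.
#' Bad channels are set to `NA` (flagged missing, never interpolated).
#'
#' @param values numeric vector, one value per channel.
#' @param geometry a [grid_geometry()].
#' @param kind map semantics: `"amplitude"` (uV), `"phase"` (radians, must
#'   lie in (-pi, pi]), or `"delay"` (ms).
#' @param id optional event id or timestamp carried along.
#' @return A `grid_map`: numeric `[n_rows x n_cols]` matrix with attributes
#'   `kind`, `id` and `geometry`.
#' @examples
#' gm <- map_to_grid(seq_len(64), grid_geometry())
#' gm[1, ]   # channels 1..8 (row-major order)
#' @export
map_to_grid <- function(values, geometry, kind = "amplitude", id = NULL) {
  if (length(values) != n_channels(geometry))
    stop("length(values) must equal the geometry channel count")
  kind <- match.arg(kind, c("amplitude", "phase", "delay"))
  if (kind == "phase") {
    ok <- is.na(values) | (values > -pi & values <= pi + 1e-12)
    if (!all(ok)) stop("phase values must lie in (-pi, pi]")
  }
  m <- matrix(NA_real_, geometry$n_rows, geometry$n_cols)
  co <- geometry$channel_order
  m[cbind(co[, "row"], co[, "col"])] <- as.numeric(values)
  if (length(geometry$bad_channels)) {
    bc <- co[geometry$bad_channels, , drop = FALSE]
    m[cbind(bc[, "row"], bc[, "col"])] <- NA_real_
  }
  structure(m, kind = kind, id = id, geometry = geometry, class = "grid_map")
}

#' Recover the channel vector from a grid map
#'
#' Inverse of [map_to_grid()] on non-bad channels; bad channels come back
#' as `NA`.
#'
#' @param gm a `grid_map`.
#' @return numeric vector of length `n_channels`.
#' @export
grid_to_channels <- function(gm) {
  geometry <- attr(gm, "geometry")
  co <- geometry$channel_order
  unclass(gm)[cbind(co[, "row"], co[, "col"])]
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("grid_map (%s): %d x %d\n", attr(x, "kind"),
              nrow(x), ncol(x)))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Heatmap of a grid map
#'
#' Base-graphics image of an 8 x 8 (or any) grid map, drawn with row 1 at
#' the top so the picture matches the array as physically laid out. Bad
#' channels appear blank.
#'
#' @param x a `grid_map`.
#' @param main plot title; defaults to the map kind.
#' @param ... passed to [graphics::image()].
#' @export
plot.grid_map <- function(x, main = attr(x, "kind"), ...) {
  m <- unclass(x)
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = main, ...)
  invisible(x)
}
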