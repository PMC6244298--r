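#' Spike-detection configuration
#'
#' Field-potential spike complexes (ictal and inter-ictal epileptiform
#' waveforms, not single-unit action potentials) are extracted by a voltage
#' threshold on the across-channel maximum absolute voltage. Window sizes
#' follow the two temporal regimes: ictal spikes are narrow and dense
#' (100 ms windows), inter-ictal spikes are broad and sparse (500 ms), so
#' each window holds exactly one spike complex.
#'
#' @param threshold detection threshold in uV (default 500).
#' @param window_ictal_ms window length for ictal context, ms (default 100).
#' @param window_interictal_ms window length for inter-ictal context, ms
#'   (default 500).
#' @param ictal_rate_cutoff local spike rate (spikes/s) at or above which
#'   context is called ictal (default 1).
#' @param rate_window_s width of the sliding window for the local-rate
#'   estimate, seconds (default 10).
#' @param refractory_ms events closer than this are merged into the one
#'   with the larger peak (default 50).
#' @param polarity `"abs"` (threshold on |v|, default) or `"pos"`
#'   (positive excursions only).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(threshold = 500, window_ictal_ms = 100,
                             window_interictal_ms = 500,
                             ictal_rate_cutoff = 1, rate_window_s = 10,
                             refractory_ms = 50,
                             polarity = c("abs", "pos")) {
  stopifnot(threshold > 0, window_ictal_ms > 0,
            window_ictal_ms <= window_interictal_ms, refractory_ms >= 0)
  structure(list(threshold = threshold, window_ictal_ms = window_ictal_ms,
                 window_interictal_ms = window_interictal_ms,
                 ictal_rate_cutoff = ictal_rate_cutoff,
                 rate_window_s = rate_window_s, refractory_ms = refractory_ms,
                 polarity = match.arg(polarity)),
            class = "detection_config")
}

#' One extracted spike event
#'
#' @param event_id integer id.
#' @param window `(start, end)` seconds in recording time.
#' @param segment `[n_channels x window samples]` voltage matrix, uV.
#' @param context `"ictal"` or `"interictal"`.
#' @param peak_channel channel holding the global peak.
#' @param peak_time time of the global peak, seconds.
#' @param fs sampling rate, Hz.
#' @param geometry the recording's [grid_geometry()].
#' @return An object of class `spike_event`.
#' @export
spike_event <- function(event_id, window, segment, context, peak_channel,
                        peak_time, fs, geometry) {
  structure(list(event_id = event_id, window = window,
                 segment = as.matrix(segment), context = context,
                 peak_channel = peak_channel, peak_time = peak_time,
                 fs = fs, geometry = geometry),
            class = "spike_event")
}

#' @export
print.spike_event <- function(x, ...) {
  cat(sprintf(
    "spike_event %s [%s]: %.3f–%.3f s, peak ch %d @ %.3f s\n",
    format(x$event_id), x$context, x$window[1], x$window[2],
    x$peak_channel, x$peak_time))
  invisible(x)
}

#' Threshold-based spike-event extraction
#'
#' Detection runs on the across-channel maximum (absolute) voltage over
#' good channels so a wave entering at any edge of the array is caught at
#' its first strong channel. Each supra-threshold excursion seeds one
#' candidate at its global peak; candidates closer than the refractory
#' interval are merged into the larger-peak one. Context (ictal vs
#' inter-ictal) is assigned from a sliding local-rate estimate, which then
#' sets the window length; windows are centred on the peak, kept inside the
#' recording, and made non-overlapping (overlapping windows merge into the
#' larger-peak event, preserving one spike complex per window).
#'
#' The recording should already be low-pass filtered at 120 Hz
#' ([preset_filter()] `"epileptic_lowpass"`); unfiltered input works but
#' high-frequency noise may fragment detections.
#'
#' @param rec an [mc_recording()].
#' @param cfg a [detection_config()].
#' @return list of [spike_event()]s sorted by time (possibly empty).
#' @export
detect_events <- function(rec, cfg = detection_config()) {
  n <- ncol(rec$data)
  fs <- rec$fs
  if (n < round(cfg$window_ictal_ms / 1000 * fs))
    stop("recording shorter than one detection window")
  gc <- good_channels(rec$geometry)
  v <- rec$data[gc, , drop = FALSE]
  vmax <- if (cfg$polarity == "abs")
    apply(abs(v), 2L, max) else apply(v, 2L, max)
  above <- vmax >= cfg$threshold
  if (!any(above)) return(list())

  # supra-threshold runs -> candidate peaks
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  peaks <- t(apply(runs, 1L, function(se) {
    i <- se[1]:se[2]
    j <- i[which.max(vmax[i])]
    c(sample = j, value = vmax[j])
  }))

  # refractory merge: keep the larger peak of any pair too close
  refr <- cfg$refractory_ms / 1000 * fs
  keep <- rep(TRUE, nrow(peaks))
  repeat {
    idx <- which(keep)
    if (length(idx) < 2L) break
    gaps <- diff(peaks[idx, "sample"])
    close_i <- which(gaps < refr)
    if (!length(close_i)) break
    a <- idx[close_i[1L]]; b <- idx[close_i[1L] + 1L]
    keep[if (peaks[a, "value"] >= peaks[b, "value"]) b else a] <- FALSE
  }
  peaks <- peaks[keep, , drop = FALSE]

  # sliding local rate -> context -> window length
  pk_t <- (peaks[, "sample"] - 1) / fs
  half <- cfg$rate_window_s / 2
  rate <- vapply(pk_t, function(t0)
    sum(pk_t >= t0 - half & t0 + half >= pk_t) / cfg$rate_window_s, 0)
  context <- ifelse(rate >= cfg$ictal_rate_cutoff, "ictal", "interictal")
  win_n <- ifelse(context == "ictal",
                  round(cfg$window_ictal_ms / 1000 * fs),
                  round(cfg$window_interictal_ms / 1000 * fs))

  # windows centred on peaks, clamped inside the recording
  lo <- pmax(1L, pmin(peaks[, "sample"] - win_n %/% 2L, n - win_n + 1L))
  hi <- lo + win_n - 1L
  if (any(hi > n)) stop("recording shorter than one detection window")

  # enforce non-overlap by merging into the larger-peak event
  keep <- rep(TRUE, length(lo))
  i <- 1L
  while (i < length(lo)) {
    nxt <- which(keep & seq_along(lo) > i)
    if (!length(nxt)) break
    j <- nxt[1L]
    if (!keep[i]) { i <- j; next }
    if (lo[j] <= hi[i]) {
      keep[if (peaks[i, "value"] >= peaks[j, "value"]) j else i] <- FALSE
      if (!keep[i]) i <- j
    } else i <- j
  }

  idx <- which(keep)
  lapply(seq_along(idx), function(k) {
    i <- idx[k]
    seg <- rec$data[, lo[i]:hi[i], drop = FALSE]
    sub <- seg[gc, , drop = FALSE]
    pk <- arrayInd(which.max(abs(sub)), dim(sub))
    spike_event(event_id = k,
                window = rec$t0 + c(lo[i] - 1L, hi[i]) / fs,
                segment = seg, context = context[i],
                peak_channel = gc[pk[1L]],
                peak_time = rec$t0 + (lo[i] - 1L + pk[2L] - 1L) / fs,
                fs = fs, geometry = rec$geometry)
  })
}
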