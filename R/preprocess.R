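#' Filter specification and named presets
#'
#' Butterworth designs applied forward-backward (zero-phase), so the
#' filtering adds no group delay — essential because time-delay estimation
#' downstream must not inherit filter delay. The effective order is
#' therefore twice the design order; presets are named by design order.
#'
#' Presets:
#' \describe{
#'   \item{theta}{band-pass 5–9 Hz, order 4 — the stationary-oscillation
#'     band.}
#'   \item{epileptic_lowpass}{low-pass 120 Hz, order 6 — preserves spike
#'     waveform shape while removing high-frequency noise.}
#'   \item{high_gamma}{band-pass 80–120 Hz, order 4 — the band whose power
#'     tracks local population firing, used for connectivity.}
#' }
#'
#' @param kind `"bandpass"` or `"lowpass"`.
#' @param band_hz `(low, high)` for bandpass, scalar cutoff for lowpass.
#' @param order filter order (4 or 6 for the presets).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "lowpass"), band_hz, order = 4L) {
  kind <- match.arg(kind)
  if (kind == "bandpass") {
    stopifnot(length(band_hz) == 2L, band_hz[1] > 0, band_hz[2] > band_hz[1])
  } else {
    stopifnot(length(band_hz) == 1L, band_hz > 0)
  }
  structure(list(kind = kind, band_hz = band_hz, order = as.integer(order)),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @param name preset name.
#' @export
preset_filter <- function(name = c("theta", "epileptic_lowpass", "high_gamma")) {
  switch(match.arg(name),
         theta = filter_spec("bandpass", c(5, 9), 4L),
         epileptic_lowpass = filter_spec("lowpass", 120, 6L),
         high_gamma = filter_spec("bandpass", c(80, 120), 4L))
}

#' Zero-phase Butterworth filtering of a recording
#'
#' Applies the design per channel with [signal::filtfilt()]
#' (forward-backward), preserving length and introducing no group delay.
#'
#' @param rec an [mc_recording()].
#' @param spec a [filter_spec()] or preset name.
#' @return A filtered [mc_recording()].
#' @export
apply_filter <- function(rec, spec = preset_filter("theta")) {
  if (is.character(spec)) spec <- preset_filter(spec)
  nyq <- rec$fs / 2
  hi <- max(spec$band_hz)
  if (hi >= nyq)
    stop(sprintf("band edge %g Hz not below Nyquist (%g Hz)", hi, nyq))
  w <- spec$band_hz / nyq
  bf <- signal::butter(spec$order, w,
                       type = if (spec$kind == "bandpass") "pass" else "low")
  out <- rec$data
  for (ch in seq_len(nrow(out))) out[ch, ] <- signal::filtfilt(bf, out[ch, ])
  mc_recording(out, rec$fs, rec$geometry, rec$t0)
}

#' Common-mode re-referencing
#'
#' At every sample, subtracts the mean over good channels from all
#' channels; afterwards the good-channel mean is exactly zero everywhere.
#' Removes the shared volume-conducted component, which would otherwise
#' bias connectivity estimates upward. Idempotent.
#'
#' @param rec an [mc_recording()].
#' @return A re-referenced [mc_recording()].
#' @export
subtract_common_mode <- function(rec) {
  gc <- good_channels(rec$geometry)
  if (length(gc) < 2L) stop("need at least 2 good channels")
  cm <- colMeans(rec$data[gc, , drop = FALSE])
  mc_recording(sweep(rec$data, 2L, cm), rec$fs, rec$geometry, rec$t0)
}

#' Analytic signal via the frequency domain
#'
#' Returns `x + i H(x)` where H is the Hilbert transform, computed by
#' zeroing negative frequencies of the FFT (doubling positive ones).
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude envelope
#'
#' Per-channel analytic-signal angle and magnitude of an already
#' band-limited recording (band-limiting is the caller's responsibility:
#' run [apply_filter()] first). Edge samples — the first and last 5% of the
#' segment or one period of `band_low_hz`, whichever is larger — are
#' flagged unreliable; window events with margins so edges never enter
#' statistics.
#'
#' A constant (zero-bandwidth) channel has undefined phase and is flagged
#' in `bad_phase_channels` rather than erroring.
#'
#' @param rec a band-limited [mc_recording()].
#' @param band_low_hz lower band edge used to size the edge margin
#'   (optional).
#' @return An object of class `phase_series`: `phase` (radians, (-pi, pi]),
#'   `envelope` (uV, >= 0), `reliable` (logical per sample), `fs`,
#'   `geometry`, `bad_phase_channels`.
#' @export
instantaneous_phase <- function(rec, band_low_hz = NULL) {
  d <- rec$data
  n <- ncol(d)
  phase <- matrix(NA_real_, nrow(d), n)
  env <- matrix(NA_real_, nrow(d), n)
  bad_phase <- integer()
  for (ch in seq_len(nrow(d))) {
    if (stats::sd(d[ch, ]) == 0) { bad_phase <- c(bad_phase, ch); next }
    a <- analytic_signal(d[ch, ])
    phase[ch, ] <- Arg(a)
    env[ch, ] <- Mod(a)
  }
  n_edge <- ceiling(0.05 * n)
  if (!is.null(band_low_hz))
    n_edge <- max(n_edge, ceiling(rec$fs / band_low_hz))
  reliable <- rep(TRUE, n)
  n_edge <- min(n_edge, floor((n - 1) / 2))
  if (n_edge > 0) reliable[c(seq_len(n_edge), (n - n_edge + 1):n)] <- FALSE
  structure(list(phase = phase, envelope = env, reliable = reliable,
                 fs = rec$fs, geometry = rec$geometry,
                 bad_phase_channels = bad_phase),
            class = "phase_series")
}

#' Phase-synchrony index across the array
#'
#' Circular resultant length R of the instantaneous phases over good
#' channels at one sample: `R = |mean(exp(i phi))|`. R = 1 means perfect
#' phase locking (the stationary-oscillation signature); R = 0 means
#' phases spread uniformly on the circle.
#'
#' @param ph a `phase_series` from [instantaneous_phase()].
#' @param t sample index; must lie in the reliable interior.
#' @return scalar in \[0, 1\].
#' @export
synchrony_index <- function(ph, t) {
  stopifnot(t >= 1, t <= ncol(ph$phase))
  if (!ph$reliable[t]) stop("sample ", t, " is in the unreliable edge region")
  ch <- setdiff(good_channels(ph$geometry), ph$bad_phase_channels)
  phi <- ph$phase[ch, t]
  Mod(mean(exp(1i * phi)))
}
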