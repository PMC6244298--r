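#' Wave specification for the synthetic generator
#'
#' Describes one source pattern. Three kinds:
#' \describe{
#'   \item{stationary}{a global oscillation, identical phase on every
#'     channel (`frequency` Hz, `amplitude` uV) — the theta-band regime.}
#'   \item{plane}{a spike complex sweeping the array as a plane wave:
#'     the channel at position p (um) receives the spike template delayed
#'     by `(p . direction) / speed` ms.}
#'   \item{spiral}{a rotating pattern: the channel at polar angle theta
#'     about `center` receives the template with arrival offset
#'     `theta / angular_speed` ms (sign set by `chirality`); arrival time
#'     winds by one full turn around the center.}
#' }
#'
#' Defaults place cross-array delays at tens of milliseconds: a 50 um/ms
#' plane wave needs 70 ms to cross the 7 pitches of an 8 x 8, 500 um
#' array, and a 0.1 rad/ms spiral completes a turn in ~63 ms.
#'
#' @param kind `"stationary"`, `"plane"` or `"spiral"`.
#' @param amplitude peak amplitude in uV. Default 50 for stationary
#'   (low-amplitude oscillation) and 3000 for events (mV-scale spikes).
#' @param frequency oscillation frequency in Hz (stationary; default 7).
#' @param speed propagation speed in um/ms (plane; default 50).
#' @param direction unit 2-vector (x, y) of propagation (plane; default
#'   `c(-1, 0)` = right-to-left in the array frame).
#' @param center rotation centre (x, y) in um (spiral; default slightly
#'   off the array centroid so no electrode coincides with it).
#' @param angular_speed rotation rate in rad/ms (spiral; default 0.1).
#' @param chirality `"cw"` or `"ccw"` (spiral).
#' @param template_duration_ms duration of the biphasic spike template in
#'   ms (default 40).
#' @return An object of class `wave_spec`.
#' @export
wave_spec <- function(kind = c("stationary", "plane", "spiral"),
                      amplitude = NULL, frequency = 7,
                      speed = 50, direction = c(-1, 0),
                      center = NULL, angular_speed = 0.1,
                      chirality = c("cw", "ccw"),
                      template_duration_ms = 40) {
  kind <- match.arg(kind)
  chirality <- match.arg(chirality)
  if (is.null(amplitude)) amplitude <- if (kind == "stationary") 50 else 3000
  stopifnot(amplitude > 0, template_duration_ms > 0)
  if (kind == "plane") {
    stopifnot(speed > 0, length(direction) == 2L)
    nrm <- sqrt(sum(direction^2))
    if (nrm == 0) stop("direction must be a nonzero 2-vector")
    direction <- direction / nrm
  }
  if (kind == "spiral") stopifnot(angular_speed > 0)
  structure(list(kind = kind, amplitude = amplitude, frequency = frequency,
                 speed = speed, direction = direction, center = center,
                 angular_speed = angular_speed, chirality = chirality,
                 template_duration_ms = template_duration_ms),
            class = "wave_spec")
}

#' Noise specification
#'
#' @param white_sd per-channel white-noise standard deviation, uV.
#' @param common_mode_amplitude RMS amplitude (uV) of a band-limited random
#'   process added identically to every channel — the volume-conduction
#'   surrogate. 0 disables it.
#' @param common_mode_band (low, high) Hz of the shared process
#'   (default 1–10 Hz).
#' @param seed integer seed; all draws of one generation flow from it
#'   through fixed substreams (background / events / high-gamma).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(white_sd = 0, common_mode_amplitude = 0,
                       common_mode_band = c(1, 10), seed = 1L) {
  stopifnot(white_sd >= 0, common_mode_amplitude >= 0,
            length(common_mode_band) == 2L,
            common_mode_band[1] > 0, common_mode_band[2] > common_mode_band[1])
  structure(list(white_sd = white_sd,
                 common_mode_amplitude = common_mode_amplitude,
                 common_mode_band = common_mode_band,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# run expr under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# named substreams off one base seed, kept below 2^31
substream <- function(seed, name) {
  off <- c(background = 1L, events = 2L, hg = 3L, misc = 4L)[[name]]
  as.integer((as.double(seed) * 7L + off * 1009L) %% 2147483647)
}

#' Biphasic epileptic-spike template
#'
#' Continuous-time waveform evaluated at arbitrary times so fractional
#' sample delays are exact: a half-sine depolarisation over the first 45%
#' of the duration followed by a smaller opposite-polarity rebound. Zero
#' outside `[0, duration_ms]`.
#'
#' @param t_ms times in ms (vectorised).
#' @param duration_ms template duration, ms.
#' @param amplitude peak depolarisation amplitude, uV.
#' @return numeric vector of voltages (uV).
#' @export
spike_waveform <- function(t_ms, duration_ms = 40, amplitude = 3000) {
  d1 <- 0.45 * duration_ms
  d2 <- duration_ms - d1
  out <- numeric(length(t_ms))
  i1 <- t_ms >= 0 & t_ms < d1
  out[i1] <- amplitude * sin(pi * t_ms[i1] / d1)
  i2 <- t_ms >= d1 & t_ms <= duration_ms
  out[i2] <- -0.3 * amplitude * sin(pi * (t_ms[i2] - d1) / d2)
  out
}

# band-limited shared process with the requested RMS amplitude
gen_common_mode <- function(n, fs, amplitude, band) {
  if (amplitude <= 0 || n < 16L) return(numeric(n))
  x <- stats::rnorm(n)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y / s * amplitude
}

#' Generate a stationary (globally phase-locked) oscillation
#'
#' Every channel carries `amplitude * cos(2 pi f t + phase0)` with the same
#' `phase0`, plus white noise and the shared common-mode process — the
#' regime in which amplitude maps are spatially flat, phase maps are
#' uniform, and delay matrices vanish.
#'
#' @param geometry a [grid_geometry()].
#' @param fs sampling rate, Hz.
#' @param duration length in seconds.
#' @param spec a `wave_spec` with `kind = "stationary"`.
#' @param noise a [noise_spec()].
#' @param phase0 common initial phase, radians.
#' @return An [mc_recording()].
#' @export
gen_stationary <- function(geometry, fs, duration,
                           spec = wave_spec("stationary"),
                           noise = noise_spec(), phase0 = 0) {
  stopifnot(spec$kind == "stationary")
  n <- round(duration * fs)
  if (duration * spec$frequency < 10)
    warning("fewer than 10 oscillation periods; phase estimates unreliable")
  t <- (seq_len(n) - 1) / fs
  base <- spec$amplitude * cos(2 * pi * spec$frequency * t + phase0)
  n_ch <- n_channels(geometry)
  with_seed(substream(noise$seed, "background"), {
    cm <- gen_common_mode(n, fs, noise$common_mode_amplitude,
                          noise$common_mode_band)
    data <- matrix(rep(base + cm, each = n_ch), n_ch, n, byrow = FALSE)
    if (noise$white_sd > 0)
      data <- data + matrix(stats::rnorm(n_ch * n, sd = noise$white_sd),
                            n_ch, n)
    mc_recording(data, fs, geometry)
  })
}

# lay delayed copies of the spike template into a channels x samples matrix
place_template <- function(geometry, fs, spec, arrival_ms, margin_ms, n) {
  t_ms <- (seq_len(n) - 1) / fs * 1000
  n_ch <- n_channels(geometry)
  data <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch))
    data[ch, ] <- spike_waveform(t_ms - margin_ms - arrival_ms[ch],
                                 spec$template_duration_ms, spec$amplitude)
  data
}

synth_event <- function(data, fs, geometry, noise, event_id, true_delays,
                        extra = list()) {
  n <- ncol(data)
  with_seed(substream(noise$seed, "events") + event_id, {
    if (noise$white_sd > 0)
      data <- data + matrix(stats::rnorm(length(data), sd = noise$white_sd),
                            nrow(data), n)
    cm <- gen_common_mode(n, fs, noise$common_mode_amplitude,
                          noise$common_mode_band)
    if (length(cm) == n) data <- sweep(data, 2L, -cm)
  })
  pk <- arrayInd(which.max(abs(data)), dim(data))
  ev <- spike_event(event_id = event_id, window = c(0, n / fs),
                    segment = data, context = "ictal",
                    peak_channel = pk[1L], peak_time = (pk[2L] - 1) / fs,
                    fs = fs, geometry = geometry)
  c(list(event = ev, true_delays = true_delays), extra)
}

#' Generate one plane-wave spike event
#'
#' The channel at position p receives the spike template delayed by
#' `(p . direction) / speed` ms; the returned `true_delays` field is
#' exactly that inner product over speed (ms, relative — it can be
#' negative). The window is sized so the template fully crosses the array.
#'
#' @param geometry a [grid_geometry()].
#' @param fs sampling rate, Hz.
#' @param spec a `wave_spec` with `kind = "plane"`.
#' @param noise a [noise_spec()].
#' @param window_s optional window length (s); an error if too short for
#'   the crossing (`array extent / speed + template duration + margins`).
#' @param event_id integer id, also salts the noise substream.
#' @param margin_ms quiet margin before the first arrival, ms.
#' @return list with `event` (a [spike_event()]), `true_delays`
#'   (per-channel ms) and `spec`.
#' @export
gen_plane_wave_event <- function(geometry, fs, spec = wave_spec("plane"),
                                 noise = noise_spec(), window_s = NULL,
                                 event_id = 1L, margin_ms = 10) {
  stopifnot(spec$kind == "plane")
  pos <- channel_positions(geometry)
  delays <- as.numeric(pos %*% spec$direction) / spec$speed
  arrival <- delays - min(delays)
  need_s <- (max(arrival) + spec$template_duration_ms + 2 * margin_ms) / 1000
  if (is.null(window_s)) window_s <- need_s
  if (window_s < need_s)
    stop(sprintf("window %.3f s too short; template crossing needs %.3f s",
                 window_s, need_s))
  n <- round(window_s * fs)
  data <- place_template(geometry, fs, spec, arrival, margin_ms, n)
  synth_event(data, fs, geometry, noise, event_id, delays,
              extra = list(spec = spec))
}

#' Generate one spiral-wave spike event
#'
#' A pure rotating arrival-time field: the channel at polar angle theta
#' about the centre receives the template offset by `theta / angular_speed`
#' ms (sign by chirality), so arrival time depends on angle only and winds
#' by one full turn (`+/-2 pi / angular_speed` ms) around the centre.
#'
#' @inheritParams gen_plane_wave_event
#' @param spec a `wave_spec` with `kind = "spiral"`; `center` defaults to
#'   the array centroid shifted by a third of a pitch so no electrode sits
#'   on it (a centre coincident with an electrode is an error: that
#'   channel's angle would be undefined).
#' @return list with `event`, `true_delays` (the signed angular arrival
#'   offsets, ms), `winding` (+1 ccw / -1 cw) and `spec`.
#' @export
gen_spiral_wave_event <- function(geometry, fs, spec = wave_spec("spiral"),
                                  noise = noise_spec(), window_s = NULL,
                                  event_id = 1L, margin_ms = 10) {
  stopifnot(spec$kind == "spiral")
  pos <- channel_positions(geometry)
  center <- spec$center
  if (is.null(center))
    center <- colMeans(pos) + geometry$pitch * c(1 / 3, 1 / 5)
  dx <- pos[, 1] - center[1]; dy <- pos[, 2] - center[2]
  if (any(dx == 0 & dy == 0))
    stop("spiral center coincides with an electrode; its angle is undefined")
  sgn <- if (spec$chirality == "ccw") 1 else -1
  theta <- atan2(dy, dx)
  offsets <- sgn * theta / spec$angular_speed
  arrival <- offsets - min(offsets)
  need_s <- (max(arrival) + spec$template_duration_ms + 2 * margin_ms) / 1000
  if (is.null(window_s)) window_s <- need_s
  if (window_s < need_s) stop("window too short for the spiral turn")
  n <- round(window_s * fs)
  data <- place_template(geometry, fs, spec, arrival, margin_ms, n)
  synth_event(data, fs, geometry, noise, event_id, offsets,
              extra = list(spec = spec, winding = sgn, center = center))
}

#' Event schedule for a synthetic seizure
#'
#' @param onsets event onset times, seconds.
#' @param specs list of `wave_spec` objects, one per event.
#' @param labels character vector of true labels, one per event.
#' @param hg_blocks optional named list mapping each label to a partition
#'   of the channels (list of integer vectors): the planted high-gamma
#'   correlation-block structure active during events of that label, so
#'   network states co-vary with wave types by construction.
#' @return An object of class `event_schedule`.
#' @export
event_schedule <- function(onsets, specs, labels, hg_blocks = NULL) {
  stopifnot(length(onsets) == length(specs),
            length(onsets) == length(labels))
  o <- order(onsets)
  structure(list(onsets = as.numeric(onsets)[o], specs = specs[o],
                 labels = as.character(labels)[o], hg_blocks = hg_blocks),
            class = "event_schedule")
}

# window length (s) an event needs, matching the gen_* sizing rules
event_duration_s <- function(spec, geometry, margin_ms = 10) {
  pos <- channel_positions(geometry)
  span <- switch(spec$kind,
    plane = diff(range(as.numeric(pos %*% spec$direction) / spec$speed)),
    spiral = 2 * pi / spec$angular_speed,
    0)
  (span + spec$template_duration_ms + 2 * margin_ms) / 1000
}

#' Generate a full synthetic seizure recording with ground truth
#'
#' Background (white noise + shared common mode) plus scheduled spike
#' events. During each event window the channels are additionally driven by
#' high-gamma band noise whose cross-channel correlation follows the
#' schedule's planted block structure for that event's label, so functional
#' network states co-vary with propagation types by construction.
#'
#' @param geometry a [grid_geometry()].
#' @param fs sampling rate, Hz.
#' @param duration total length, seconds.
#' @param schedule an [event_schedule()]; overlapping events are an error.
#' @param noise a [noise_spec()].
#' @param hg_amplitude RMS amplitude (uV) of the planted high-gamma drive
#'   (0 disables it).
#' @param hg_band (low, high) Hz of the drive, default 80–120.
#' @param hg_rho within-block correlation of the drive before filtering.
#' @return list: `recording` (an [mc_recording()]), `truth` (data.frame
#'   event_id / onset_s / label), `hg_blocks` (the planted structure).
#' @export
gen_seizure <- function(geometry, fs, duration, schedule,
                        noise = noise_spec(), hg_amplitude = 0,
                        hg_band = c(80, 120), hg_rho = 0.8) {
  n <- round(duration * fs)
  n_ch <- n_channels(geometry)
  durs <- vapply(schedule$specs, event_duration_s, 0, geometry = geometry)
  ends <- schedule$onsets + durs
  if (length(schedule$onsets) > 1 &&
      any(schedule$onsets[-1] < ends[-length(ends)]))
    stop("overlapping events in schedule")
  if (length(ends) && max(ends) > duration)
    stop("schedule extends past the recording duration")

  data <- with_seed(substream(noise$seed, "background"), {
    cm <- gen_common_mode(n, fs, noise$common_mode_amplitude,
                          noise$common_mode_band)
    d <- matrix(if (noise$white_sd > 0)
      stats::rnorm(n_ch * n, sd = noise$white_sd) else 0, n_ch, n)
    if (length(cm) == n) d <- sweep(d, 2L, -cm)
    d
  })

  for (i in seq_along(schedule$onsets)) {
    spec <- schedule$specs[[i]]
    ev <- switch(spec$kind,
      plane = gen_plane_wave_event(geometry, fs, spec, noise_spec(seed = 1),
                                   event_id = i),
      spiral = gen_spiral_wave_event(geometry, fs, spec, noise_spec(seed = 1),
                                     event_id = i),
      stop("schedule events must be plane or spiral waves"))
    seg <- ev$event$segment
    i0 <- round(schedule$onsets[i] * fs) + 1L
    idx <- i0:(i0 + ncol(seg) - 1L)
    data[, idx] <- data[, idx] + seg
    if (hg_amplitude > 0 && !is.null(schedule$hg_blocks)) {
      blocks <- schedule$hg_blocks[[schedule$labels[i]]]
      if (is.null(blocks)) stop("no hg block structure for label ",
                                schedule$labels[i])
      hgd <- with_seed(substream(noise$seed, "hg") + i,
                       gen_hg_drive(n_ch, length(idx), fs, blocks,
                                    hg_amplitude, hg_band, hg_rho))
      data[, idx] <- data[, idx] + hgd
    }
  }

  list(recording = mc_recording(data, fs, geometry),
       truth = data.frame(event_id = seq_along(schedule$onsets),
                          onset_s = schedule$onsets,
                          label = schedule$labels),
       hg_blocks = schedule$hg_blocks)
}

# high-gamma drive with planted block correlation: channels in one block
# share sqrt(rho) of a common source; band-passed then scaled to target RMS
gen_hg_drive <- function(n_ch, n, fs, blocks, amplitude, band, rho) {
  if (fs / 2 <= band[2]) stop("fs too low for the high-gamma band")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  out <- matrix(0, n_ch, n)
  for (b in blocks) {
    shared <- stats::rnorm(n)
    for (ch in b)
      out[ch, ] <- sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n)
  }
  for (ch in seq_len(n_ch)) {
    y <- signal::filtfilt(bf, out[ch, ])
    s <- stats::sd(y)
    out[ch, ] <- if (s > 0) y / s * amplitude else 0
  }
  out
}
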