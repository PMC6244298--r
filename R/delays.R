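# Cross-correlation delay estimation.
#
# Normalised (Pearson) cross-correlation at every integer-sample lag in
# [-max_lag, max_lag]: at lag L the overlapping segments a[1:(n-L)] and
# b[(1+L):n] (L >= 0; mirrored for L < 0) are correlated with per-overlap
# mean/variance normalisation, so amplitude differences between channels
# cannot bias the lag choice. The cross term for all lags comes from one
# FFT product; the per-overlap means and variances from prefix sums.

# r at all lags -L..L; returns list(lags, r); degenerate overlaps get -Inf
xcorr_all_lags <- function(a, b, max_lag) {
  n <- length(a)
  stopifnot(length(b) == n, max_lag >= 0, max_lag <= n - 2L)
  N <- stats::nextn(n + max_lag + 1L)
  A <- stats::fft(c(a, numeric(N - n)))
  B <- stats::fft(c(b, numeric(N - n)))
  cc <- Re(stats::fft(Conj(A) * B, inverse = TRUE)) / N
  lags <- (-max_lag):max_lag
  S_ab <- cc[ifelse(lags >= 0, lags + 1L, N + lags + 1L)]
  ca <- cumsum(a);  cb <- cumsum(b)
  ca2 <- cumsum(a * a); cb2 <- cumsum(b * b)
  m <- n - abs(lags)
  L <- pmax(lags, 0L); Lm <- pmax(-lags, 0L)   # b offset / a offset
  S_a <- ca[n - L] - c(0, ca)[Lm + 1L]
  S_aa <- ca2[n - L] - c(0, ca2)[Lm + 1L]
  S_b <- cb[n - Lm] - c(0, cb)[L + 1L]
  S_bb <- cb2[n - Lm] - c(0, cb2)[L + 1L]
  va <- S_aa - S_a^2 / m
  vb <- S_bb - S_b^2 / m
  eps <- 1e-12 * max(va, vb, 1)
  r <- ifelse(va > eps & vb > eps,
              (S_ab - S_a * S_b / m) / sqrt(pmax(va, eps) * pmax(vb, eps)),
              -Inf)
  list(lags = lags, r = r)
}

# deterministic argmax: ties broken toward smallest |lag|, then negative
best_lag <- function(lags, r) {
  ord <- order(abs(lags), lags)
  i <- ord[which.max(r[ord])]
  c(lag = lags[i], r = r[i])
}

#' Time delay between two signals by cross-correlation
#'
#' Evaluates the normalised cross-correlation at all integer-sample lags in
#' `[-max_lag, max_lag]` and returns the lag maximising it; a positive lag
#' means `b` trails (arrives later than) `a`. Ties are broken toward the
#' smallest `|lag|`, then toward the negative lag.
#'
#' @param a,b equal-length numeric signals.
#' @param max_lag_ms maximum lag searched, ms; must be under half the
#'   window length.
#' @param fs sampling rate, Hz.
#' @return list: `lag_ms`, `lag_samples`, `peak_cor`.
#' @export
xcorr_delay <- function(a, b, max_lag_ms, fs) {
  n <- length(a)
  if (length(b) != n) stop("signals must have equal length")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("zero-variance input: correlation undefined")
  ml <- round(max_lag_ms / 1000 * fs)
  if (ml >= n / 2) stop("max_lag must be under half the window length")
  res <- xcorr_all_lags(a, b, ml)
  bst <- best_lag(res$lags, res$r)
  list(lag_ms = unname(bst["lag"]) / fs * 1000,
       lag_samples = as.integer(bst["lag"]),
       peak_cor = unname(bst["r"]))
}

# shared sizing rule: half the event window
default_max_lag_ms <- function(ev) (ncol(ev$segment) / ev$fs * 1000) / 2 - 1

#' Pairwise delay matrix of a spike event
#'
#' `d[i, j]` is the cross-correlation lag of channel j relative to channel
#' i, in ms (positive: j arrives later). Each unordered good pair is
#' computed once and mirrored, so the matrix is exactly antisymmetric with
#' a zero diagonal. Bad channels stay `NA`. `quality[i, j]` holds the peak
#' correlation of each pair.
#'
#' @param ev a [spike_event()] (segment should be low-pass filtered).
#' @param max_lag_ms lag search bound, ms; default half the event window
#'   (50 ms for ictal 100 ms windows, 250 ms for inter-ictal 500 ms ones).
#' @return An object of class `delay_matrix`: `d`, `quality`, `fs`,
#'   `geometry`, `event_id`, `max_lag_ms`.
#' @export
delay_matrix <- function(ev, max_lag_ms = NULL) {
  if (is.null(max_lag_ms)) max_lag_ms <- default_max_lag_ms(ev)
  seg <- ev$segment
  n <- ncol(seg)
  ml <- round(max_lag_ms / 1000 * fs_of(ev))
  ml <- min(ml, n - 2L)
  gc <- good_channels(ev$geometry)
  for (ch in gc) if (stats::var(seg[ch, ]) == 0)
    stop("zero-variance channel ", ch, ": correlation undefined")
  n_ch <- nrow(seg)
  d <- matrix(NA_real_, n_ch, n_ch)
  q <- matrix(NA_real_, n_ch, n_ch)
  d[cbind(gc, gc)] <- 0; q[cbind(gc, gc)] <- 1
  # one forward FFT per channel, one inverse per pair
  N <- stats::nextn(n + ml + 1L)
  Fs <- lapply(gc, function(ch) stats::fft(c(seg[ch, ], numeric(N - n))))
  lags <- (-ml):ml
  pre <- lapply(gc, function(ch) {
    x <- seg[ch, ]
    list(c1 = cumsum(x), c2 = cumsum(x * x))
  })
  names(pre) <- names(Fs) <- as.character(gc)
  m <- n - abs(lags)
  Lp <- pmax(lags, 0L); Lm <- pmax(-lags, 0L)
  for (ii in seq_along(gc)) for (jj in seq_along(gc)) {
    if (jj <= ii) next
    i <- gc[ii]; j <- gc[jj]
    cc <- Re(stats::fft(Conj(Fs[[ii]]) * Fs[[jj]], inverse = TRUE)) / N
    S_ab <- cc[ifelse(lags >= 0, lags + 1L, N + lags + 1L)]
    pa <- pre[[ii]]; pb <- pre[[jj]]
    S_a <- pa$c1[n - Lp] - c(0, pa$c1)[Lm + 1L]
    S_aa <- pa$c2[n - Lp] - c(0, pa$c2)[Lm + 1L]
    S_b <- pb$c1[n - Lm] - c(0, pb$c1)[Lp + 1L]
    S_bb <- pb$c2[n - Lm] - c(0, pb$c2)[Lp + 1L]
    va <- S_aa - S_a^2 / m; vb <- S_bb - S_b^2 / m
    eps <- 1e-12 * max(va, vb, 1)
    r <- ifelse(va > eps & vb > eps,
                (S_ab - S_a * S_b / m) / sqrt(pmax(va, eps) * pmax(vb, eps)),
                -Inf)
    bst <- best_lag(lags, r)
    lag_ms <- bst["lag"] / fs_of(ev) * 1000
    d[i, j] <- lag_ms;  d[j, i] <- -lag_ms
    q[i, j] <- q[j, i] <- bst["r"]
  }
  structure(list(d = d, quality = q, fs = fs_of(ev),
                 geometry = ev$geometry, event_id = ev$event_id,
                 max_lag_ms = max_lag_ms),
            class = "delay_matrix")
}

fs_of <- function(ev) ev$fs

#' Peak-time delay matrix
#'
#' The simpler alternative estimator: `d[i, j] = peak_time(j) -
#' peak_time(i)` from each channel's global absolute peak. Exactly
#' antisymmetric by construction; agrees with [delay_matrix()] on clean
#' propagating events.
#'
#' @param ev a [spike_event()].
#' @return A `delay_matrix` object (with `quality = NA`).
#' @export
peak_time_delay <- function(ev) {
  seg <- ev$segment
  gc <- good_channels(ev$geometry)
  for (ch in gc) if (stats::var(seg[ch, ]) == 0)
    stop("flat channel ", ch, ": peak undefined")
  pk <- vapply(gc, function(ch) which.max(abs(seg[ch, ])), 0L)
  pk_ms <- (pk - 1) / ev$fs * 1000
  n_ch <- nrow(seg)
  d <- matrix(NA_real_, n_ch, n_ch)
  d[gc, gc] <- outer(pk_ms, pk_ms, function(a, b) b - a)
  structure(list(d = d, quality = matrix(NA_real_, n_ch, n_ch),
                 fs = ev$fs, geometry = ev$geometry,
                 event_id = ev$event_id, max_lag_ms = NA_real_),
            class = "delay_matrix")
}

#' Delay map relative to a reference channel
#'
#' Arranges row `reference` of the delay matrix on the electrode grid: each
#' cell is that channel's lag (ms) behind the reference, zero at the
#' reference itself. The spatial gradient of the map points along the
#' propagation direction; a spiral shows a full angular wrap instead.
#'
#' @param dm a [delay_matrix()].
#' @param reference reference channel (default: first good channel).
#' @return A `grid_map` of kind `"delay"`.
#' @export
delay_map <- function(dm, reference = NULL) {
  gc <- good_channels(dm$geometry)
  if (is.null(reference)) reference <- gc[1L]
  if (!(reference %in% gc)) stop("reference channel ", reference, " is bad")
  map_to_grid(dm$d[reference, ], dm$geometry, kind = "delay",
              id = dm$event_id)
}

#' Delay features for propagation-pattern clustering
#'
#' One row per event: the delays of every good channel relative to the
#' reference channel (the first column of the full delay matrix restricted
#' to good channels). The full `n x n` matrix is antisymmetric and thus
#' redundant; this single column already separates distinct propagation
#' types while avoiding the curse of dimensionality.
#'
#' @param events list of [spike_event()]s.
#' @param reference reference channel (default first good channel).
#' @param max_lag_ms lag bound per event; default half each event window.
#' @return numeric matrix `[n_events x n_good_channels]` of delays in ms;
#'   the reference column is identically zero.
#' @export
delay_features <- function(events, reference = NULL, max_lag_ms = NULL) {
  stopifnot(length(events) >= 1L)
  geometry <- events[[1L]]$geometry
  gc <- good_channels(geometry)
  if (is.null(reference)) reference <- gc[1L]
  if (!(reference %in% gc)) stop("reference channel ", reference, " is bad")
  feat <- t(vapply(events, function(ev) {
    ml <- if (is.null(max_lag_ms)) default_max_lag_ms(ev) else max_lag_ms
    a <- ev$segment[reference, ]
    vapply(gc, function(j) {
      if (j == reference) return(0)
      xcorr_delay(a, ev$segment[j, ], ml, ev$fs)$lag_ms
    }, 0)
  }, numeric(length(gc))))
  colnames(feat) <- paste0("ch", gc)
  rownames(feat) <- vapply(events, function(e) format(e$event_id), "")
  feat
}
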