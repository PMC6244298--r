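geom <- grid_geometry()
fs <- 1000

test_that("xcorr_delay recovers identity and pure shifts", {
  set.seed(2)
  a <- rnorm(400)
  r <- xcorr_delay(a, a, 100, fs)
  expect_identical(r$lag_samples, 0L)
  expect_equal(r$peak_cor, 1)

  x <- rnorm(500)
  a <- x[101:400]; b <- x[91:390]              # b = a shifted by +10 samples
  r <- xcorr_delay(a, b, 50, fs)
  expect_identical(r$lag_samples, 10L)
  expect_equal(r$lag_ms, 10)

  expect_error(xcorr_delay(rep(1, 100), rnorm(100), 10, fs), "zero-variance")
  expect_error(xcorr_delay(rnorm(100), rnorm(100), 60, fs), "half")
})

test_that("xcorr_delay matches the exhaustive lag-scan oracle on random pairs", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(60:300, 1)
    ml <- sample(5:floor(n / 2 - 1), 1)
    a <- rnorm(n)
    b <- if (i %% 3 == 0) rnorm(n) else
      stats::filter(c(rnorm(20), a), rep(1 / 3, 3), sides = 1)[sample(5:15, 1) + seq_len(n)]
    b[is.na(b)] <- 0
    if (sd(b) == 0) next
    got <- xcorr_delay(a, b, ml / fs * 1000, fs)$lag_samples
    expect_identical(got, as.integer(oracle_xcorr_lag(a, b, ml)))
  }
})

test_that("delay matrices on plane waves match the ground-truth field", {
  sp <- wave_spec("plane", speed = 50, direction = c(-1, 0))
  ev <- gen_plane_wave_event(geom, fs, sp, noise_spec(white_sd = 300, seed = 4),
                             window_s = 0.2)
  dm <- delay_matrix(ev$event)
  truth <- outer(ev$true_delays, ev$true_delays, function(a, b) b - a)
  expect_gte(mean(abs(dm$d - truth) <= 1 + 1e-9, na.rm = TRUE), 0.95)
  # antisymmetry holds exactly, zero diagonal
  expect_identical(dm$d, -t(dm$d))
  expect_true(all(diag(dm$d) == 0))
  expect_true(all(abs(dm$d) <= dm$max_lag_ms + 1e-9, na.rm = TRUE))

  # peak-time estimator agrees within 2 samples on >= 90% of pairs once
  # the segment is low-pass filtered as the pipeline prescribes
  evf <- ev$event
  evf$segment <- apply_filter(mc_recording(evf$segment, fs, geom),
                              "epileptic_lowpass")$data
  dmf <- delay_matrix(evf)
  pt <- peak_time_delay(evf)
  expect_gte(mean(abs(pt$d - dmf$d) <= 2 + 1e-9, na.rm = TRUE), 0.9)
  expect_identical(pt$d, -t(pt$d))
})

test_that("identical channels give an all-zero delay matrix", {
  seg <- matrix(rep(spike_waveform(seq(0, 99.9, 0.1) - 30), each = 64),
                64, 1000, byrow = FALSE)
  ev <- spike_event(1, c(0, 1), seg, "ictal", 1, 0.3, fs, geom)
  dm <- delay_matrix(ev, max_lag_ms = 100)
  expect_true(all(dm$d == 0))
  pt <- peak_time_delay(ev)
  expect_true(all(pt$d == 0))
})

test_that("delay maps read out propagation geometry", {
  sp <- wave_spec("plane", speed = 50, direction = c(-1, 0))
  ev <- gen_plane_wave_event(geom, fs, sp, noise_spec(white_sd = 100, seed = 8),
                             window_s = 0.2)
  m <- unclass(delay_map(delay_matrix(ev$event), reference = 1))
  expect_equal(m[1, 1], 0)                     # reference cell
  # right-to-left wave: arrivals get later leftward, map falls along rows
  expect_true(all(apply(m, 1, diff) <= 0))

  # spiral: sorted-by-angle ring values rise monotonically once unwrapped
  evs <- gen_spiral_wave_event(geom, fs, wave_spec("spiral", chirality = "ccw"),
                               noise_spec(white_sd = 100, seed = 9),
                               window_s = 0.2)
  ms <- unclass(delay_map(delay_matrix(evs$event), reference = 1))
  pos <- channel_positions(geom)
  v <- grid_to_channels(delay_map(delay_matrix(evs$event), reference = 1))
  th <- atan2(pos[, 2] - evs$center[2], pos[, 1] - evs$center[1])
  o <- order(th)
  inc <- diff(c(v[o], v[o][1]))                # closed loop around the centre
  expect_gte(mean(inc >= -2), 0.95)            # monotone modulo one wrap
  expect_equal(sum(inc < -10), 1L)             # exactly one full-turn jump

  zero <- delay_matrix(spike_event(1, c(0, 1),
    matrix(rep(sin(1:300), each = 16), 16, 300, byrow = FALSE), "ictal",
    1, 0, fs, grid_geometry(4, 4)), max_lag_ms = 50)
  expect_true(all(unclass(delay_map(zero)) == 0))

  gb <- grid_geometry(bad_channels = 1L)
  evb <- spike_event(1, c(0, 1), ev$event$segment, "ictal", 2, 0, fs, gb)
  expect_error(delay_map(delay_matrix(evb), reference = 1), "bad")
})

test_that("delay features are antisymmetric in direction and low-rank", {
  # mirrored directions give negated features (noiseless, fine sampling)
  fs10 <- 10000
  e1 <- gen_plane_wave_event(geom, fs10, wave_spec("plane", direction = c(-1, 0)),
                             noise_spec(), window_s = 0.2)
  e2 <- gen_plane_wave_event(geom, fs10, wave_spec("plane", direction = c(1, 0)),
                             noise_spec(), window_s = 0.2)
  f <- delay_features(list(e1$event, e2$event))
  expect_equal(f[1, ], -f[2, ], tolerance = 1e-9)

  # identical events give identical rows
  f2 <- delay_features(list(e1$event, e1$event))
  expect_identical(f2[1, ], f2[2, ])

  # noiseless plane-wave features over many directions: numerical rank <= 3
  set.seed(23)
  evs <- lapply(runif(10, 0, 2 * pi), function(a)
    gen_plane_wave_event(geom, fs10,
      wave_spec("plane", direction = c(cos(a), sin(a))),
      noise_spec(), window_s = 0.25)$event)
  fm <- delay_features(evs)
  sv <- svd(fm)$d
  expect_true(all(sv[-(1:3)] < 0.02 * sv[1]))
})

test_that("delay-map gradients recover inverse speed within 10% at high SNR", {
  sp <- wave_spec("plane", speed = 50, direction = c(-1, 0), amplitude = 3000)
  ev <- gen_plane_wave_event(geom, fs, sp, noise_spec(white_sd = 300, seed = 12),
                             window_s = 0.2)
  f <- delay_features(list(ev$event))[1, ]
  pos <- channel_positions(geom)
  g <- coef(lm(f ~ pos))[-1]                   # ms per um
  expect_equal(sqrt(sum(g^2)), 1 / 50, tolerance = 0.1)
  # gradient points along the true propagation direction
  expect_lt(g[1], 0)
  expect_lt(abs(g[2]) / abs(g[1]), 0.1)
})
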