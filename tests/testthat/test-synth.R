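geom <- grid_geometry()

test_that("noiseless stationary generation is identical across channels", {
  rec <- gen_stationary(geom, 1000, 2, wave_spec("stationary"), noise_spec())
  expect_true(all(rec$data == rec$data[rep(1, 64), ]))
  # spectral peak at the oscillation frequency (periodogram oracle)
  pg <- spec.pgram(ts(rec$data[1, ], frequency = 1000), plot = FALSE,
                   taper = 0, detrend = TRUE)
  expect_equal(pg$freq[which.max(pg$spec)], 7, tolerance = 0.05)
})

test_that("stationary generation warns below 10 periods and is seed-reproducible", {
  expect_warning(gen_stationary(geom, 1000, 1, wave_spec("stationary", frequency = 5),
                                noise_spec(white_sd = 1)), "10")
  n1 <- gen_stationary(geom, 500, 2, noise = noise_spec(white_sd = 5, seed = 7))
  n2 <- gen_stationary(geom, 500, 2, noise = noise_spec(white_sd = 5, seed = 7))
  expect_identical(n1$data, n2$data)
})

test_that("plane-wave true delays follow the geometry", {
  sp <- wave_spec("plane", speed = 50, direction = c(-1, 0))
  ev <- gen_plane_wave_event(geom, 1000, sp, noise_spec())
  d <- matrix(ev$true_delays, 8, 8, byrow = TRUE)
  # adjacent columns differ by pitch / speed = 500 / 50 = 10 ms
  expect_equal(unique(as.vector(diff(t(d)))), -10)
  # 8 columns span 7 pitches: 70 ms range (brute force over positions)
  expect_equal(diff(range(ev$true_delays)), 70)
  pos <- channel_positions(geom)
  expect_equal(ev$true_delays,
               as.numeric(pos %*% c(-1, 0)) / 50)
  # mirrored directions give negated delay fields
  ev2 <- gen_plane_wave_event(geom, 1000, wave_spec("plane", direction = c(1, 0)),
                              noise_spec())
  expect_equal(ev2$true_delays, -ev$true_delays)
})

test_that("plane-wave delay fields over many directions span <= 2 dimensions", {
  set.seed(5)
  fields <- sapply(runif(12, 0, 2 * pi), function(a) {
    gen_plane_wave_event(geom, 1000,
      wave_spec("plane", direction = c(cos(a), sin(a))),
      noise_spec())$true_delays
  })
  sv <- svd(sweep(fields, 1L, rowMeans(fields)))$d
  expect_lt(sv[3] / sv[1], 1e-10)
})

test_that("plane-wave window shorter than the crossing errors", {
  expect_error(gen_plane_wave_event(geom, 1000, wave_spec("plane"),
                                    noise_spec(), window_s = 0.05),
               "too short")
})

test_that("spiral arrival fields rotate with unit winding", {
  sp <- wave_spec("spiral", angular_speed = 0.1, chirality = "ccw")
  ev <- gen_spiral_wave_event(geom, 1000, sp, noise_spec())
  # chirality flip negates the angular offsets
  ev_cw <- gen_spiral_wave_event(geom, 1000,
    wave_spec("spiral", angular_speed = 0.1, chirality = "cw"), noise_spec())
  expect_equal(ev_cw$true_delays, -ev$true_delays)

  # brute-force loop sum: wrapped arrival-phase increments around the
  # centre total one signed full turn
  pos <- channel_positions(geom)
  theta <- atan2(pos[, 2] - ev$center[2], pos[, 1] - ev$center[1])
  ring <- order(theta)
  phi <- ev$true_delays[ring] * sp$angular_speed   # back to radians
  inc <- diff(c(phi, phi[1]))
  inc <- (inc + pi) %% (2 * pi) - pi
  expect_equal(sum(inc) / (2 * pi), 1)
  expect_equal(ev$winding, 1)

  # equal angle, different radius -> identical offsets (pure rotation)
  ev0 <- gen_spiral_wave_event(geom, 1000,
    wave_spec("spiral", center = c(-500, 0)), noise_spec())
  expect_equal(ev0$true_delays[1], ev0$true_delays[2])  # row 1, cols 1-2

  expect_error(gen_spiral_wave_event(geom, 1000,
    wave_spec("spiral", center = c(500, 500)), noise_spec()),
    "coincides")
})

test_that("seizure generation respects the schedule and plants hg structure", {
  fs <- 1000
  sched0 <- event_schedule(numeric(0), list(), character(0))
  bg <- gen_seizure(geom, fs, 2, sched0, noise_spec())
  expect_true(all(bg$recording$data == 0))   # no events, no noise

  blocks <- list(A = list(1:32, 33:64))
  on <- c(0.5, 1.2)
  sched <- event_schedule(on, list(wave_spec("plane"), wave_spec("plane")),
                          c("A", "A"), hg_blocks = blocks)
  sez <- gen_seizure(geom, fs, 2, sched, noise_spec(seed = 3),
                     hg_amplitude = 30)
  expect_equal(sez$truth$onset_s, on)
  # within-block high-gamma correlation beats across-block (sample oracle)
  i0 <- round(0.5 * fs) + 1
  seg <- sez$recording$data[, i0:(i0 + 120)]
  hg <- apply_filter(mc_recording(seg, fs, geom), "high_gamma")$data
  cc <- cor(t(hg))
  within <- c(cc[1:32, 1:32][upper.tri(diag(32))],
              cc[33:64, 33:64][upper.tri(diag(32))])
  across <- cc[1:32, 33:64]
  expect_gt(mean(within), mean(across))

  expect_error(gen_seizure(geom, fs, 2,
    event_schedule(c(0.5, 0.55), list(wave_spec("plane"), wave_spec("plane")),
                   c("A", "A"), blocks), noise_spec(), hg_amplitude = 30),
    "overlapping")
})

test_that("generation is bit-reproducible under a fixed seed", {
  blocks <- list(A = list(1:32, 33:64))
  sched <- event_schedule(0.3, list(wave_spec("spiral")), "A", blocks)
  a <- gen_seizure(geom, 1000, 1, sched, noise_spec(white_sd = 20, seed = 11),
                   hg_amplitude = 25)
  b <- gen_seizure(geom, 1000, 1, sched, noise_spec(white_sd = 20, seed = 11),
                   hg_amplitude = 25)
  expect_identical(a$recording$data, b$recording$data)
})
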