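test_that("anechoic RIR is a pure scaled, delayed impulse per microphone", {
  room <- room_spec()
  geo <- array_geometry()
  r <- simulate_rir(room, 2, 30, geo, anechoic = TRUE)
  for (l in 1:4) {
    nz <- which(r$h[, l] != 0)
    expect_length(nz, 1)
  }
  # at 0 degrees all four direct-path delays coincide
  r0 <- simulate_rir(room, 2, 0, geo, anechoic = TRUE)
  peaks <- apply(r0$h, 2, which.max)
  expect_true(all(abs(peaks - peaks[1]) <= 1))
})

test_that("direct-path inter-mic delays match the far-field formula", {
  room <- room_spec()
  geo <- array_geometry()
  for (ang in c(-40, 25, 50)) {
    r <- simulate_rir(room, 2, ang, geo, anechoic = TRUE)
    peaks <- apply(r$h, 2, which.max)
    expected <- -das_delays(geo, ang) * r$rate   # closer mics arrive earlier
    expect_true(all(abs((peaks - peaks[1]) - expected) <= 1),
                info = paste("angle", ang))
  }
})

test_that("simulated room reproduces the nominal RT60", {
  r <- default_condition()$rir
  t60 <- estimate_rt60(r)
  expect_lt(abs(t60 - 0.5), 0.1)
})

test_that("RT60 estimator recovers a known exponential decay and flags impulses", {
  set.seed(4)
  fs <- 16000
  for (t60 in c(0.3, 0.6)) {
    t <- (0:(fs - 1)) / fs
    x <- stats::rnorm(fs) * 10^(-3 * t / t60)
    expect_lt(abs(estimate_rt60(x, fs) - t60) / t60, 0.05)
  }
  flagged <- estimate_rt60(c(1, numeric(50)), fs)
  expect_true(is.na(flagged))
  expect_true(attr(flagged, "flagged"))
  expect_error(estimate_rt60(numeric(0)), "empty")
})

test_that("RIR grid is the exact 3 x 11 Cartesian product", {
  grid <- build_rir_grid(room_spec(), array_geometry(), anechoic = TRUE)
  expect_length(grid, 33)
  combos <- data.frame(d = vapply(grid, `[[`, 0, "distance"),
                       a = vapply(grid, `[[`, 0, "angle"))
  expect_equal(nrow(unique(combos)), 33)
  expect_setequal(unique(combos$d), c(1, 2, 3))
  expect_setequal(unique(combos$a), seq(-50, 50, by = 10))
  small <- build_rir_grid(room_spec(), array_geometry(), distances = 2,
                          angles = 0, anechoic = TRUE)
  expect_length(small, 1)
})

test_that("mix_at_snr hits the requested SNR exactly", {
  set.seed(7)
  tg <- stats::rnorm(8000)
  nz <- stats::rnorm(12000)
  for (snr in c(-5, 0, 10, 23)) {
    m <- mix_at_snr(tg, nz, snr)
    got <- 10 * log10(sum(tg^2) / sum(m$noise_scaled^2))
    expect_lt(abs(got - snr), 1e-9)
  }
  # 0 dB with equal-energy inputs means unit gain
  nz2 <- nz[1:8000] * sqrt(sum(tg^2) / sum(nz[1:8000]^2))
  expect_equal(mix_at_snr(tg, nz2, 0)$gain, 1, tolerance = 1e-12)
  # Inf sentinel disables the noise
  expect_identical(mix_at_snr(tg, nz, Inf)$mix, tg)
  expect_error(mix_at_snr(tg, numeric(100), 10), "zero-energy")
})

test_that("robot/environment mixture honours the energy ratio", {
  set.seed(8)
  r <- stats::rnorm(4000)
  e <- stats::rnorm(4000)
  for (ratio in c(-5, 0, 5)) {
    mx <- make_noise_mixture(r, e, ratio)
    env_part <- mx - r
    got <- 10 * log10(sum(r^2) / sum(env_part^2))
    expect_lt(abs(got - ratio), 1e-9)
  }
  expect_identical(make_noise_mixture(r, NULL, 0), r)
  expect_identical(make_noise_mixture(r, e, Inf), r)
  expect_error(make_noise_mixture(numeric(0), e), "empty")
})

test_that("augmentation draws stay in range and are logged faithfully", {
  subs <- test_subjects()[1:2, ]
  p <- test_profile()
  corpus <- generate_corpus(subs, p, seed = 9)
  grid <- build_rir_grid(room_spec(), array_geometry(), distances = 2,
                         angles = c(0, 20), anechoic = TRUE)
  bank <- test_noise_bank()
  captured <- list()
  sim <- simulate_training_corpus(
    corpus, p, grid, bank, seed = 10,
    handler = function(cap, row) cap
  )
  expect_equal(nrow(sim$provenance), 12)
  expect_true(all(sim$provenance$snr_db >= 5 & sim$provenance$snr_db <= 15))
  expect_true(all(sim$provenance$ratio_db >= -5 & sim$provenance$ratio_db <= 5))
  # energy bookkeeping: the logged SNR is recoverable from the stored
  # clean reference and noise component
  for (i in c(1, 5, 12)) {
    cap <- sim$results[[i]]
    got <- 10 * log10(sum(cap$reference^2) / sum(cap$noise_component^2))
    expect_lt(abs(got - sim$provenance$snr_db[i]), 1e-6)
  }
})

test_that("uniform ratio draws centre on 0 dB (Monte Carlo)", {
  set.seed(12)
  draws <- stats::runif(600, -5, 5)
  r <- stats::rnorm(200)
  e <- stats::rnorm(200)
  realized <- vapply(draws, function(rd) {
    mx <- make_noise_mixture(r, e, rd)
    10 * log10(sum(r^2) / sum((mx - r)^2))
  }, 0)
  se <- sqrt(10^2 / 12) / sqrt(600)
  expect_lt(abs(mean(realized) - 0), 3 * se)
})

test_that("triangular DOA track has the stated limits, rate and period", {
  fs <- 16000
  track <- doa_triangle(round(12.7 * fs), fs, 0.42, 50)
  expect_lt(abs(max(track) - 50), 0.5)
  expect_lt(abs(min(track) + 50), 0.5)
  slope <- (track[2000] - track[1000]) / (1000 / fs)   # deg/s on the ramp
  expect_equal(slope * pi / 180, 0.42, tolerance = 1e-3)
  # one full back-and-forth sweep fits into a mean-length utterance:
  # period = 4 * 50 deg / (0.42 rad/s in deg/s)
  period <- 4 * 50 / (0.42 * 180 / pi)
  expect_lt(period, 12.7)
  peak_idx <- which.max(track)
  trough_idx <- which(track == min(track))[1]
  expect_lt(max(peak_idx, trough_idx) / fs, 12.7)
})

test_that("dynamic capture degenerates to the static one at zero limits", {
  p <- test_profile()
  v <- synthesize_vocalization(list(subject_id = "D", mmrc_class = 1L),
                               "ae", 1, p, seed = 77)
  room <- room_spec()
  geo <- array_geometry()
  dyn <- simulate_dynamic_capture(v, room, geo, distance = 2,
                                  limit_deg = 0, anechoic = TRUE)
  expect_true(all(dyn$doa_track == 0))
  cond <- list(distance = 2, angle = 0,
               rir = simulate_rir(room, 2, 0, geo, anechoic = TRUE))
  stat <- dysvox:::apply_rir(v$samples, cond$rir)[seq_along(v$samples), ]
  expect_equal(dyn$channels, stat, tolerance = 1e-10)
})

test_that("convolution with a unit impulse is the identity", {
  x <- stats::rnorm(500)
  rir <- structure(list(h = cbind(c(1, numeric(9)), c(1, numeric(9))),
                        rate = 16000), class = "dysvox_rir")
  out <- dysvox:::apply_rir(x, rir)
  expect_equal(out[seq_along(x), 1], x, tolerance = 1e-12)
  expect_equal(out[seq_along(x), 2], x, tolerance = 1e-12)
})

test_that("noise bank produces the six environmental surrogates", {
  bank <- test_noise_bank()
  expect_named(bank$env, c("street", "station", "car", "babble",
                           "restaurant", "airport"))
  expect_equal(ncol(bank$robot_mc), 4)
  # channel realizations are mutually distinct
  expect_lt(abs(stats::cor(bank$robot_mc[, 1], bank$robot_mc[, 2])), 0.2)
})
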