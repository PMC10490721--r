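test_that("STFT bin count and round-trip reconstruction", {
  set.seed(1)
  x <- stats::rnorm(16000)
  fr <- stft(x, 16000, frame_length = 512, overlap = 0.5, dft_size = 512)
  expect_equal(fr$num_freq_bins, 257)
  y <- istft(fr)
  interior <- 600:15400
  expect_lt(max(abs(y[interior] - x[interior])) / stats::sd(x), 1e-6)
  # a pure tone concentrates its energy in the matching bin
  t <- (0:15999) / 16000
  tone <- sin(2 * pi * 1000 * t)
  pw <- rowMeans(abs(stft(tone, 16000)$X[, , 1])^2)
  expect_equal(which.max(pw) - 1L, 1000 * 512 / 16000)
  expect_error(stft(numeric(0)), "empty")
  expect_error(stft(x, overlap = 1), "overlap")
})

test_that("geometric delays follow d/v * sin(phi)", {
  geo <- array_geometry()
  expect_equal(das_delays(geo, 0), rep(0, 4))
  tau90 <- das_delays(geo, 90)
  expect_equal(tau90[1], 0)
  expect_equal(tau90[4], 0.12 / 343, tolerance = 1e-12)
  for (phi in c(10, 35, 80)) {
    expect_equal(das_delays(geo, -phi), -das_delays(geo, phi))
  }
  expect_error(das_delays(geo, 95), "90")
})

test_that("delay-and-sum of pre-aligned channels is a coherent x4 sum", {
  set.seed(2)
  x <- stats::rnorm(4000)
  ch <- matrix(rep(x, 4), ncol = 4)
  y <- delay_and_sum(ch, array_geometry(), doa = 0)
  expect_equal(y, 4 * x, tolerance = 1e-12)
})

test_that("delay-and-sum achieves the classical ~6 dB coherent gain", {
  # plane wave from 20 deg plus independent white noise per channel
  set.seed(3)
  geo <- array_geometry()
  fs <- 16000
  t <- (0:(2 * fs - 1)) / fs
  env <- c(numeric(0.4 * fs), rep(1, 1.2 * fs), numeric(0.4 * fs))
  sig <- sin(2 * pi * 800 * t) * env
  tau <- das_delays(geo, 20) * fs
  ch <- vapply(1:4, function(l) {
    dysvox:::fractional_delay(sig, -tau[l]) + 0.4 * stats::rnorm(length(sig))
  }, numeric(length(sig)))
  snr_in <- estimate_snr(ch[, 1], fs)
  snr_das <- estimate_snr(delay_and_sum(ch, geo, doa = 20), fs)
  gain <- snr_das - snr_in
  expect_gt(gain, 4.5)
  expect_lt(gain, 7.5)
  # steering 90 degrees away never beats steering at the source
  snr_off <- estimate_snr(delay_and_sum(ch, geo, doa = -70), fs)
  expect_lte(snr_off, snr_das)
})

test_that("noise covariance converges to sigma^2 I for spatially white noise", {
  set.seed(4)
  fs <- 16000
  ch <- matrix(stats::rnorm(4 * fs), ncol = 4)
  fr <- stft(ch, fs)
  m <- dim(fr$X)[2]
  S <- estimate_noise_covariance(fr, rep(TRUE, m), loading = 1e-3)
  # average over mid-band bins: off-diagonals vanish relative to diagonal
  ratios <- vapply(50:200, function(b) {
    Sb <- S[, , b]
    max(Mod(Sb[upper.tri(Sb)])) / mean(Re(diag(Sb)))
  }, 0)
  expect_lt(stats::median(ratios), 0.25)
  # single noise frame stays invertible through loading
  S1 <- estimate_noise_covariance(fr, seq_len(m) == 1, loading = 1e-3)
  expect_true(attr(S1, "flagged"))
  expect_no_error(solve(S1[, , 10]))
  # all-zero masked frames: loaded zero matrix, still invertible
  frz <- fr
  frz$X[, 1, ] <- 0
  Sz <- estimate_noise_covariance(frz, seq_len(m) == 1, loading = 1e-3)
  expect_no_error(solve(Sz[, , 10]))
  expect_error(estimate_noise_covariance(fr, rep(FALSE, m)), "edge")
})

test_that("MVDR weights are distortionless and reduce to D&S for white noise", {
  set.seed(5)
  # closed form: identity covariance gives w = v / L
  v <- exp(-1i * stats::runif(4, 0, 2))
  expect_equal(mvdr_weights(v, diag(4) + 0i), v / 4, tolerance = 1e-12)
  # distortionless for random Hermitian PSD covariances
  for (i in 1:20) {
    A <- matrix(complex(real = stats::rnorm(16), imaginary = stats::rnorm(16)), 4)
    S <- A %*% Conj(t(A)) + 0.01 * diag(4)
    v <- exp(-1i * stats::runif(4, 0, 6))
    w <- mvdr_weights(v, S)
    expect_lt(Mod(sum(Conj(w) * v) - 1), 1e-9)
  }
})

test_that("MVDR steers a null at a dominant interferer", {
  geo <- array_geometry(offsets = c(0, 0.08))
  fs <- 16000
  f <- 1500
  omega <- 2 * pi * f
  v_look <- exp(-1i * omega * das_delays(geo, 0))
  v_int <- exp(-1i * omega * das_delays(geo, 40))
  S <- 100 * (v_int %*% Conj(t(v_int))) + 0.01 * diag(2)
  w <- mvdr_weights(v_look, S)
  # brute-force beampattern scan: the minimum sits near the interferer
  angs <- seq(-90, 90, by = 2)
  bp <- vapply(angs, function(a) {
    Mod(sum(Conj(w) * exp(-1i * omega * das_delays(geo, a))))
  }, 0)
  expect_lt(Mod(sum(Conj(w) * v_int)), 0.1)
  expect_lt(abs(angs[which.min(bp)] - 40), 15)
})

test_that("single-channel MVDR is the identity and clean captures pass through", {
  set.seed(6)
  p <- test_profile()
  v <- synthesize_vocalization(list(subject_id = "M", mmrc_class = 0L),
                               "ae", 1, p, seed = 13)
  x1 <- matrix(v$samples, ncol = 1)
  y1 <- mvdr_filter(x1, array_geometry(offsets = 0), doa = 0)
  expect_equal(y1, v$samples, tolerance = 1e-12)
  # noise-free anechoic capture: output strongly correlates with the clean
  # reference (distortionless pass-through)
  cond <- list(distance = 2, angle = 0,
               rir = simulate_rir(room_spec(), 2, 0, array_geometry(),
                                  anechoic = TRUE))
  cap <- simulate_capture(v, cond, bank = NULL, snr_db = Inf)
  y <- mvdr_filter(cap, array_geometry())
  expect_gt(stats::cor(y, cap$reference), 0.99)
})

test_that("edge-interval SNR estimator recovers constructed mixtures", {
  set.seed(7)
  fs <- 16000
  noise <- stats::rnorm(3 * fs, 0, 0.1)
  # tone filling the whole interior, with power 10x the noise power
  ne <- 0.3 * fs
  interior <- (ne + 1):(3 * fs - ne)
  tone <- sqrt(2 * 10 * 0.01) * sin(2 * pi * 500 * seq_along(interior) / fs)
  x <- noise
  x[interior] <- x[interior] + tone
  expect_lt(abs(estimate_snr(x, fs) - 10), 1)
  # pure stationary noise sits at (or flags) the lower bound
  s0 <- estimate_snr(noise, fs)
  expect_true(isTRUE(attr(s0, "lower_bound")) || s0 < -10)
  # monotone in speech gain for silent edges
  mk <- function(g) {
    z <- stats::rnorm(3 * fs, 0, 1e-4)
    z[interior] <- z[interior] + g * tone
    estimate_snr(z, fs)
  }
  snrs <- vapply(c(0.5, 1, 2, 4), mk, 0)
  expect_true(all(diff(snrs) > 0))
  expect_gt(snrs[1], 20)
  expect_error(estimate_snr(stats::rnorm(100), fs), "edge")
})

test_that("D&S equals scaled MVDR when the noise field is isotropic", {
  # with Sigma = I the MVDR weights are v/L: filtering with them equals
  # delay-and-sum up to the 1/L scale; checked in the frequency domain
  geo <- array_geometry()
  fs <- 16000
  omega <- 2 * pi * 700
  v <- exp(-1i * omega * das_delays(geo, 15))
  w <- mvdr_weights(v, diag(4) + 0i)
  expect_equal(w, v / 4, tolerance = 1e-12)
})
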