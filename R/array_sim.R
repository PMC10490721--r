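# Acoustic HRI scene simulation.
#
# Emulates the recording environment: a reverberant room (image-source
# room impulse responses on a 3-distance x 11-angle grid), a robot-ego +
# environmental noise mixture, and static or rotating-head capture on a
# 4-microphone linear array with a known DOA track.

#' Linear microphone-array geometry
#'
#' @param offsets microphone positions (m) along the array axis relative
#'   to the reference microphone (microphone 1). Default is a 4-element
#'   non-uniform Kinect-like layout.
#' @param v speed of sound (m/s).
#' @return object of class `dysvox_geometry`.
#' @export
array_geometry <- function(offsets = c(0, 0.04, 0.08, 0.12), v = 343) {
  if (offsets[1] != 0) stop("reference microphone offset must be 0", call. = FALSE)
  if (any(diff(offsets) <= 0)) stop("offsets must be strictly increasing", call. = FALSE)
  structure(list(offsets = offsets, v = v, L = length(offsets)),
            class = "dysvox_geometry")
}

#' Room specification
#'
#' The default box is 6.5 x 5.35 x 3.0 m (~104 m^3) with RT60 = 0.5 s,
#' emulating the target indoor recording room.
#'
#' @param dims box dimensions (m).
#' @param rt60 target reverberation time (s).
#' @param array_pos position of the reference microphone (m); must be
#'   inside the box. The array lies along the x axis; sources are placed
#'   in the x-y plane at the capture distance and angle from broadside
#'   (+y).
#' @return object of class `dysvox_room`.
#' @export
room_spec <- function(dims = c(6.5, 5.35, 3.0), rt60 = 0.5,
                      array_pos = c(dims[1] / 2, 1.2, 1.5)) {
  if (any(dims <= 0)) stop("room dimensions must be positive", call. = FALSE)
  if (rt60 <= 0) stop("rt60 must be positive", call. = FALSE)
  if (any(array_pos <= 0) || any(array_pos >= dims)) {
    stop("array position must lie inside the room", call. = FALSE)
  }
  structure(list(dims = dims, rt60 = rt60, array_pos = array_pos,
                 volume = prod(dims)),
            class = "dysvox_room")
}

# Source position for a given capture distance and DOA (degrees from
# broadside, positive towards increasing mic offsets).
source_position <- function(room, distance, angle_deg) {
  a <- angle_deg * pi / 180
  pos <- room$array_pos + distance * c(sin(a), cos(a), 0)
  if (any(pos <= 0) || any(pos >= room$dims)) {
    stop(sprintf("source at %.1f m / %.0f deg falls outside the room",
                 distance, angle_deg), call. = FALSE)
  }
  pos
}

# ---- image-source RIR ------------------------------------------------------

# Uniform wall reflection coefficient from Eyring's formula.
wall_beta <- function(room) {
  d <- room$dims
  S <- 2 * (d[1] * d[2] + d[1] * d[3] + d[2] * d[3])
  alpha <- 1 - exp(-0.161 * room$volume / (S * room$rt60))
  sqrt(1 - min(alpha, 0.9999))
}

.beta_cache <- new.env(parent = emptyenv())

# Calibrated wall coefficient: with frequency-independent walls the
# image-source decay is dominated by axial paths and runs slower than the
# Eyring prediction, so the coefficient is adjusted until the simulated
# Schroeder RT60 matches the room's nominal RT60. Cached per room/rate.
room_beta <- function(room, rate) {
  key <- paste(c(room$dims, room$rt60, rate), collapse = "_")
  if (!is.null(.beta_cache[[key]])) return(.beta_cache[[key]])
  beta <- wall_beta(room)
  src <- source_position(room, 2, 0)
  for (it in 1:5) {
    h <- ism_channel(room, src, room$array_pos, rate, beta,
                     1.1 * room$rt60)
    t_est <- estimate_rt60(h, rate)
    if (is.na(t_est)) break
    if (abs(t_est - room$rt60) < 0.02 * room$rt60) break
    beta <- beta^(t_est / room$rt60)
  }
  .beta_cache[[key]] <- beta
  beta
}

# Image-source impulse response from a point source to one microphone.
# `axis` (unit vector) gives the source's facing direction; when set, a
# cardioid directivity pattern is applied (loudspeaker-like source), with
# the pattern axis mirrored per image reflection parity.
ism_channel <- function(room, src, mic, rate, beta, rir_length,
                        axis = NULL) {
  v <- 343
  d_max <- v * rir_length
  dims <- room$dims
  n_ord <- ceiling(d_max / (2 * dims)) + 1L
  g <- expand.grid(nx = -n_ord[1]:n_ord[1], ny = -n_ord[2]:n_ord[2],
                   nz = -n_ord[3]:n_ord[3], px = 0:1, py = 0:1, pz = 0:1,
                   KEEP.OUT.ATTRS = FALSE)
  img <- cbind((1 - 2 * g$px) * src[1] + 2 * g$nx * dims[1],
               (1 - 2 * g$py) * src[2] + 2 * g$ny * dims[2],
               (1 - 2 * g$pz) * src[3] + 2 * g$nz * dims[3])
  refl <- abs(g$nx - g$px) + abs(g$nx) + abs(g$ny - g$py) + abs(g$ny) +
    abs(g$nz - g$pz) + abs(g$nz)
  dl <- sqrt((img[, 1] - mic[1])^2 + (img[, 2] - mic[2])^2 +
             (img[, 3] - mic[3])^2)
  keep <- dl <= d_max
  amp <- beta^refl[keep] / (4 * pi * dl[keep])
  if (!is.null(axis)) {
    ex <- (mic[1] - img[keep, 1]) / dl[keep]
    ey <- (mic[2] - img[keep, 2]) / dl[keep]
    ez <- (mic[3] - img[keep, 3]) / dl[keep]
    ct <- ex * (1 - 2 * g$px[keep]) * axis[1] +
      ey * (1 - 2 * g$py[keep]) * axis[2] +
      ez * (1 - 2 * g$pz[keep]) * axis[3]
    amp <- amp * (1 + ct) / 2
  }
  n <- ceiling(rir_length * rate)
  idx <- round(dl[keep] / v * rate) + 1L
  ok <- idx <= n
  s <- rowsum(amp[ok], idx[ok])
  h <- numeric(n)
  h[as.integer(rownames(s))] <- s[, 1]
  h
}

#' Simulate a room impulse response for one capture condition
#'
#' Frequency-independent image-source method with a uniform wall
#' reflection coefficient derived from the room's RT60 (Eyring). The
#' direct-path inter-microphone delays equal [das_delays()] for the same
#' angle within one sample.
#'
#' @param room a [room_spec()].
#' @param distance source distance (m).
#' @param angle source DOA (degrees from array broadside).
#' @param geometry an [array_geometry()].
#' @param rate sample rate (Hz).
#' @param anechoic if TRUE only the direct path is rendered (a pure
#'   scaled, delayed impulse per microphone).
#' @param directional_source if TRUE (default) the source radiates with a
#'   cardioid pattern facing the array, emulating the testbed's
#'   loudspeaker sources; FALSE gives an omnidirectional point source.
#' @param rir_length RIR length (s); defaults to 1.1 x RT60.
#' @return object of class `dysvox_rir`: list with `h` (samples x L
#'   matrix), `rate`, `distance`, `angle`.
#' @export
simulate_rir <- function(room, distance, angle, geometry = array_geometry(),
                         rate = 16000, anechoic = FALSE, rir_length = NULL,
                         directional_source = TRUE) {
  src <- source_position(room, distance, angle)
  mics <- lapply(geometry$offsets,
                 function(o) room$array_pos + c(o, 0, 0))
  v <- geometry$v
  if (anechoic) {
    dists <- vapply(mics, function(m) sqrt(sum((src - m)^2)), 0)
    n <- max(round(dists / v * rate)) + 8L
    h <- matrix(0, n, geometry$L)
    for (l in seq_len(geometry$L)) {
      h[round(dists[l] / v * rate) + 1L, l] <- 1 / (4 * pi * dists[l])
    }
    return(structure(list(h = h, rate = rate, distance = distance,
                          angle = angle), class = "dysvox_rir"))
  }
  if (is.null(rir_length)) rir_length <- 1.1 * room$rt60
  beta <- room_beta(room, rate)
  axis <- if (directional_source) {
    a <- room$array_pos - src
    a / sqrt(sum(a^2))
  } else NULL
  h <- vapply(mics, function(m) ism_channel(room, src, m, rate, beta,
                                            rir_length, axis),
              numeric(ceiling(rir_length * rate)))
  structure(list(h = h, rate = rate, distance = distance, angle = angle),
            class = "dysvox_rir")
}

#' Build the full RIR condition grid
#'
#' Cartesian product of capture distances and head angles; the default 3
#' distances x 11 angles gives the 33 capture conditions. Each condition
#' also carries the RIR of the noise source, which sits at a fixed
#' angular separation from the speech source.
#'
#' @param room,geometry,rate as in [simulate_rir()].
#' @param distances capture distances (m).
#' @param angles head angles (degrees); default 11 values -50..50.
#' @param noise_sep_deg angular separation of the noise source from the
#'   speech source (degrees).
#' @param anechoic passed to [simulate_rir()].
#' @return list of conditions; each is a list with `distance`, `angle`,
#'   `rir` (speech-source `dysvox_rir`) and `noise_rir`.
#' @export
build_rir_grid <- function(room = room_spec(), geometry = array_geometry(),
                           distances = c(1, 2, 3),
                           angles = seq(-50, 50, by = 10),
                           rate = 16000, noise_sep_deg = 45,
                           anechoic = FALSE) {
  combos <- expand.grid(distance = distances, angle = angles,
                        KEEP.OUT.ATTRS = FALSE)
  if (anyDuplicated(combos)) stop("duplicate grid conditions", call. = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    d <- combos$distance[i]; a <- combos$angle[i]
    # keep the noise source inside the room: flip the separation side if needed
    na <- a + noise_sep_deg
    ok <- tryCatch({source_position(room, d, na); TRUE},
                   error = function(e) FALSE)
    if (!ok) na <- a - noise_sep_deg
    list(distance = d, angle = a,
         rir = simulate_rir(room, d, a, geometry, rate, anechoic = anechoic),
         noise_rir = simulate_rir(room, d, na, geometry, rate,
                                  anechoic = anechoic))
  })
}

# FFT convolution (full length).
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                     stats::fft(c(h, numeric(nf - length(h)))),
                     inverse = TRUE)) / nf
  y[seq_len(n)]
}

# Convolve a mono signal with a multichannel RIR -> samples x L matrix.
apply_rir <- function(x, rir) {
  vapply(seq_len(ncol(rir$h)), function(l) fft_conv(x, rir$h[, l]),
         numeric(length(x) + nrow(rir$h) - 1L))
}

# ---- noise model -----------------------------------------------------------

pink_noise <- function(n) {
  # Paul Kellet's economy pink-noise filter
  w <- stats::rnorm(n)
  b <- as.numeric(signal::filter(c(0.049922035, -0.095993537, 0.050612699,
                                   -0.004408786),
                                 c(1, -2.494956002, 2.017265875,
                                   -0.522189400), w))
  b / max(1e-12, stats::sd(b))
}

band_noise <- function(n, lo, hi, rate) {
  ny <- rate / 2
  bf <- signal::butter(2, c(max(lo, 1) / ny, min(hi, ny * 0.98) / ny), "pass")
  x <- as.numeric(signal::filter(bf, stats::rnorm(n)))
  x / max(1e-12, stats::sd(x))
}

#' Generate the robot-ego and environmental noise bank
#'
#' The robot surrogate is band-limited pink noise plus a low-frequency
#' fan hum. Six generated environmental classes mirror common indoor /
#' transport noise categories (street, station, car, babble, restaurant,
#' airport) through distinct spectral shapes and amplitude modulations.
#'
#' @param rate sample rate (Hz).
#' @param duration noise duration (s).
#' @param seed integer seed.
#' @return list with `robot` (samples), `robot_mc` (samples x 4 matrix of
#'   independent ego-noise realizations, channel 1 equal to `robot`),
#'   `env` (named list of 6 sample vectors), `rate`.
#' @export
noise_bank <- function(rate = 16000, duration = 15, seed = 1) {
  n <- round(duration * rate)
  t <- seq_len(n) / rate
  with_seed(seed, {
    make_robot <- function() {
      r <- pink_noise(n) +
        0.5 * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi)) +
        0.2 * sin(2 * pi * 100 * t + stats::runif(1, 0, 2 * pi))
      r / stats::sd(r)
    }
    # four independent realizations: ego noise is generated at the head and
    # is modelled as spatially incoherent across the microphones
    robot_mc <- vapply(1:4, function(l) make_robot(), numeric(n))
    am <- function(f) 1 + 0.5 * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    env <- list(
      street = band_noise(n, 50, 2000, rate) * am(0.5),
      station = band_noise(n, 100, 6000, rate) * am(0.3),
      car = band_noise(n, 30, 300, rate),
      babble = band_noise(n, 300, 3400, rate) * am(4),
      restaurant = band_noise(n, 200, 4000, rate) * am(3) +
        0.3 * band_noise(n, 3000, 7000, rate) * (stats::runif(n) < 0.001),
      airport = band_noise(n, 100, 5000, rate) * am(0.2) +
        0.2 * sin(2 * pi * 440 * t) * (t %% 5 < 1)
    )
    list(robot = robot_mc[, 1], robot_mc = robot_mc,
         env = lapply(env, function(e) e / stats::sd(e)),
         rate = rate)
  })
}

# Loop or trim `noise` to exactly `n` samples.
fit_length <- function(noise, n) {
  if (length(noise) == 0L) stop("empty noise input", call. = FALSE)
  if (length(noise) < n) {
    noise <- rep_len(noise, n)
  } else if (length(noise) > n) {
    noise <- noise[seq_len(n)]
  }
  noise
}

#' Mix noise into a target signal at an exact SNR
#'
#' The noise is looped or trimmed to the target length and scaled so that
#' `10*log10(E_target / E_noise)` equals `snr_db` exactly (energies over
#' the full length). `snr_db = Inf` disables the noise.
#'
#' @param target,noise sample vectors.
#' @param snr_db desired signal-to-noise ratio (dB), or `Inf`.
#' @return list with `mix`, `noise_scaled`, `gain`.
#' @export
mix_at_snr <- function(target, noise, snr_db) {
  if (is.infinite(snr_db) && snr_db > 0) {
    return(list(mix = target, noise_scaled = numeric(length(target)),
                gain = 0))
  }
  noise <- fit_length(noise, length(target))
  e_t <- signal_energy(target)
  e_n <- signal_energy(noise)
  if (e_n <= 0) stop("zero-energy noise", call. = FALSE)
  g <- sqrt(e_t / (e_n * db_to_pow(snr_db)))
  ns <- g * noise
  list(mix = target + ns, noise_scaled = ns, gain = g)
}

#' Combine robot and environmental noise at a given energy ratio
#'
#' @param robot_noise,env_noise sample vectors; `env_noise = NULL`
#'   disables the environmental component.
#' @param ratio_db robot-to-environment energy ratio (dB).
#' @return combined noise samples (length of `robot_noise`).
#' @export
make_noise_mixture <- function(robot_noise, env_noise, ratio_db = 0) {
  if (length(robot_noise) == 0L) stop("empty robot noise", call. = FALSE)
  if (is.null(env_noise) || length(env_noise) == 0L ||
      (is.infinite(ratio_db) && ratio_db > 0)) {
    return(robot_noise)
  }
  env_noise <- fit_length(env_noise, length(robot_noise))
  if (is.infinite(ratio_db)) {                  # -Inf: environment only
    return(env_noise * sqrt(signal_energy(robot_noise) /
                              signal_energy(env_noise)))
  }
  e_r <- signal_energy(robot_noise)
  e_e <- signal_energy(env_noise)
  if (e_e <= 0) stop("zero-energy environmental noise", call. = FALSE)
  g <- sqrt(e_r / (e_e * db_to_pow(ratio_db)))
  robot_noise + g * env_noise
}

# ---- capture ---------------------------------------------------------------

new_capture <- function(channels, rate, doa, scene, reference = NULL,
                        noise_component = NULL, doa_track = NULL) {
  structure(list(channels = channels, rate = rate, doa = doa,
                 doa_track = doa_track, scene = scene,
                 reference = reference, noise_component = noise_component),
            class = "dysvox_capture")
}

#' Simulate one static array capture
#'
#' Convolves a mono vocalization with the speech-source RIR of one grid
#' condition and adds the scene noise at the requested SNR (defined on
#' the reference channel). Environmental noise plays through the
#' noise-source loudspeaker (spatialized by the condition's noise RIR);
#' robot ego noise originates at the head and is added at the
#' microphones as spatially incoherent per-channel streams. The two are
#' combined at `ratio_db` (robot-to-environment energy ratio on channel
#' 1); `ratio_db = -Inf` gives the environment-only testbed scene (the
#' default), `+Inf` robot-only.
#'
#' @param x mono samples (or a `dysvox_vocalization`).
#' @param condition one element of [build_rir_grid()].
#' @param bank a [noise_bank()]; `NULL` disables noise.
#' @param snr_db speech SNR (dB) on channel 1; `Inf` disables noise.
#' @param ratio_db robot-to-environment ratio (dB); see above.
#' @param env_class name of the environmental class to use.
#' @param rate sample rate; taken from `x` when it is a vocalization.
#' @return a `dysvox_capture` with clean reference and noise component
#'   stored for SNR bookkeeping.
#' @export
simulate_capture <- function(x, condition, bank = NULL, snr_db = 10,
                             ratio_db = -Inf, env_class = "restaurant",
                             rate = 16000) {
  if (inherits(x, "dysvox_vocalization")) {
    rate <- x$rate
    x <- x$samples
  }
  clean <- apply_rir(x, condition$rir)
  n <- nrow(clean)
  L <- ncol(clean)
  scene <- list(distance = condition$distance, angle = condition$angle,
                snr_db = snr_db, ratio_db = ratio_db, env_class = env_class)
  if (is.null(bank) || is.infinite(snr_db) && snr_db > 0) {
    return(new_capture(clean, rate, condition$angle, scene,
                       reference = clean[, 1],
                       noise_component = numeric(n)))
  }
  if (is.infinite(ratio_db) && ratio_db > 0) {            # robot only
    noise <- apply(bank$robot_mc, 2, fit_length, n = n)
  } else {
    env_sp <- apply_rir(fit_length(bank$env[[env_class]], n),
                        condition$noise_rir)[seq_len(n), , drop = FALSE]
    if (is.infinite(ratio_db)) {                          # environment only
      noise <- env_sp
    } else {
      robot <- apply(bank$robot_mc, 2, fit_length, n = n)
      g_env <- sqrt(signal_energy(robot[, 1]) /
                      (signal_energy(env_sp[, 1]) * db_to_pow(ratio_db)))
      noise <- robot + g_env * env_sp
    }
  }
  m <- mix_at_snr(clean[, 1], noise[, 1], snr_db)
  new_capture(clean + m$gain * noise[, seq_len(L), drop = FALSE], rate,
              condition$angle, scene,
              reference = clean[, 1],
              noise_component = m$gain * noise[, 1])
}

#' Apply the acoustic training augmentation to a corpus
#'
#' For every corpus utterance: draw a RIR condition, an environmental
#' noise class, a robot/environment ratio and an SNR, build the
#' 4-channel capture, and hand it to `handler`. All draws are logged in
#' the returned provenance table.
#'
#' @param corpus metadata table from [generate_corpus()].
#' @param profile the [generator_profile()] used to build the corpus
#'   (utterances are re-synthesized from their stored seeds).
#' @param rir_grid from [build_rir_grid()].
#' @param bank a [noise_bank()].
#' @param snr_range length-2 range of speech SNR draws (dB).
#' @param ratio_range length-2 range of robot/environment ratio draws (dB).
#' @param seed master seed for the draws.
#' @param handler function(capture, meta_row) called per utterance; its
#'   results are returned in `$results`.
#' @return list with `provenance` (data.frame, one row per utterance) and
#'   `results` (list of handler outputs).
#' @export
simulate_training_corpus <- function(corpus, profile, rir_grid, bank,
                                     snr_range = c(5, 15),
                                     ratio_range = c(-5, 5),
                                     seed = 1, handler = NULL) {
  n <- nrow(corpus)
  draws <- with_seed(seed, data.frame(
    cond = sample.int(length(rir_grid), n, replace = TRUE),
    env = sample(names(bank$env), n, replace = TRUE),
    snr_db = stats::runif(n, snr_range[1], snr_range[2]),
    ratio_db = stats::runif(n, ratio_range[1], ratio_range[2]),
    stringsAsFactors = FALSE
  ))
  results <- vector("list", n)
  for (i in seq_len(n)) {
    voc <- corpus_vocalization(corpus[i, ], profile)
    cap <- simulate_capture(voc, rir_grid[[draws$cond[i]]], bank,
                            draws$snr_db[i], draws$ratio_db[i],
                            draws$env[i])
    if (!is.null(handler)) results[[i]] <- handler(cap, corpus[i, ])
  }
  prov <- cbind(corpus[, c("subject_id", "mmrc_class", "phonetization",
                           "repetition", "file")],
                distance = vapply(draws$cond, function(j) rir_grid[[j]]$distance, 0),
                angle = vapply(draws$cond, function(j) rir_grid[[j]]$angle, 0),
                draws[, c("env", "snr_db", "ratio_db")])
  list(provenance = prov, results = results)
}

#' Triangular DOA track for the rotating-head scenario
#'
#' @param n number of samples.
#' @param rate sample rate (Hz).
#' @param rate_rad_s angular velocity (rad/s).
#' @param limit_deg rotation limits (+/- degrees).
#' @return numeric vector of angles (degrees), one per sample; a
#'   triangular wave starting at 0 and rising.
#' @export
doa_triangle <- function(n, rate, rate_rad_s = 0.42, limit_deg = 50) {
  if (rate_rad_s <= 0) stop("angular rate must be > 0", call. = FALSE)
  if (limit_deg == 0) return(numeric(n))
  slope <- rate_rad_s * 180 / pi              # deg/s
  t <- (seq_len(n) - 1L) / rate
  period <- 4 * limit_deg / slope
  ph <- (t %% period) / period                 # 0..1
  tri <- ifelse(ph < 0.25, 4 * ph,
                ifelse(ph < 0.75, 2 - 4 * ph, 4 * ph - 4))
  limit_deg * tri
}

#' Simulate a rotating-head (dynamic) capture
#'
#' The head sweeps between the rotation limits at constant angular
#' velocity (triangular DOA track). The capture is built in 20 ms blocks;
#' each block is convolved with the RIR of the nearest angle in a
#' precomputed angle set and the block responses are overlap-added.
#'
#' @param x mono samples or `dysvox_vocalization`.
#' @param room,geometry as elsewhere.
#' @param distance source distance (m).
#' @param rate_rad_s,limit_deg motion parameters.
#' @param bank,snr_db,ratio_db,env_class noise scene (as in
#'   [simulate_capture()]).
#' @param block_s block length (s).
#' @param angle_step resolution of the precomputed RIR angle set (deg).
#' @param anechoic build anechoic RIRs (for geometry tests).
#' @param rate sample rate.
#' @return a `dysvox_capture` with `doa_track` (per-sample, degrees).
#' @export
simulate_dynamic_capture <- function(x, room = room_spec(),
                                     geometry = array_geometry(),
                                     distance = 2, rate_rad_s = 0.42,
                                     limit_deg = 50, bank = NULL,
                                     snr_db = Inf, ratio_db = 0,
                                     env_class = "babble", block_s = 0.02,
                                     angle_step = 5, anechoic = FALSE,
                                     rate = 16000) {
  if (block_s <= 0) stop("block length must be > 0", call. = FALSE)
  if (inherits(x, "dysvox_vocalization")) {
    rate <- x$rate
    x <- x$samples
  }
  n <- length(x)
  track <- doa_triangle(n, rate, rate_rad_s, limit_deg)
  angles <- if (limit_deg == 0) 0 else seq(-limit_deg, limit_deg, by = angle_step)
  rirs <- lapply(angles, function(a)
    simulate_rir(room, distance, a, geometry, rate, anechoic = anechoic))
  h_len <- max(vapply(rirs, function(r) nrow(r$h), 0L))
  blk <- max(1L, round(block_s * rate))
  out <- matrix(0, n + h_len, geometry$L)
  starts <- seq(1L, n, by = blk)
  for (s in starts) {
    e <- min(n, s + blk - 1L)
    a_blk <- track[(s + e) %/% 2L]
    r <- rirs[[which.min(abs(angles - a_blk))]]
    seg <- x[s:e]
    y <- vapply(seq_len(geometry$L),
                function(l) fft_conv(seg, r$h[, l]),
                numeric(length(seg) + nrow(r$h) - 1L))
    idx <- s:(s + nrow(y) - 1L)
    out[idx, ] <- out[idx, ] + y
  }
  out <- out[seq_len(n), , drop = FALSE]
  scene <- list(distance = distance, rate_rad_s = rate_rad_s,
                limit_deg = limit_deg, snr_db = snr_db,
                ratio_db = ratio_db, env_class = env_class)
  if (is.null(bank) || is.infinite(snr_db)) {
    return(new_capture(out, rate, NULL, scene, reference = out[, 1],
                       noise_component = numeric(n), doa_track = track))
  }
  nm <- make_noise_mixture(bank$robot, bank$env[[env_class]], ratio_db)
  nm <- fit_length(nm, n)
  # noise source is static relative to the room; reuse the broadside+45 RIR
  nrir <- simulate_rir(room, distance, 45, geometry, rate,
                       anechoic = anechoic)
  noise_sp <- apply_rir(nm, nrir)[seq_len(n), , drop = FALSE]
  m <- mix_at_snr(out[, 1], noise_sp[, 1], snr_db)
  new_capture(out + m$gain * noise_sp, rate, NULL, scene,
              reference = out[, 1],
              noise_component = m$gain * noise_sp[, 1], doa_track = track)
}

#' Estimate RT60 by Schroeder backward integration
#'
#' Fits the -5 to -25 dB span of the Schroeder energy-decay curve (T20)
#' and extrapolates to 60 dB.
#'
#' @param rir sample vector (one channel) or a `dysvox_rir` (channel 1
#'   is used).
#' @param rate sample rate (Hz); taken from the object if available.
#' @return estimated RT60 in seconds. If the decay range is insufficient
#'   to fit (less than 25 dB of decay), `NA` is returned with attribute
#'   `flagged = TRUE`.
#' @export
estimate_rt60 <- function(rir, rate = 16000) {
  if (inherits(rir, "dysvox_rir")) {
    rate <- rir$rate
    rir <- rir$h[, 1]
  }
  if (length(rir) == 0L) stop("empty impulse response", call. = FALSE)
  e <- rev(cumsum(rev(rir^2)))
  e <- e / e[1]
  db <- 10 * log10(pmax(e, 1e-30))
  i5 <- which(db <= -5)[1]
  i25 <- which(db <= -25)[1]
  if (is.na(i5) || is.na(i25) || i25 - i5 < 4L) {
    return(structure(NA_real_, flagged = TRUE))
  }
  t <- (seq_along(db) - 1L) / rate
  fit <- stats::lm.fit(cbind(1, t[i5:i25]), db[i5:i25])
  slope <- fit$coefficients[2]
  unname(-60 / slope)
}

#' @export
print.dysvox_capture <- function(x, ...) {
  cat(sprintf("<array capture: %d channels x %d samples @ %d Hz, %s>\n",
              ncol(x$channels), nrow(x$channels), x$rate,
              if (is.null(x$doa_track)) sprintf("static DOA %.0f deg", x$doa)
              else sprintf("dynamic DOA track (+/-%g deg)", x$scene$limit_deg)))
  invisible(x)
}
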