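# Spatial filtering: delay-and-sum and MVDR beamformers, the STFT
# machinery they operate in, and the edge-interval SNR estimator.
#
# Conventions: the steering vector at frame m is
# v(m, w) = [exp(-j w tau_1), ..., exp(-j w tau_L)] with tau_l the
# geometric delay of channel l for the frame's DOA, and the MVDR weights
# are w^H = v^H S^-1 / (v^H S^-1 v) with S the noise covariance, so the
# look direction is passed with unit gain (distortionless constraint).

#' Short-time Fourier transform of a (multi)channel signal
#'
#' sqrt-Hann analysis window; with the default 50% overlap the
#' analysis/synthesis pair satisfies constant overlap-add, so
#' [istft()] reconstructs the interior of the signal exactly.
#'
#' @param x numeric vector (mono) or samples x channels matrix.
#' @param rate sample rate (Hz).
#' @param frame_length frame length in samples (default 512 = 32 ms at
#'   16 kHz).
#' @param overlap fractional overlap in \[0, 1).
#' @param dft_size DFT length (>= frame_length); `dft_size/2 + 1`
#'   one-sided frequency bins are kept.
#' @return object of class `dysvox_stft`: list with `X` (complex array
#'   bins x frames x channels), `rate`, `frame_length`, `dft_size`,
#'   `hop`, `n_samples`, `num_freq_bins`.
#' @export
stft <- function(x, rate = 16000, frame_length = 512, overlap = 0.5,
                 dft_size = frame_length) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (nrow(x) == 0L) stop("empty input", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0,1)", call. = FALSE)
  if (dft_size < frame_length) stop("dft_size must be >= frame_length", call. = FALSE)
  hop <- max(1L, round(frame_length * (1 - overlap)))
  n <- nrow(x)
  n_pad <- n + frame_length                      # zero tail for full OLA
  starts <- seq(1L, n_pad - frame_length + 1L, by = hop)
  m <- length(starts)
  nb <- dft_size %/% 2L + 1L
  win <- sqrt(hann_periodic(frame_length))
  X <- array(0i, dim = c(nb, m, ncol(x)))
  idx <- outer(0:(frame_length - 1L), starts, "+")
  for (l in seq_len(ncol(x))) {
    xp <- c(x[, l], numeric(frame_length))
    fr <- matrix(xp[idx], frame_length, m) * win
    if (dft_size > frame_length) {
      fr <- rbind(fr, matrix(0, dft_size - frame_length, m))
    }
    X[, , l] <- stats::mvfft(fr)[seq_len(nb), , drop = FALSE]
  }
  structure(list(X = X, rate = rate, frame_length = frame_length,
                 dft_size = dft_size, hop = hop, n_samples = n,
                 num_freq_bins = nb),
            class = "dysvox_stft")
}

hann_periodic <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Inverse STFT (overlap-add with the matched sqrt-Hann window)
#'
#' @param frames a `dysvox_stft`, or such an object whose `X` has been
#'   replaced by a bins x frames matrix (single-channel spectra).
#' @param channel which channel to invert when `X` is 3-dimensional.
#' @return numeric sample vector of length `n_samples`.
#' @export
istft <- function(frames, channel = 1L) {
  X <- frames$X
  if (length(dim(X)) == 3L) X <- X[, , channel, drop = TRUE]
  nb <- frames$num_freq_bins
  dft <- frames$dft_size
  fl <- frames$frame_length
  m <- ncol(X)
  full <- rbind(X, Conj(X[(nb - 1L):2L, , drop = FALSE]))
  fr <- Re(stats::mvfft(full, inverse = TRUE)) / dft
  fr <- fr[seq_len(fl), , drop = FALSE]
  win <- sqrt(hann_periodic(fl))
  fr <- fr * win
  hop <- frames$hop
  out <- numeric(frames$n_samples + fl)
  wsum <- numeric(frames$n_samples + fl)
  starts <- seq(1L, by = hop, length.out = m)
  for (j in seq_len(m)) {
    idx <- starts[j]:(starts[j] + fl - 1L)
    out[idx] <- out[idx] + fr[, j]
    wsum[idx] <- wsum[idx] + win^2
  }
  (out / pmax(wsum, 1e-12))[seq_len(frames$n_samples)]
}

#' Geometric array delays for a DOA
#'
#' `tau_l = (d_l / v) * sin(phi)`: the delay applied to channel l to
#' align it with the reference microphone for a plane wave from angle
#' `phi` (degrees from broadside).
#'
#' @param geometry an [array_geometry()].
#' @param doa_deg angle in degrees, |phi| <= 90.
#' @return numeric vector of L delays (seconds); `tau_1 == 0`.
#' @export
das_delays <- function(geometry, doa_deg) {
  if (abs(doa_deg) > 90) stop("|DOA| must be <= 90 degrees", call. = FALSE)
  geometry$offsets / geometry$v * sin(doa_deg * pi / 180)
}

# Windowed-sinc fractional delay (8-tap, Hann-windowed). Positive
# `delay` shifts the signal later in time; fractional parts are
# interpolated.
fractional_delay <- function(x, delay_samples) {
  n0 <- length(x)
  n_int <- floor(delay_samples)
  frac <- delay_samples - n_int
  if (frac > 1e-9) {
    k <- 0:7
    taps <- sinc(k - 3 - frac) * hann_periodic(9)[k + 1]
    taps <- taps / sum(taps)
    xf <- as.numeric(stats::filter(c(x, numeric(8)), taps, sides = 1))
    xf[is.na(xf)] <- 0
    x <- xf
    n_int <- n_int - 3L                       # FIR group delay ~3 samples
  }
  y <- shift_samples(x, as.integer(n_int))
  if (length(y) >= n0) y[seq_len(n0)] else c(y, numeric(n0 - length(y)))
}

sinc <- function(t) ifelse(abs(t) < 1e-12, 1, sin(pi * t) / (pi * t))

shift_samples <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x[seq_len(n)])
  if (k > 0) c(numeric(k), x)[seq_len(n)] else c(x[-seq_len(-k)], numeric(-k))[seq_len(n)]
}

#' Delay-and-sum beamformer
#'
#' Time-aligns the channels toward the DOA with windowed-sinc fractional
#' delays and sums them (no 1/L normalization). For dynamic captures the
#' delays are recomputed per 20 ms block from the DOA track.
#'
#' @param capture a `dysvox_capture`, or a samples x channels matrix.
#' @param geometry an [array_geometry()].
#' @param doa look direction in degrees; defaults to the capture's
#'   stored DOA. Ignored when the capture has a DOA track.
#' @param block_s block length (s) for dynamic steering.
#' @return mono sample vector.
#' @export
delay_and_sum <- function(capture, geometry = array_geometry(), doa = NULL,
                          block_s = 0.02) {
  ch <- if (inherits(capture, "dysvox_capture")) capture$channels else capture
  track <- if (inherits(capture, "dysvox_capture")) capture$doa_track else NULL
  rate <- if (inherits(capture, "dysvox_capture")) capture$rate else 16000
  n <- nrow(ch)
  if (is.null(track)) {
    if (is.null(doa)) {
      if (inherits(capture, "dysvox_capture") && !is.null(capture$doa)) {
        doa <- capture$doa
      } else {
        stop("a DOA (or a capture with a DOA track) is required", call. = FALSE)
      }
    }
    tau <- das_delays(geometry, doa) * rate
    y <- numeric(n)
    for (l in seq_len(ncol(ch))) {
      y <- y + fractional_delay(ch[, l], tau[l])
    }
    return(y)
  }
  blk <- max(1L, round(block_s * rate))
  y <- numeric(n)
  starts <- seq(1L, n, by = blk)
  for (s in starts) {
    e <- min(n, s + blk - 1L)
    a <- track[(s + e) %/% 2L]
    tau <- das_delays(geometry, a) * rate
    pad <- 16L
    lo <- max(1L, s - pad); hi <- min(n, e + pad)
    acc <- numeric(hi - lo + 1L)
    for (l in seq_len(ncol(ch))) {
      acc <- acc + fractional_delay(ch[lo:hi, l], tau[l])
    }
    y[s:e] <- acc[(s - lo + 1L):(s - lo + 1L + (e - s))]
  }
  y
}

#' Noise spatial covariance per frequency bin
#'
#' Sample covariance of the channel spectra over noise-only frames, plus
#' diagonal loading `delta * trace/L` for invertibility.
#'
#' @param frames a multichannel `dysvox_stft`.
#' @param noise_mask logical vector over frames; TRUE marks noise-only
#'   frames.
#' @param loading diagonal loading factor `delta`.
#' @return complex array L x L x bins with attribute `flagged` when
#'   fewer than L noise frames were available.
#' @export
estimate_noise_covariance <- function(frames, noise_mask, loading = 1e-3) {
  X <- frames$X
  stopifnot(length(dim(X)) == 3L)
  nb <- dim(X)[1]; m <- dim(X)[2]; L <- dim(X)[3]
  if (length(noise_mask) != m) stop("noise_mask length must equal frame count", call. = FALSE)
  nf <- which(noise_mask)
  if (length(nf) == 0L) {
    stop("no noise-only frames; fall back to the 0.3 s edge intervals",
         call. = FALSE)
  }
  S <- array(0i, dim = c(L, L, nb))
  for (b in seq_len(nb)) {
    Xi <- matrix(X[b, nf, ], nrow = length(nf), ncol = L)
    Sb <- crossprod(Xi, Conj(Xi)) / length(nf)     # E[X X^H], L x L Hermitian
    tr <- Re(sum(diag(Sb)))
    S[, , b] <- Sb + diag(L) * (loading * max(tr, 1e-12) / L)
  }
  attr(S, "flagged") <- length(nf) < L
  S
}

#' MVDR weights for one steering vector and noise covariance
#'
#' @param v complex steering vector (length L).
#' @param Sigma L x L Hermitian noise covariance (already loaded).
#' @return complex weight vector `w` with `Conj(w) %*% v == 1`.
#' @export
mvdr_weights <- function(v, Sigma) {
  sv <- solve(Sigma, v)
  denom <- sum(Conj(v) * sv)
  as.vector(sv / Conj(denom))
}

steering_vector <- function(geometry, doa_deg, omega) {
  tau <- das_delays(geometry, doa_deg)
  exp(-1i * outer(omega, tau))                    # bins x L
}

#' MVDR beamformer
#'
#' Per-frame, per-bin minimum variance distortionless response filter:
#' `Y(m,w) = w(m,w)^H [X_1..X_L]^T` with weights from [mvdr_weights()],
#' steering built from the capture DOA (or per-frame from the DOA
#' track), and the noise covariance estimated from noise-only frames
#' (default: the 0.3 s edge intervals).
#'
#' @param capture a `dysvox_capture` or samples x channels matrix.
#' @param geometry an [array_geometry()].
#' @param doa look direction (degrees); default from the capture.
#' @param noise_mask logical over STFT frames; default marks frames
#'   fully inside the first/last `edge_s` seconds.
#' @param frame_length,overlap STFT parameters.
#' @param loading diagonal loading factor.
#' @param edge_s edge-interval duration used for the default noise mask.
#' @return mono sample vector (same length as the capture).
#' @export
mvdr_filter <- function(capture, geometry = array_geometry(), doa = NULL,
                        noise_mask = NULL, frame_length = 512,
                        overlap = 0.5, loading = 1e-3, edge_s = 0.3) {
  ch <- if (inherits(capture, "dysvox_capture")) capture$channels else capture
  track <- if (inherits(capture, "dysvox_capture")) capture$doa_track else NULL
  rate <- if (inherits(capture, "dysvox_capture")) capture$rate else 16000
  if (is.null(doa) && is.null(track)) {
    if (inherits(capture, "dysvox_capture") && !is.null(capture$doa)) {
      doa <- capture$doa
    } else {
      stop("a DOA or DOA track is required", call. = FALSE)
    }
  }
  fr <- stft(ch, rate, frame_length, overlap)
  nb <- fr$num_freq_bins
  m <- dim(fr$X)[2]
  L <- dim(fr$X)[3]
  if (L == 1L) return(ch[, 1])
  if (is.null(noise_mask)) {
    centers <- (seq_len(m) - 1L) * fr$hop + frame_length / 2
    noise_mask <- centers < edge_s * rate |
      centers > nrow(ch) - edge_s * rate
    if (!any(noise_mask)) noise_mask[c(1L, m)] <- TRUE
  }
  S <- estimate_noise_covariance(fr, noise_mask, loading)
  omega <- 2 * pi * (seq_len(nb) - 1L) * rate / fr$dft_size
  Y <- matrix(0i, nb, m)
  if (is.null(track)) {
    V <- steering_vector(geometry, doa, omega)
    for (b in seq_len(nb)) {
      w <- mvdr_weights(V[b, ], S[, , b])
      Y[b, ] <- Conj(w) %*% t(matrix(fr$X[b, , ], nrow = m))
    }
  } else {
    centers <- pmin((seq_len(m) - 1L) * fr$hop + frame_length %/% 2L,
                    length(track))
    ang <- round(track[centers])                 # 1-degree weight reuse
    for (a in unique(ang)) {
      cols <- which(ang == a)
      V <- steering_vector(geometry, a, omega)
      for (b in seq_len(nb)) {
        w <- mvdr_weights(V[b, ], S[, , b])
        Y[b, cols] <- Conj(w) %*% t(matrix(fr$X[b, cols, ], nrow = length(cols)))
      }
    }
  }
  fr$X <- Y
  istft(fr)
}

#' Edge-interval SNR estimate
#'
#' Noise power is taken as the mean power of the first and last
#' `edge_duration` seconds (assumed non-speech); signal power as the
#' noise-corrected power of the interior.
#'
#' @param x mono samples.
#' @param rate sample rate (Hz).
#' @param edge_duration edge interval length (s).
#' @return SNR in dB. When the interior power does not exceed the noise
#'   power the epsilon floor is reported with attribute
#'   `lower_bound = TRUE`.
#' @export
estimate_snr <- function(x, rate = 16000, edge_duration = 0.3) {
  ne <- round(edge_duration * rate)
  if (length(x) <= 2 * ne) stop("signal shorter than twice the edge interval", call. = FALSE)
  noise <- c(x[seq_len(ne)], x[(length(x) - ne + 1L):length(x)])
  p_n <- mean(noise^2)
  interior <- x[(ne + 1L):(length(x) - ne)]
  p_t <- mean(interior^2)
  eps <- 1e-6
  num <- p_t - p_n
  if (p_n <= 0) p_n <- .Machine$double.eps
  if (num <= eps * p_n) {
    return(structure(pow_to_db(eps), lower_bound = TRUE))
  }
  pow_to_db(num / p_n)
}
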