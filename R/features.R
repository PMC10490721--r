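# Feature front-end: F0-based time-independent features, Mel/log-spectral
# time-dependent features, whole-database mean/variance normalization and
# zero padding.
#
# Time-dependent features are computed at 8 kHz regardless of the capture
# rate (the feature design stems from telephone-bandwidth speech); the
# 50 ms analysis window is 400 samples, zero-padded to the 512-point FFT,
# giving 257 one-sided bins.

FEATURE_RATE <- 8000

#' Resample audio between integer rates
#'
#' Thin wrapper over polyphase resampling with the rational factor
#' reduced by the gcd.
#'
#' @param x mono samples.
#' @param from,to sample rates (Hz).
#' @return resampled samples.
#' @export
resample_to <- function(x, from, to) {
  if (from == to) return(x)
  g <- gcd_int(from, to)
  as.numeric(signal::resample(x, to / g, from / g))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Frames fully contained in the signal: floor((N - w)/h) + 1 frames.
frame_matrix <- function(x, w, h) {
  n <- length(x)
  if (n < w) stop("input shorter than one analysis window", call. = FALSE)
  m <- (n - w) %/% h + 1L
  starts <- (seq_len(m) - 1L) * h + 1L
  matrix(x[outer(0:(w - 1L), starts, "+")], w, m)
}

# One-sided power spectrum per frame (columns), 512-point FFT of
# Hann-windowed 50 ms frames with 50% overlap.
log_power_frames <- function(x, rate, window_s = 0.05, dft = 512) {
  w <- round(window_s * rate)
  h <- w %/% 2L
  fr <- frame_matrix(x, w, h) * hann_periodic(w)
  if (dft > w) fr <- rbind(fr, matrix(0, dft - w, ncol(fr)))
  X <- stats::mvfft(fr)[seq_len(dft %/% 2L + 1L), , drop = FALSE]
  abs(X)^2
}

#' Estimate the fundamental-frequency track
#'
#' Frame-wise normalized autocorrelation with peak picking in the 60-400
#' Hz lag range; a frame is voiced when the normalized peak exceeds the
#' threshold. Among candidate peaks within 5% of the maximum, the
#' shortest lag (highest octave) wins, which suppresses octave-down
#' errors.
#'
#' @param x mono samples.
#' @param rate sample rate (Hz).
#' @param fmin,fmax F0 search range (Hz).
#' @param frame_s,hop_s analysis frame and hop (s).
#' @param threshold voicing threshold on the normalized autocorrelation.
#' @return object of class `dysvox_f0`: data.frame with `time` (s), `f0`
#'   (Hz, NA when unvoiced), `voiced`; attribute `hop` (s).
#' @export
extract_f0 <- function(x, rate, fmin = 60, fmax = 400,
                       frame_s = 0.04, hop_s = 0.01, threshold = 0.45) {
  if (length(x) == 0L) stop("empty audio", call. = FALSE)
  w <- round(frame_s * rate)
  h <- round(hop_s * rate)
  if (length(x) < w) stop("audio shorter than one F0 frame", call. = FALSE)
  fr <- frame_matrix(x, w, h)
  fr <- fr - rep(colMeans(fr), each = w)
  nfft <- stats::nextn(2L * w, 2)
  F <- stats::mvfft(rbind(fr, matrix(0, nfft - w, ncol(fr))))
  ac <- Re(stats::mvfft(F * Conj(F), inverse = TRUE))[seq_len(w), , drop = FALSE] / nfft
  lag_min <- max(2L, floor(rate / fmax))
  lag_max <- min(w - 1L, ceiling(rate / fmin))
  m <- ncol(fr)
  f0 <- rep(NA_real_, m)
  voiced <- logical(m)
  for (j in seq_len(m)) {
    r0 <- ac[1, j]
    if (r0 <= 0) next
    seg <- ac[(lag_min + 1L):(lag_max + 1L), j] / r0
    pk <- max(seg)
    if (pk <= threshold) next
    cand <- which(seg >= 0.95 * pk)
    lag <- lag_min + cand[1] - 1L
    # parabolic interpolation around the peak
    i <- lag + 1L
    if (i > 2L && i < w) {
      y1 <- ac[i - 1L, j] / r0; y2 <- ac[i, j] / r0; y3 <- ac[i + 1L, j] / r0
      den <- y1 - 2 * y2 + y3
      if (abs(den) > 1e-12) lag <- lag + 0.5 * (y1 - y3) / den
    }
    f0[j] <- rate / lag
    voiced[j] <- TRUE
  }
  structure(data.frame(time = (seq_len(m) - 1L) * h / rate + frame_s / 2,
                       f0 = f0, voiced = voiced),
            hop = hop_s, class = c("dysvox_f0", "data.frame"))
}

#' Time-independent feature triplet
#'
#' From the F0 curve of a vocalization: the standard deviation of the
#' mean-normalized F0 over voiced frames (`f0_spread`), the mean of the
#' normalized slope over consecutive voiced-frame pairs
#' (`f0_norm_slope_mean`, the per-second F0 change divided by the mean
#' F0), and the file duration in seconds.
#'
#' @param x mono samples.
#' @param rate sample rate (Hz).
#' @param f0_track optionally a precomputed [extract_f0()] result.
#' @return named numeric vector of length 3
#'   (`f0_spread`, `f0_norm_slope_mean`, `duration`); attribute
#'   `flagged = TRUE` when fewer than 2 voiced frames were available and
#'   the F0 terms are zeroed.
#' @export
time_independent_features <- function(x, rate, f0_track = NULL) {
  dur <- length(x) / rate
  if (is.null(f0_track)) f0_track <- extract_f0(x, rate)
  v <- which(f0_track$voiced)
  if (length(v) < 2L) {
    return(structure(c(f0_spread = 0, f0_norm_slope_mean = 0,
                       duration = dur), flagged = TRUE))
  }
  f0 <- f0_track$f0[v]
  mu <- mean(f0)
  spread <- stats::sd(f0 / mu)
  adj <- which(diff(v) == 1L)             # consecutive voiced pairs only
  slope <- if (length(adj) > 0) {
    dt <- attr(f0_track, "hop")
    mean((f0_track$f0[v[adj] + 1L] - f0_track$f0[v[adj]]) / dt) / mu
  } else 0
  c(f0_spread = spread, f0_norm_slope_mean = slope, duration = dur)
}

mel_scale <- function(f) 2595 * log10(1 + f / 700)
mel_inv <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular Mel filterbank, bins x n_filters.
mel_filterbank <- function(n_filters, n_bins, rate, dft, fmax = rate / 2) {
  edges <- mel_inv(seq(0, mel_scale(fmax), length.out = n_filters + 2L))
  freqs <- (seq_len(n_bins) - 1L) * rate / dft
  fb <- matrix(0, n_bins, n_filters)
  for (k in seq_len(n_filters)) {
    lo <- edges[k]; ce <- edges[k + 1L]; hi <- edges[k + 2L]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[, k] <- pmax(0, pmin(up, dn))
  }
  fb
}

LOG_FLOOR <- 1e-10

#' Log Mel filter energies (time-dependent features for /ae-ae/, /sa-sa/)
#'
#' 14 triangular Mel filters over the one-sided 512-point power spectrum
#' of 50 ms / 50%-overlap frames at the 8 kHz feature rate.
#'
#' @param x mono samples.
#' @param rate sample rate of `x`; resampled to 8 kHz internally.
#' @return frames x 14 matrix of log filter energies.
#' @export
mel_features <- function(x, rate = FEATURE_RATE) {
  x <- resample_to(x, rate, FEATURE_RATE)
  P <- log_power_frames(x, FEATURE_RATE)
  fb <- mel_filterbank(14L, nrow(P), FEATURE_RATE, 512L)
  t(log(pmax(crossprod(fb, P), LOG_FLOOR)))
}

#' Log-spectrum + delta features (time-dependent features for counting)
#'
#' The lowest 75% of the 257 log-power bins (193, rounded up so that
#' statics plus deltas give the full 386 dimensions) concatenated with
#' their first differences (zero-prepended).
#'
#' @param x mono samples.
#' @param rate sample rate of `x`; resampled to 8 kHz internally.
#' @return frames x 386 matrix.
#' @export
counting_spectral_features <- function(x, rate = FEATURE_RATE) {
  x <- resample_to(x, rate, FEATURE_RATE)
  P <- log(pmax(log_power_frames(x, FEATURE_RATE), LOG_FLOOR))
  n_keep <- ceiling(0.75 * nrow(P))       # 193 of 257
  S <- t(P[seq_len(n_keep), , drop = FALSE])
  D <- rbind(0, diff(S))
  cbind(S, D)
}

#' Fit mean/variance normalization statistics
#'
#' @param rows matrix whose rows are observations (feature frames or
#'   time-independent vectors) from the whole fitting population.
#' @param var_floor variance floor.
#' @return object of class `dysvox_mvn`: list with `mean`, `var`,
#'   `flagged` (logical per dimension, TRUE where the variance hit the
#'   floor).
#' @export
fit_mvn <- function(rows, var_floor = 1e-8) {
  mu <- colMeans(rows)
  v <- apply(rows, 2, stats::var)
  if (nrow(rows) < 2L) v <- rep(0, ncol(rows))
  flagged <- v < var_floor
  structure(list(mean = mu, var = pmax(v, var_floor), flagged = flagged),
            class = "dysvox_mvn")
}

#' Apply (or invert) mean/variance normalization
#'
#' @param x matrix (rows = observations) or a single vector.
#' @param stats a [fit_mvn()] object.
#' @param invert if TRUE undoes the normalization.
#' @return normalized matrix/vector; flagged (constant) dimensions map
#'   to 0.
#' @export
apply_mvn <- function(x, stats, invert = FALSE) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  sdv <- sqrt(stats$var)
  out <- if (invert) {
    sweep(sweep(x, 2, sdv, "*"), 2, stats$mean, "+")
  } else {
    z <- sweep(sweep(x, 2, stats$mean, "-"), 2, sdv, "/")
    z[, stats$flagged] <- 0
    z
  }
  if (vec) drop(out) else out
}

#' Zero-pad (or truncate) a feature matrix to a fixed frame count
#'
#' @param x frames x dims matrix.
#' @param pad_length target frame count, taken from the longest training
#'   utterance of the same phonetization type.
#' @return pad_length x dims matrix; rows beyond the true length are
#'   zero. Inputs longer than `pad_length` are truncated and the result
#'   carries attribute `truncated = TRUE`.
#' @export
pad_to_length <- function(x, pad_length) {
  if (pad_length <= 0) stop("pad_length must be positive", call. = FALSE)
  m <- nrow(x)
  if (m == pad_length) return(x)
  if (m > pad_length) {
    return(structure(x[seq_len(pad_length), , drop = FALSE],
                     truncated = TRUE))
  }
  rbind(x, matrix(0, pad_length - m, ncol(x)))
}
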