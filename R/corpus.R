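# Synthetic vocalization corpus.
#
# Emulates a clinical corpus of controlled vocalizations (sustained
# /ae-ae/, /sa-sa/, and rapid 1-to-30 counting; two repetitions each)
# labelled with mMRC dyspnea classes 0-3. Severity is encoded the way
# dyspnea manifests in controlled phonation tasks: shorter phonation,
# more and longer pauses, larger intonation variability, and audible
# breath noise, all monotone in the mMRC class by construction.

PHONETIZATIONS <- c("ae", "sa", "count")

#' Per-class synthesis profile for the vocalization generator
#'
#' Returns the class-conditional parameters that drive synthesis. The
#' defaults are calibrated so that, with the default class composition
#' (34/22/22/22 subjects over mMRC 0-3), the corpus grand-mean utterance
#' duration is 12.7 s. Class 0 has the longest phonation and no breath
#' noise; class 3 the shortest phonation, the most pauses and the most
#' breath noise.
#'
#' @param duration_scale multiplier applied to every timing parameter
#'   (durations, pauses, syllable lengths). Useful for scaled-down runs;
#'   1 reproduces the calibrated corpus.
#' @param rate sample rate in Hz for the generated audio.
#' @return An object of class `dysvox_profile`: a list with per-class
#'   (length-4) vectors `duration_mean`, `duration_sd`, `pause_prob`,
#'   `pause_mean`, `f0_base`, `f0_jitter_sd`, `breath_prob`,
#'   `breath_gain_db`, plus `rate` and `duration_scale`.
#' @export
generator_profile <- function(duration_scale = 1, rate = 16000) {
  stopifnot_scalar(duration_scale)
  if (duration_scale <= 0) stop("duration_scale must be > 0", call. = FALSE)
  p <- list(
    # class-conditional utterance duration (s); weighted mean over the
    # default 34/22/22/22 composition equals 12.7 s
    duration_mean = c(15.0, 13.3, 11.65, 9.6) * duration_scale,
    duration_sd = 0.15 * c(15.0, 13.3, 11.65, 9.6) * duration_scale,
    pause_prob = c(0.05, 0.15, 0.30, 0.45),   # per syllable
    pause_mean = c(0.40, 0.40, 0.45, 0.50) * duration_scale,
    f0_base = c(120, 118, 116, 114),           # Hz
    f0_jitter_sd = c(0.010, 0.020, 0.035, 0.050),  # relative
    breath_prob = c(0.0, 0.10, 0.25, 0.40),    # per syllable boundary
    breath_gain_db = c(-22, -20, -18, -16),    # re phonation level
    edge_silence = 0.5,                        # s of non-speech per file edge
    rate = as.integer(rate),
    duration_scale = duration_scale
  )
  validate_profile(p)
  structure(p, class = "dysvox_profile")
}

validate_profile <- function(p) {
  for (f in c("pause_prob", "breath_prob")) {
    if (any(p[[f]] < 0 | p[[f]] > 1)) {
      stop(sprintf("profile$%s must lie in [0, 1]", f), call. = FALSE)
    }
  }
  if (any(p$duration_mean <= 0) || any(p$pause_mean <= 0)) {
    stop("profile durations must be positive", call. = FALSE)
  }
  if (any(diff(p$duration_mean) > 0)) {
    stop("duration_mean must be non-increasing in mMRC class", call. = FALSE)
  }
  if (any(diff(p$pause_prob) < 0)) {
    stop("pause_prob must be non-decreasing in mMRC class", call. = FALSE)
  }
  invisible(p)
}

#' Generate the subject roster
#'
#' @param n_total total number of subjects.
#' @param n_per_class integer vector of length 4: subjects in mMRC
#'   classes 0-3. Must sum to `n_total`. The default composition is 34
#'   healthy subjects (class 0) and 66 patients split over classes 1-3.
#' @param seed integer seed; the roster is deterministic given the seed.
#' @return data.frame with columns `subject_id`, `mmrc_class` (0-3),
#'   `group` ("healthy"/"patient") and `diagnosis` (metadata only;
#'   synthesis does not depend on it).
#' @export
generate_subjects <- function(n_total = 100,
                              n_per_class = c(34, 22, 22, 22),
                              seed = 1) {
  if (length(n_per_class) != 4L || any(n_per_class < 1)) {
    stop("n_per_class must be 4 counts, each >= 1", call. = FALSE)
  }
  if (sum(n_per_class) != n_total) {
    stop("sum(n_per_class) must equal n_total", call. = FALSE)
  }
  with_seed(seed, {
    classes <- sample(rep(0:3, times = n_per_class))
    ids <- sprintf("S%03d", seq_len(n_total))
    group <- ifelse(classes == 0L, "healthy", "patient")
    diagnosis <- rep(NA_character_, n_total)
    idx_pat <- which(group == "patient")
    # diagnosis subgroups carried as metadata only (roughly 43/19/4 COPD /
    # pulmonary fibrosis / post-COVID out of 66 patients)
    diagnosis[idx_pat] <- sample(
      c("COPD", "pulmonary_fibrosis", "post_COVID"),
      length(idx_pat), replace = TRUE, prob = c(43, 19, 4) / 66
    )
    data.frame(subject_id = ids, mmrc_class = as.integer(classes),
               group = group, diagnosis = diagnosis,
               stringsAsFactors = FALSE)
  })
}

# ---- segment renderers -----------------------------------------------------

# Second-order resonator (single formant) as an IIR biquad.
resonator_coefs <- function(freq, bw, rate) {
  r <- exp(-pi * bw / rate)
  theta <- 2 * pi * freq / rate
  b <- 1 - r
  a <- c(1, -2 * r * cos(theta), r^2)
  list(b = b, a = a)
}

# Harmonic glottal pulse train with slow F0 wander, shaped by a fixed
# /ae/-like three-formant cascade.
render_vowel <- function(dur, f0, jitter_sd, rate) {
  n <- max(1L, round(dur * rate))
  n_pulses <- ceiling(dur * f0 * 1.3) + 2L
  wander <- cumsum(stats::rnorm(n_pulses, 0, jitter_sd / 2))
  wander <- wander - mean(wander)
  f0_i <- f0 * (1 + pmin(pmax(stats::rnorm(n_pulses, 0, jitter_sd) + wander,
                              -0.3), 0.3))
  periods <- 1 / f0_i
  times <- cumsum(periods)
  times <- times[times < dur]
  x <- numeric(n)
  idx <- pmin(n, 1L + round(times * rate))
  x[idx] <- 1
  for (fm in list(c(660, 90), c(1720, 110), c(2410, 140))) {
    co <- resonator_coefs(fm[1], fm[2], rate)
    x <- as.numeric(signal::filter(co$b, co$a, x))
  }
  x * taper_env(n, rate)
}

# High-passed noise burst used as the /s/ fricative.
render_fricative <- function(dur, rate) {
  n <- max(1L, round(dur * rate))
  bf <- signal::butter(4, min(0.95, 3000 / (rate / 2)), type = "high")
  x <- as.numeric(signal::filter(bf, stats::rnorm(n)))
  0.15 * x / max(1e-12, stats::sd(x)) * taper_env(n, rate)
}

# Band-limited (300-1500 Hz) breath-noise burst.
render_breath <- function(dur, rate) {
  n <- max(1L, round(dur * rate))
  bf <- signal::butter(2, c(300, 1500) / (rate / 2), type = "pass")
  x <- as.numeric(signal::filter(bf, stats::rnorm(n)))
  x / max(1e-12, stats::sd(x)) * taper_env(n, rate)
}

# Raised-cosine onset/offset envelope (30 ms ramps).
taper_env <- function(n, rate) {
  ramp <- min(n %/% 2L, round(0.03 * rate))
  env <- rep(1, n)
  if (ramp > 0) {
    up <- 0.5 - 0.5 * cos(pi * seq_len(ramp) / ramp)
    env[seq_len(ramp)] <- up
    env[n + 1L - seq_len(ramp)] <- up
  }
  env
}

# ---- vocalization synthesis ------------------------------------------------

#' Synthesize one controlled vocalization
#'
#' Renders one utterance for a subject: `"ae"` is a sustained harmonic
#' vowel, `"sa"` alternates a fricative and the vowel, `"count"` produces
#' exactly 30 syllable-like vowel bursts separated by gaps. Class-dependent
#' pauses and band-limited breath-noise bursts are inserted according to
#' the profile, and every segment is recorded in an event log so that
#' structural properties can be asserted without audio analysis.
#'
#' @param subject one row of [generate_subjects()] output (data.frame or
#'   list with `subject_id` and `mmrc_class`).
#' @param phonetization one of `"ae"`, `"sa"`, `"count"`.
#' @param repetition repetition index, 1 or 2.
#' @param profile a [generator_profile()].
#' @param seed integer seed; synthesis is sample-reproducible given it.
#' @return An object of class `dysvox_vocalization`: list with `samples`,
#'   `rate`, `duration` (s), `events` (data.frame event/start/end),
#'   `subject_id`, `mmrc_class`, `phonetization`, `repetition`.
#' @export
synthesize_vocalization <- function(subject, phonetization, repetition,
                                    profile = generator_profile(),
                                    seed = 1) {
  if (!phonetization %in% PHONETIZATIONS) {
    stop("unknown phonetization: ", phonetization, call. = FALSE)
  }
  if (!repetition %in% c(1L, 2L)) stop("repetition must be 1 or 2", call. = FALSE)
  cls <- as.integer(subject$mmrc_class)
  stopifnot(cls >= 0L, cls <= 3L)
  k <- cls + 1L
  rate <- profile$rate

  with_seed(seed, {
    target <- max(0.12 * profile$duration_scale * 30 + 2 * profile$edge_silence,
                  stats::rnorm(1, profile$duration_mean[k],
                               profile$duration_sd[k]))
    f0 <- profile$f0_base[k] * exp(stats::rnorm(1, 0, 0.08))
    # non-speech intervals bracket every file (the capture convention the
    # edge-interval SNR estimator and the MVDR noise mask rely on)
    speech_target <- target - 2 * profile$edge_silence
    plan <- if (phonetization == "count") {
      plan_count(speech_target, profile, k)
    } else {
      plan_sustained(speech_target, profile, k, phonetization)
    }
    plan <- rbind(
      data.frame(event = "silence", dur = profile$edge_silence),
      plan,
      data.frame(event = "silence", dur = profile$edge_silence)
    )
    segs <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      segs[[i]] <- switch(
        plan$event[i],
        syllable = render_vowel(plan$dur[i], f0, profile$f0_jitter_sd[k], rate),
        fricative = render_fricative(plan$dur[i], rate),
        pause = numeric(max(1L, round(plan$dur[i] * rate))),
        gap = numeric(max(1L, round(plan$dur[i] * rate))),
        silence = numeric(max(1L, round(plan$dur[i] * rate))),
        breath = db_to_pow(profile$breath_gain_db[k] / 2) *
          render_breath(plan$dur[i], rate)
      )
    }
    x <- unlist(segs, use.names = FALSE)
    n_target <- round(target * rate)
    if (length(x) >= n_target) x <- x[seq_len(n_target)]
    else x <- c(x, numeric(n_target - length(x)))
    # normalize phonation level, then add a quiet mic-noise floor
    x <- 0.3 * x / max(1e-12, max(abs(x)))
    x <- x + stats::rnorm(length(x), 0, 0.3 * db_to_pow(-50 / 2))
    ends <- cumsum(plan$dur)
    events <- data.frame(event = plan$event,
                         start = c(0, ends[-length(ends)]),
                         end = ends, stringsAsFactors = FALSE)
    events <- events[events$start < target, , drop = FALSE]
    events$end <- pmin(events$end, target)
    structure(list(
      samples = x, rate = rate, duration = length(x) / rate,
      events = events, subject_id = subject$subject_id,
      mmrc_class = cls, phonetization = phonetization,
      repetition = as.integer(repetition)
    ), class = "dysvox_vocalization")
  })
}

# Fill the target duration with syllable units, inserting pauses and
# breaths with class-dependent probability after each unit.
plan_sustained <- function(target, profile, k, phonetization) {
  syl <- 0.45 * profile$duration_scale
  ev <- character(0); du <- numeric(0); t <- 0
  while (t < target) {
    if (phonetization == "sa") {
      ev <- c(ev, "fricative"); du <- c(du, 0.4 * syl)
      t <- t + 0.4 * syl
    }
    ev <- c(ev, "syllable"); du <- c(du, syl); t <- t + syl
    if (stats::runif(1) < profile$pause_prob[k]) {
      d <- stats::rexp(1, 1 / profile$pause_mean[k]) + 0.1 * profile$pause_mean[k]
      ev <- c(ev, "pause"); du <- c(du, d); t <- t + d
    }
    if (stats::runif(1) < profile$breath_prob[k]) {
      d <- 0.25 * profile$duration_scale
      ev <- c(ev, "breath"); du <- c(du, d); t <- t + d
    }
  }
  data.frame(event = ev, dur = du, stringsAsFactors = FALSE)
}

# Exactly 30 syllables; inter-syllable gap stretched so the plan fills the
# drawn target duration.
plan_count <- function(target, profile, k) {
  n_syl <- 30L
  ev <- character(0); du <- numeric(0)
  extra <- 0
  for (i in seq_len(n_syl)) {
    ev <- c(ev, "syllable"); du <- c(du, NA)  # syllable length set below
    if (i < n_syl) {
      if (stats::runif(1) < profile$pause_prob[k]) {
        d <- stats::rexp(1, 1 / profile$pause_mean[k]) + 0.1 * profile$pause_mean[k]
        ev <- c(ev, "pause"); du <- c(du, d); extra <- extra + d
      }
      if (stats::runif(1) < profile$breath_prob[k]) {
        d <- 0.25 * profile$duration_scale
        ev <- c(ev, "breath"); du <- c(du, d); extra <- extra + d
      }
      ev <- c(ev, "gap"); du <- c(du, NA)
    }
  }
  # split the remaining time 70/30 between syllables and gaps
  remaining <- max(target - extra, 0.06 * profile$duration_scale * n_syl)
  syl_d <- 0.7 * remaining / n_syl
  gap_d <- 0.3 * remaining / (n_syl - 1L)
  du[ev == "syllable"] <- syl_d
  du[ev == "gap"] <- gap_d
  ev[ev == "gap"] <- "gap"
  data.frame(event = ev, dur = du, stringsAsFactors = FALSE)
}

#' Generate the full vocalization corpus
#'
#' Produces |subjects| x 3 phonetizations x 2 repetitions vocalizations
#' (600 for the default roster) with per-file seeds derived from the
#' master seed, and a metadata table with one row per file.
#'
#' @param subjects roster from [generate_subjects()].
#' @param profile a [generator_profile()].
#' @param seed master integer seed.
#' @param out_dir if non-NULL, WAV files (`<subject>_<type>_<rep>.wav`),
#'   per-file event logs (`*.events.csv`) and `metadata.csv` are written
#'   there.
#' @param keep_audio if TRUE the returned object carries the vocalization
#'   objects in memory (`attr(meta, "vocalizations")`); off by default to
#'   bound memory for the 600-file corpus.
#' @return metadata data.frame: `subject_id`, `mmrc_class`, `group`,
#'   `phonetization`, `repetition`, `duration`, `file`, `seed`.
#' @export
generate_corpus <- function(subjects, profile = generator_profile(),
                            seed = 1, out_dir = NULL, keep_audio = FALSE) {
  if (nrow(subjects) == 0L) stop("subjects roster is empty", call. = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  grid <- expand.grid(rep = 1:2, phon = PHONETIZATIONS,
                      si = seq_len(nrow(subjects)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  meta <- vector("list", n)
  vocs <- if (keep_audio) vector("list", n) else NULL
  for (i in seq_len(n)) {
    s <- subjects[grid$si[i], ]
    fseed <- derive_seed(seed, i)
    v <- synthesize_vocalization(s, grid$phon[i], grid$rep[i], profile, fseed)
    fname <- sprintf("%s_%s_%d.wav", s$subject_id, grid$phon[i], grid$rep[i])
    if (!is.null(out_dir)) {
      write_wav(v$samples, file.path(out_dir, fname), v$rate)
      utils::write.csv(v$events,
                       file.path(out_dir, sub("\\.wav$", ".events.csv", fname)),
                       row.names = FALSE)
    }
    meta[[i]] <- data.frame(
      subject_id = s$subject_id, mmrc_class = s$mmrc_class, group = s$group,
      phonetization = grid$phon[i], repetition = grid$rep[i],
      duration = v$duration, file = fname, seed = fseed,
      stringsAsFactors = FALSE
    )
    if (keep_audio) vocs[[i]] <- v
  }
  meta <- do.call(rbind, meta)
  if (!is.null(out_dir)) {
    utils::write.csv(meta, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
  }
  if (keep_audio) attr(meta, "vocalizations") <- vocs
  meta
}

#' Re-synthesize one corpus vocalization from its metadata row
#'
#' Corpus audio is fully determined by the per-file seed stored in the
#' metadata, so utterances can be re-created on demand instead of being
#' held in memory.
#'
#' @param meta_row one row of [generate_corpus()] metadata.
#' @param profile the profile used to generate the corpus.
#' @return A `dysvox_vocalization`.
#' @export
corpus_vocalization <- function(meta_row, profile = generator_profile()) {
  synthesize_vocalization(
    list(subject_id = meta_row$subject_id, mmrc_class = meta_row$mmrc_class),
    meta_row$phonetization, meta_row$repetition, profile, meta_row$seed
  )
}

#' @export
print.dysvox_vocalization <- function(x, ...) {
  cat(sprintf("<vocalization %s /%s/ rep %d, mMRC %d, %.2f s @ %d Hz, %d events>\n",
              x$subject_id, x$phonetization, x$repetition, x$mmrc_class,
              x$duration, x$rate, nrow(x$events)))
  invisible(x)
}
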