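# End-to-end experiment driver: corpus synthesis -> acoustic simulation
# -> beamforming -> feature extraction -> fold-wise double-validation
# training -> fusion -> metrics.

#' Feature extraction front-end for one (beamformed) vocalization
#'
#' @param x mono samples.
#' @param rate sample rate (Hz).
#' @param phonetization `"ae"`, `"sa"` or `"count"` (selects the
#'   time-dependent representation).
#' @return list with `ti` (length-3 time-independent vector) and `td`
#'   (frames x 14 or frames x 386 matrix).
#' @export
extract_utterance_features <- function(x, rate, phonetization) {
  ti <- time_independent_features(x, rate)
  td <- if (phonetization == "count") {
    counting_spectral_features(x, rate)
  } else {
    mel_features(x, rate)
  }
  list(ti = ti, td = td)
}

# Incremental per-dimension mean/variance over stacked frame rows.
mvn_accumulate <- function(acc, rows) {
  if (is.null(acc)) {
    acc <- list(n = 0, s = numeric(ncol(rows)), ss = numeric(ncol(rows)))
  }
  acc$n <- acc$n + nrow(rows)
  acc$s <- acc$s + colSums(rows)
  acc$ss <- acc$ss + colSums(rows^2)
  acc
}

mvn_finalize <- function(acc, var_floor = 1e-8) {
  mu <- acc$s / acc$n
  v <- (acc$ss - acc$n * mu^2) / max(acc$n - 1, 1)
  v[v < 0] <- 0
  structure(list(mean = mu, var = pmax(v, var_floor),
                 flagged = v < var_floor),
            class = "dysvox_mvn")
}

#' Run the full severity-estimation experiment on a synthetic corpus
#'
#' Generates the corpus, applies the acoustic training augmentation
#' (random RIR condition, robot+environment noise mixture, random SNR),
#' beamforms each capture, extracts features, normalizes them over the
#' whole database, then runs `repeats` independent rounds of the
#' speaker-disjoint k-fold double-validation protocol and fuses the
#' per-classifier softmaxes into subject-level predictions.
#'
#' @param n_per_class subjects per mMRC class 0-3.
#' @param duration_scale timing scale of the generator (1 = the
#'   calibrated 12.7 s corpus).
#' @param folds,runs,repeats protocol parameters (defaults follow the
#'   published protocol: 9 folds, 8 runs, 5 repeats).
#' @param beamformer `"das"`, `"mvdr"` or `"none"` (reference channel).
#' @param feature_kinds classifier families to train; both by default.
#' @param snr_range,ratio_range augmentation draw ranges (dB).
#' @param max_epochs_td,max_epochs_ti,patience_td,patience_ti training
#'   caps per classifier family.
#' @param batch_size minibatch size.
#' @param seed master seed for the whole experiment.
#' @param verbose print progress.
#' @return object of class `dysvox_experiment`: list with `per_repeat`
#'   (one entry per outer repeat: `predictions` data.frame, `accuracy`,
#'   `auc`, `phonetization_accuracy`), `pooled` (accuracy/auc over all
#'   repeats), `provenance`, `config`.
#' @export
run_experiment <- function(n_per_class = c(34, 22, 22, 22),
                           duration_scale = 1,
                           folds = 9, runs = 8, repeats = 5,
                           beamformer = c("das", "none", "mvdr"),
                           feature_kinds = c("time_dep", "time_indep"),
                           snr_range = c(5, 15), ratio_range = c(-5, 5),
                           max_epochs_td = 20, max_epochs_ti = 300,
                           patience_td = 6, patience_ti = 50,
                           batch_size = 16, seed = 1, verbose = FALSE) {
  beamformer <- match.arg(beamformer)
  say <- function(...) if (verbose) message(sprintf(...))
  geometry <- array_geometry()
  room <- room_spec()
  profile <- generator_profile(duration_scale)

  say("generating subjects and corpus metadata")
  subjects <- generate_subjects(sum(n_per_class), n_per_class,
                                seed = derive_seed(seed, 1))
  corpus <- generate_corpus(subjects, profile, seed = derive_seed(seed, 2))

  say("building RIR grid and noise bank")
  grid <- build_rir_grid(room, geometry)
  bank <- noise_bank(seed = derive_seed(seed, 3))

  say("simulating captures and extracting features")
  handler <- function(cap, row) {
    y <- switch(beamformer,
                none = cap$channels[, 1],
                das = delay_and_sum(cap, geometry),
                mvdr = mvdr_filter(cap, geometry))
    extract_utterance_features(y, cap$rate, row$phonetization)
  }
  sim <- simulate_training_corpus(corpus, profile, grid, bank,
                                  snr_range = snr_range,
                                  ratio_range = ratio_range,
                                  seed = derive_seed(seed, 4),
                                  handler = handler)
  feats <- sim$results

  say("fitting whole-database MVN statistics")
  for (ph in PHONETIZATIONS) {
    idx <- which(corpus$phonetization == ph)
    ti_stats <- fit_mvn(do.call(rbind, lapply(feats[idx], `[[`, "ti")))
    acc <- NULL
    for (i in idx) acc <- mvn_accumulate(acc, feats[[i]]$td)
    td_stats <- mvn_finalize(acc)
    for (i in idx) {
      feats[[i]]$ti <- apply_mvn(feats[[i]]$ti, ti_stats)
      feats[[i]]$td <- apply_mvn(feats[[i]]$td, td_stats)
    }
  }

  cls_of <- subjects$mmrc_class
  names(cls_of) <- subjects$subject_id

  per_repeat <- vector("list", repeats)
  for (rep_i in seq_len(repeats)) {
    say("outer repeat %d/%d", rep_i, repeats)
    plan <- make_fold_plan(subjects, k = folds,
                           seed = derive_seed(seed, 100 + rep_i))
    # leaves[[subject]][[phonetization]][[kind]] <- list of rep softmaxes
    leaves <- stats::setNames(
      replicate(nrow(subjects), list(), simplify = FALSE),
      subjects$subject_id
    )
    for (f_i in seq_along(plan)) {
      part <- plan[[f_i]]
      for (ph in PHONETIZATIONS) {
        idx_ph <- which(corpus$phonetization == ph)
        sel <- function(ids) idx_ph[corpus$subject_id[idx_ph] %in% ids]
        i_tr <- sel(part$train); i_v1 <- sel(part$val1)
        i_v2 <- sel(part$val2); i_te <- sel(part$test)
        pad_len <- max(vapply(feats[i_tr], function(f) nrow(f$td), 0L))
        td_array <- function(ii) {
          a <- array(0, dim = c(length(ii), pad_len, ncol(feats[[ii[1]]]$td), 1L))
          for (j in seq_along(ii)) {
            a[j, , , 1] <- pad_to_length(feats[[ii[j]]]$td, pad_len)
          }
          a
        }
        ti_matrix <- function(ii) do.call(rbind, lapply(feats[ii], `[[`, "ti"))
        y_of <- function(ii) as.integer(cls_of[corpus$subject_id[ii]])
        for (fk in feature_kinds) {
          spec <- model_spec(ph, fk)
          mk <- if (fk == "time_dep") td_array else ti_matrix
          data <- list(train = list(x = mk(i_tr), y = y_of(i_tr)),
                       val1 = list(x = mk(i_v1), y = y_of(i_v1)),
                       val2 = list(x = mk(i_v2), y = y_of(i_v2)))
          trained <- train_with_double_validation(
            spec, data, runs = runs,
            patience = if (fk == "time_dep") patience_td else patience_ti,
            max_epochs = if (fk == "time_dep") max_epochs_td else max_epochs_ti,
            batch_size = batch_size,
            seed = derive_seed(seed, 1000 * rep_i + 10 * f_i +
                                 match(ph, PHONETIZATIONS))
          )
          probs <- predict_softmax(trained$model, mk(i_te))
          for (j in seq_along(i_te)) {
            sid <- corpus$subject_id[i_te[j]]
            rep_k <- corpus$repetition[i_te[j]]
            leaves[[sid]][[ph]][[fk]][[rep_k]] <- probs[j, ]
          }
        }
      }
    }
    preds <- lapply(subjects$subject_id, function(sid) {
      subject_score(leaves[[sid]], true_class = cls_of[[sid]])
    })
    predicted <- vapply(preds, `[[`, 0L, "predicted")
    truth <- subjects$mmrc_class
    phon_acc <- vapply(PHONETIZATIONS, function(ph) {
      pp <- vapply(preds, function(p) {
        if (is.null(p$per_phonetization[[ph]])) return(NA_integer_)
        which.max(p$per_phonetization[[ph]]) - 1L
      }, 0L)
      accuracy(pp, truth)
    }, 0)
    per_repeat[[rep_i]] <- list(
      predictions = data.frame(
        subject_id = subjects$subject_id, true = truth,
        predicted = predicted,
        p_dyspnea = vapply(preds, function(p) 1 - p$final[1], 0)
      ),
      accuracy = accuracy(predicted, truth),
      auc = binary_auc(lapply(preds, `[[`, "final"), truth),
      phonetization_accuracy = phon_acc
    )
    say("  repeat %d: accuracy %.1f%%, AUC %.3f", rep_i,
        per_repeat[[rep_i]]$accuracy, per_repeat[[rep_i]]$auc)
  }
  all_pred <- do.call(rbind, lapply(per_repeat, `[[`, "predictions"))
  pooled <- list(
    accuracy = accuracy(all_pred$predicted, all_pred$true),
    auc = {
      pos <- all_pred$true > 0
      r <- rank(all_pred$p_dyspnea)
      (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
        (sum(pos) * sum(!pos))
    },
    n = nrow(all_pred)
  )
  structure(list(per_repeat = per_repeat, pooled = pooled,
                 provenance = sim$provenance, subjects = subjects,
                 config = list(n_per_class = n_per_class,
                               duration_scale = duration_scale,
                               folds = folds, runs = runs,
                               repeats = repeats, beamformer = beamformer,
                               feature_kinds = feature_kinds, seed = seed)),
            class = "dysvox_experiment")
}

#' @export
print.dysvox_experiment <- function(x, ...) {
  accs <- vapply(x$per_repeat, `[[`, 0, "accuracy")
  aucs <- vapply(x$per_repeat, `[[`, 0, "auc")
  cat(sprintf(
    "<severity-estimation experiment: %d subjects, %d repeats x %d folds, %s>\n",
    nrow(x$subjects), x$config$repeats, x$config$folds, x$config$beamformer))
  cat(sprintf("  accuracy %.1f%% (per-repeat %s)\n", x$pooled$accuracy,
              paste(sprintf("%.1f", accs), collapse = "/")))
  cat(sprintf("  binary AUC %.3f (per-repeat %s)\n", x$pooled$auc,
              paste(sprintf("%.2f", aucs), collapse = "/")))
  invisible(x)
}
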