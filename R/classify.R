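# Per-phonetization classifiers and the speaker-disjoint 9-fold
# double-validation training protocol.
#
# Time-independent features feed multilayer perceptrons whose layouts and
# learning rates follow the published system (/ae-ae/: 2x40, lr 0.01;
# /sa-sa/: 2x20, lr 0.01; counting: 5x10, lr 0.001). Time-dependent
# features feed small convolutional networks (two 3x3 conv blocks with
# 2x2 max-pooling, global average pooling over time and frequency, one
# dense layer); learning rates 5e-4 (/ae-ae/, /sa-sa/) and 1e-4
# (counting).

N_CLASSES <- 4L

#' Classifier specification for one phonetization / feature kind
#'
#' @param phonetization `"ae"`, `"sa"` or `"count"`.
#' @param feature_kind `"time_indep"` (3-dimensional vectors, MLP) or
#'   `"time_dep"` (frames x dims matrices, CNN).
#' @param hidden override the hidden layout (MLP widths, or conv filter
#'   counts for the CNN).
#' @param learning_rate override the learning rate.
#' @param dense_width width of the dense layer after global pooling
#'   (CNN only).
#' @return object of class `dysvox_model_spec`.
#' @export
model_spec <- function(phonetization, feature_kind = c("time_indep", "time_dep"),
                       hidden = NULL, learning_rate = NULL,
                       dense_width = 32L) {
  feature_kind <- match.arg(feature_kind)
  if (!phonetization %in% PHONETIZATIONS) {
    stop("unknown phonetization: ", phonetization, call. = FALSE)
  }
  if (feature_kind == "time_indep") {
    def <- switch(phonetization,
                  ae = list(hidden = c(40L, 40L), lr = 0.01),
                  sa = list(hidden = c(20L, 20L), lr = 0.01),
                  count = list(hidden = rep(10L, 5L), lr = 0.001))
  } else {
    # counting spectra (386 dims at the 40 ms feature frame rate) are
    # average-pool decimated by 2x along time and 4x along frequency
    # before the conv blocks; Mel inputs (14 dims) are used as-is
    def <- switch(phonetization,
                  ae = list(hidden = c(8L, 16L), lr = 5e-4, fpool = c(1L, 1L)),
                  sa = list(hidden = c(8L, 16L), lr = 5e-4, fpool = c(1L, 1L)),
                  count = list(hidden = 8L, lr = 1e-4,
                               fpool = c(2L, 4L)))
  }
  if (is.null(hidden)) hidden <- def$hidden
  if (is.null(learning_rate)) learning_rate <- def$lr
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  structure(list(phonetization = phonetization, feature_kind = feature_kind,
                 hidden = as.integer(hidden), learning_rate = learning_rate,
                 dense_width = as.integer(dense_width),
                 decimate = if (feature_kind == "time_dep") def$fpool else c(1L, 1L),
                 n_classes = N_CLASSES),
            class = "dysvox_model_spec")
}

#' Build an untrained classifier from a specification
#'
#' MLPs take a 3-dimensional input; CNNs take `N x frames x dims x 1`
#' arrays of any spatial size compatible with two conv/pool blocks.
#' Hidden activations are ReLU; the head is a 4-way softmax.
#'
#' @param spec a [model_spec()].
#' @param input_dim input dimensionality (MLP only; default 3).
#' @param seed integer seed for weight initialization.
#' @return object of class `dysvox_model`.
#' @export
build_model <- function(spec, input_dim = 3L, seed = 1) {
  with_seed(seed, {
    layers <- list()
    if (spec$feature_kind == "time_indep") {
      d <- input_dim
      for (hwidth in spec$hidden) {
        layers <- c(layers, list(nn_layer_dense(d, hwidth), nn_layer_relu()))
        d <- hwidth
      }
      layers <- c(layers, list(nn_layer_dense(d, spec$n_classes)))
    } else {
      if (!is.null(spec$decimate) && any(spec$decimate > 1L)) {
        layers <- c(layers, list(nn_layer_fpool(spec$decimate[1], spec$decimate[2])))
      }
      c_in <- 1L
      for (nf in spec$hidden) {
        layers <- c(layers, list(nn_layer_conv(c_in, nf), nn_layer_relu(),
                                 nn_layer_pool()))
        c_in <- nf
      }
      layers <- c(layers, list(
        nn_layer_gap(),
        nn_layer_dense(c_in, spec$dense_width), nn_layer_relu(),
        nn_layer_dense(spec$dense_width, spec$n_classes)
      ))
    }
    structure(list(layers = layers, spec = spec), class = "dysvox_model")
  })
}

#' Class-probability (softmax) predictions
#'
#' @param model a (trained) `dysvox_model`.
#' @param x N x 3 matrix (MLP) or N x frames x dims x 1 array (CNN); a
#'   single vector/matrix observation is promoted to a batch of one.
#' @return N x 4 matrix of class probabilities (rows on the simplex).
#' @export
predict_softmax <- function(model, x) {
  spec <- model$spec
  if (spec$feature_kind == "time_indep") {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    if (ncol(x) != dim(model$layers[[1]]$W)[1]) {
      stop("input dimension mismatch", call. = FALSE)
    }
  } else {
    if (length(dim(x)) == 2L) {
      x <- array(x, dim = c(1L, dim(x), 1L))
    }
    if (length(dim(x)) != 4L) stop("expected a 4-d array input", call. = FALSE)
  }
  softmax_rows(nn_forward(model, x)$out)
}

#' Speaker-disjoint k-fold partition plan with double validation
#'
#' Splits subjects into k test groups of as-equal-as-possible size (for
#' 100 subjects and k = 9: eight groups of 11 and one of 12); within each
#' partition the remaining subjects are split 70/15/15 into training,
#' validation-1 and validation-2, stratified by mMRC class where counts
#' allow. All four subsets are subject-disjoint by construction.
#'
#' @param subjects roster from [generate_subjects()] (or any data.frame
#'   with `subject_id` and `mmrc_class`).
#' @param k number of folds.
#' @param seed integer seed.
#' @param split train/val1/val2 fractions of the non-test subjects.
#' @return object of class `dysvox_fold_plan`: list of k partitions,
#'   each with character vectors `test`, `train`, `val1`, `val2`.
#' @export
make_fold_plan <- function(subjects, k = 9, seed = 1,
                           split = c(0.7, 0.15, 0.15)) {
  n <- nrow(subjects)
  if (n < k) stop("need at least k subjects", call. = FALSE)
  stopifnot(abs(sum(split) - 1) < 1e-9)
  with_seed(seed, {
    ord <- sample.int(n)
    ids <- subjects$subject_id[ord]
    cls <- subjects$mmrc_class[ord]
    base <- n %/% k
    sizes <- rep(base, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- base + 1L
    stops <- cumsum(sizes)
    starts <- c(1L, stops[-k] + 1L)
    plan <- vector("list", k)
    for (i in seq_len(k)) {
      test_idx <- starts[i]:stops[i]
      rest <- setdiff(seq_len(n), test_idx)
      tr <- v1 <- v2 <- character(0)
      for (cc in sort(unique(cls[rest]))) {
        pool <- rest[cls[rest] == cc]
        pool <- pool[sample.int(length(pool))]
        nc <- length(pool)
        n_tr <- round(split[1] * nc)
        n_v1 <- round(split[2] * nc)
        n_v1 <- min(n_v1, nc - n_tr)
        tr <- c(tr, ids[pool[seq_len(n_tr)]])
        if (n_v1 > 0) v1 <- c(v1, ids[pool[n_tr + seq_len(n_v1)]])
        if (nc > n_tr + n_v1) v2 <- c(v2, ids[pool[(n_tr + n_v1 + 1L):nc]])
      }
      if (length(tr) == 0L || length(v1) == 0L || length(v2) == 0L) {
        warning("class counts too small for a stratified split; ",
                "falling back to an unstratified 70/15/15 split")
        pool <- rest[sample.int(length(rest))]
        nr <- length(pool)
        n_tr <- max(1L, round(split[1] * nr))
        n_v1 <- max(1L, round(split[2] * nr))
        tr <- ids[pool[seq_len(n_tr)]]
        v1 <- ids[pool[n_tr + seq_len(min(n_v1, nr - n_tr))]]
        v2 <- if (nr > n_tr + n_v1) ids[pool[(n_tr + n_v1 + 1L):nr]] else character(0)
      }
      plan[[i]] <- list(test = ids[test_idx], train = tr, val1 = v1, val2 = v2)
    }
    structure(plan, class = "dysvox_fold_plan")
  })
}

#' Train one classifier with the double-validation protocol
#'
#' Runs `runs` independently initialized trainings; each stops early when
#' validation-1 accuracy has not improved for `patience` epochs, keeping
#' the best-epoch weights. The winner is the run with the highest mean of
#' validation-1 and validation-2 accuracy (ties broken by lower
#' validation-1 loss).
#'
#' @param spec a [model_spec()].
#' @param data list with elements `train`, `val1`, `val2`, each a list
#'   with `x` (matrix/array) and `y` (integer labels 0-3).
#' @param runs number of training repetitions.
#' @param patience early-stopping patience (epochs).
#' @param max_epochs epoch cap per run.
#' @param batch_size minibatch size.
#' @param seed integer seed; run r uses a seed derived from it.
#' @return object of class `dysvox_trained`: list with `model` (winning
#'   `dysvox_model`), `log` (per-run data.frame), `winner` (run index).
#' @export
train_with_double_validation <- function(spec, data, runs = 8, patience = 20,
                                         max_epochs = 200, batch_size = 16,
                                         seed = 1) {
  for (part in c("train", "val1", "val2")) {
    nx <- if (is.matrix(data[[part]]$x)) nrow(data[[part]]$x) else dim(data[[part]]$x)[1]
    if (is.null(nx) || nx == 0L) {
      stop("empty subset: ", part, call. = FALSE)
    }
  }
  # the leading frequency-pool layer is deterministic: apply it to the
  # data once instead of inside every forward pass, and re-attach it to
  # the winning model afterwards
  fp <- if (spec$feature_kind == "time_dep" && !is.null(spec$decimate)) {
    spec$decimate
  } else c(1L, 1L)
  train_spec <- spec
  if (any(fp > 1L)) {
    fpl <- nn_layer_fpool(fp[1], fp[2])
    for (part in c("train", "val1", "val2")) {
      data[[part]]$x <- nn_forward_layer(fpl, data[[part]]$x)$out
    }
    train_spec$decimate <- c(1L, 1L)
  }
  input_dim <- if (is.matrix(data$train$x)) ncol(data$train$x) else 3L
  results <- vector("list", runs)
  for (r in seq_len(runs)) {
    rs <- derive_seed(seed, r)
    model0 <- build_model(train_spec, input_dim = input_dim, seed = rs)
    res <- with_seed(rs + 1L, nn_train_run(
      model0, data$train$x, data$train$y, data$val1$x, data$val1$y,
      lr = spec$learning_rate, batch_size = batch_size,
      max_epochs = max_epochs, patience = patience
    ))
    res$val2_acc <- nn_accuracy(res$model, data$val2$x, data$val2$y)
    res$val1_loss <- nn_loss(res$model, data$val1$x, data$val1$y)
    results[[r]] <- res
  }
  log <- data.frame(
    run = seq_len(runs),
    epochs = vapply(results, `[[`, 0, "epochs"),
    best_epoch = vapply(results, `[[`, 0L, "best_epoch"),
    val1_acc = vapply(results, `[[`, 0, "val1_acc"),
    val2_acc = vapply(results, `[[`, 0, "val2_acc"),
    val1_loss = vapply(results, `[[`, 0, "val1_loss")
  )
  score <- (log$val1_acc + log$val2_acc) / 2
  best <- which(score == max(score))
  winner <- best[which.min(log$val1_loss[best])]
  model <- results[[winner]]$model
  if (any(fp > 1L)) {
    model$layers <- c(list(nn_layer_fpool(fp[1], fp[2])), model$layers)
    model$spec <- spec
  }
  structure(list(model = model, log = log, winner = winner),
            class = "dysvox_trained")
}

#' @export
print.dysvox_trained <- function(x, ...) {
  cat(sprintf("<trained %s/%s classifier: run %d of %d, val acc %.2f/%.2f>\n",
              x$model$spec$phonetization, x$model$spec$feature_kind,
              x$winner, nrow(x$log), x$log$val1_acc[x$winner],
              x$log$val2_acc[x$winner]))
  invisible(x)
}
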