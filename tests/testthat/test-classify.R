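test_that("fold plan reproduces the published partition sizes", {
  subs <- generate_subjects(seed = 21)
  plan <- make_fold_plan(subs, k = 9, seed = 22)
  sizes <- sort(vapply(plan, function(p) length(p$test), 0L))
  expect_equal(sizes, c(rep(11L, 8), 12L))
  # test sets partition the roster
  all_test <- unlist(lapply(plan, `[[`, "test"))
  expect_setequal(all_test, subs$subject_id)
  expect_equal(anyDuplicated(all_test), 0L)
  # subject-disjointness of the four subsets within every partition
  for (p in plan) {
    expect_equal(anyDuplicated(c(p$test, p$train, p$val1, p$val2)), 0L)
    expect_setequal(c(p$test, p$train, p$val1, p$val2), subs$subject_id)
  }
  # determinism
  expect_identical(plan, make_fold_plan(subs, k = 9, seed = 22))
})

test_that("leave-one-subject-out degenerate plan works", {
  subs <- generate_subjects(12, c(3, 3, 3, 3), seed = 23)
  w <- capture_warnings(plan <- make_fold_plan(subs, k = 12, seed = 1))
  expect_true(any(grepl("stratified", w)))
  expect_length(plan, 12)
  expect_true(all(vapply(plan, function(p) length(p$test), 0L) == 1L))
})

test_that("model specs follow the published MLP layouts", {
  expect_equal(model_spec("ae", "time_indep")$hidden, c(40L, 40L))
  expect_equal(model_spec("ae", "time_indep")$learning_rate, 0.01)
  expect_equal(model_spec("sa", "time_indep")$hidden, c(20L, 20L))
  expect_equal(model_spec("count", "time_indep")$hidden, rep(10L, 5L))
  expect_equal(model_spec("count", "time_indep")$learning_rate, 0.001)
  expect_equal(model_spec("ae", "time_dep")$learning_rate, 5e-4)
  expect_equal(model_spec("count", "time_dep")$learning_rate, 1e-4)
  expect_error(model_spec("hum"), "phonetization")
  expect_error(model_spec("ae", learning_rate = -1), "learning_rate")
  # parameter shapes match the declared layout exactly
  m <- build_model(model_spec("ae", "time_indep"), seed = 1)
  dims <- lapply(Filter(function(l) !is.null(l$W), m$layers),
                 function(l) dim(l$W))
  expect_equal(dims, list(c(3L, 40L), c(40L, 40L), c(40L, 4L)))
})

test_that("softmax outputs live on the simplex and are deterministic", {
  m <- build_model(model_spec("sa", "time_indep"), seed = 2)
  x <- matrix(stats::rnorm(15), 5, 3)
  p <- predict_softmax(m, x)
  expect_equal(dim(p), c(5L, 4L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_identical(p, predict_softmax(m, x))
  # zeroed final layer: exactly uniform
  m0 <- m
  last <- length(m0$layers)
  m0$layers[[last]]$W[] <- 0
  m0$layers[[last]]$b[] <- 0
  expect_equal(predict_softmax(m0, x), matrix(0.25, 5, 4), tolerance = 1e-12)
  expect_error(predict_softmax(m, matrix(1, 2, 5)), "dimension")
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(3)
  for (kind in c("mlp", "cnn")) {
    if (kind == "mlp") {
      m <- build_model(model_spec("count", "time_indep"), seed = 4)
      x <- matrix(stats::rnorm(12), 4, 3)
      y <- c(0L, 1L, 2L, 3L)
    } else {
      m <- build_model(model_spec("count", "time_dep",
                                  hidden = c(2L, 3L), dense_width = 4L),
                       seed = 4)
      x <- array(stats::rnorm(2 * 48 * 40), dim = c(2, 48, 40, 1))
      y <- c(1L, 3L)
    }
    fw <- dysvox:::nn_forward(m, x, with_cache = TRUE)
    l <- dysvox:::softmax_xent(fw$out, y)
    gr <- dysvox:::nn_backward(m, fw$caches, l$dz)
    eps <- 1e-5
    for (i in seq_along(m$layers)) {
      if (is.null(m$layers[[i]]$W)) next
      for (j in sample(length(m$layers[[i]]$W),
                       min(5L, length(m$layers[[i]]$W)))) {
        up <- m; up$layers[[i]]$W[j] <- up$layers[[i]]$W[j] + eps
        dn <- m; dn$layers[[i]]$W[j] <- dn$layers[[i]]$W[j] - eps
        num <- (dysvox:::softmax_xent(dysvox:::nn_forward(up, x)$out, y)$loss -
                dysvox:::softmax_xent(dysvox:::nn_forward(dn, x)$out, y)$loss) /
          (2 * eps)
        expect_lt(abs(num - gr[[i]]$W[j]) / max(1e-6, abs(num)), 1e-4)
      }
    }
  }
})

test_that("double-validation training solves separable data and is reproducible", {
  set.seed(5)
  n <- 120
  y <- sample(0:3, n, replace = TRUE)
  x <- matrix(stats::rnorm(n * 3, 0, 0.05), n, 3)
  x[, 2] <- x[, 2] + y
  data <- list(train = list(x = x[1:80, ], y = y[1:80]),
               val1 = list(x = x[81:100, ], y = y[81:100]),
               val2 = list(x = x[101:120, ], y = y[101:120]))
  tr <- train_with_double_validation(model_spec("ae", "time_indep"), data,
                                     runs = 2, patience = 15,
                                     max_epochs = 120, seed = 6)
  expect_equal(tr$log$val1_acc[tr$winner], 1)
  expect_equal(nrow(tr$log), 2)
  # winner has the best mean validation accuracy
  score <- (tr$log$val1_acc + tr$log$val2_acc) / 2
  expect_equal(score[tr$winner], max(score))
  # reproducibility: identical seed, identical winner and metrics
  tr2 <- train_with_double_validation(model_spec("ae", "time_indep"), data,
                                      runs = 2, patience = 15,
                                      max_epochs = 120, seed = 6)
  expect_identical(tr$winner, tr2$winner)
  expect_identical(tr$log, tr2$log)
  expect_error(
    train_with_double_validation(model_spec("ae", "time_indep"),
                                 list(train = data$train,
                                      val1 = list(x = matrix(0, 0, 3),
                                                  y = integer(0)),
                                      val2 = data$val2)),
    "empty")
})

test_that("degenerate protocol (one run, zero patience) stops at first plateau", {
  set.seed(7)
  x <- matrix(stats::rnorm(60), 20, 3)
  y <- sample(0:3, 20, replace = TRUE)
  data <- list(train = list(x = x, y = y),
               val1 = list(x = x, y = y), val2 = list(x = x, y = y))
  tr <- train_with_double_validation(model_spec("sa", "time_indep"), data,
                                     runs = 1, patience = 0,
                                     max_epochs = 50, seed = 8)
  expect_equal(nrow(tr$log), 1)
  # stopped as soon as val1 accuracy failed to improve
  expect_lte(tr$log$epochs, 50)
})
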