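test_that("combination rules satisfy their algebraic identities", {
  onehot <- c(0, 0, 1, 0)
  for (r in c("mean", "median", "min", "max", "product")) {
    expect_equal(combine_rule(list(onehot, onehot, onehot), r), onehot)
  }
  # hand-computed product-rule oracle
  got <- combine_rule(list(c(0.7, 0.1, 0.1, 0.1), c(0.4, 0.3, 0.2, 0.1)),
                      "product")
  raw <- c(0.28, 0.03, 0.02, 0.01)
  expect_equal(got, raw / sum(raw), tolerance = 1e-12)
  # two-vector mean equals the elementwise median
  a <- c(0.5, 0.2, 0.2, 0.1); b <- c(0.1, 0.4, 0.3, 0.2)
  expect_equal(combine_rule(list(a, b), "mean"),
               combine_rule(list(a, b), "median"))
  # every rule returns a simplex vector
  set.seed(1)
  for (i in 1:10) {
    vs <- lapply(1:3, function(j) { v <- stats::runif(4); v / sum(v) })
    for (r in c("mean", "median", "min", "max", "product")) {
      out <- combine_rule(vs, r)
      expect_true(all(out >= 0) && abs(sum(out) - 1) < 1e-9)
    }
  }
  expect_error(combine_rule(list()), "no softmax")
})

test_that("five-rule fusion is symmetric and matches brute force", {
  a <- c(0.5, 0.2, 0.2, 0.1)
  b <- c(0.1, 0.4, 0.3, 0.2)
  got <- five_rule_fuse(list(a, b))
  # independent brute-force recomputation of all five rules + average
  M <- rbind(a, b)
  renorm <- function(v) v / sum(v)
  brute <- (renorm(colMeans(M)) + renorm(apply(M, 2, stats::median)) +
            renorm(pmin(a, b)) + renorm(pmax(a, b)) + renorm(a * b)) / 5
  expect_equal(got, brute, tolerance = 1e-12)
  expect_equal(five_rule_fuse(list(b, a)), got)
  onehot <- c(1, 0, 0, 0)
  expect_equal(five_rule_fuse(list(onehot, onehot)), onehot)
})

test_that("subject hierarchy fuses unanimity, ablations and full trees", {
  onehot2 <- c(0, 0, 1, 0)
  leaves <- list()
  for (ph in c("ae", "sa", "count")) {
    leaves[[ph]] <- list(time_dep = list(onehot2, onehot2),
                         time_indep = list(onehot2, onehot2))
  }
  s <- subject_score(leaves, true_class = 2L)
  expect_equal(s$predicted, 2L)
  expect_equal(s$final, onehot2)
  # time-dependent-only ablation still yields a prediction
  abl <- lapply(leaves, function(p) p["time_dep"])
  expect_equal(subject_score(abl)$predicted, 2L)
  # explicit 12-leaf fixture equals brute-force tree evaluation
  set.seed(2)
  rnd <- function() { v <- stats::runif(4); v / sum(v) }
  lv <- list()
  for (ph in c("ae", "sa", "count")) {
    lv[[ph]] <- list(time_dep = list(rnd(), rnd()),
                     time_indep = list(rnd(), rnd()))
  }
  got <- subject_score(lv)
  brute_phon <- lapply(lv, function(p) {
    (five_rule_fuse(p$time_dep) + five_rule_fuse(p$time_indep)) / 2
  })
  brute_final <- five_rule_fuse(unname(brute_phon))
  expect_equal(got$final, brute_final, tolerance = 1e-12)
  # permuting phonetization order leaves the final vector unchanged
  got_perm <- subject_score(lv[c("count", "ae", "sa")])
  expect_equal(got_perm$final, got$final)
  # argmax ties break toward the healthier class
  tie <- c(0.4, 0.4, 0.1, 0.1)
  expect_equal(subject_score(list(ae = list(time_indep = list(tie))))$predicted,
               0L)
  expect_error(subject_score(list()), "leaf")
})

test_that("accuracy computes percentages over 4 classes", {
  expect_equal(accuracy(c(0, 1, 2, 3), c(0, 1, 2, 3)), 100)
  expect_equal(accuracy(c(0, 1, 2, 0), c(0, 1, 2, 3)), 75)
  # label-independent predictions on balanced classes sit near chance
  set.seed(3)
  truth <- rep(0:3, each = 250)
  pred <- sample(truth)
  expect_lt(abs(accuracy(pred, truth) - 25), 5)
  expect_error(accuracy(integer(0), integer(0)), "no predictions")
})

test_that("binary AUC equals exhaustive pair counting", {
  softmax_from_p0 <- function(p0) c(p0, rep((1 - p0) / 3, 3))
  # perfect separation and all-ties
  perf <- lapply(c(0.9, 0.8, 0.2, 0.1), softmax_from_p0)
  expect_equal(binary_auc(perf, c(0, 0, 1, 2)), 1)
  ties <- lapply(rep(0.5, 4), softmax_from_p0)
  expect_equal(binary_auc(ties, c(0, 0, 1, 3)), 0.5)
  # 6-subject toy list vs brute force over all (healthy, dyspnea) pairs
  p0s <- c(0.7, 0.55, 0.6, 0.4, 0.55, 0.2)
  cls <- c(0, 0, 0, 1, 2, 3)
  sm <- lapply(p0s, softmax_from_p0)
  got <- binary_auc(sm, cls)
  scores <- 1 - p0s
  brute <- mean(outer(scores[cls > 0], scores[cls == 0],
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(got, brute)
  # the score definition 1 - P(0) coincides with P(1)+P(2)+P(3)
  v <- c(0.25, 0.3, 0.25, 0.2)
  expect_equal(1 - v[1], sum(v[2:4]))
  expect_error(binary_auc(sm, rep(1, 6)), "non-empty")
})
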