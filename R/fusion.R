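# Softmax fusion hierarchy and evaluation metrics.
#
# The currency of the hierarchy is the 4-dimensional softmax vector over
# mMRC classes 0-3. Per (phonetization, feature kind) the two repetition
# softmaxes are fused with five rules (mean, median, min, max, product)
# whose outputs are averaged; per phonetization the two feature-kind
# softmaxes are averaged; across the three phonetizations the five-rule
# fusion is applied again and the final argmax gives the estimated mMRC
# score.

FUSION_RULES <- c("mean", "median", "min", "max", "product")

assert_softmax <- function(v) {
  if (length(v) != N_CLASSES || any(v < -1e-9) || abs(sum(v) - 1) > 1e-6) {
    stop("not a valid 4-class softmax vector", call. = FALSE)
  }
  invisible(v)
}

#' Combine softmax vectors with one fusion rule
#'
#' Element-wise mean, median, min, max or product, renormalized to the
#' probability simplex (min/max/product do not preserve the sum).
#'
#' @param vectors list of numeric length-4 softmax vectors.
#' @param rule one of `"mean"`, `"median"`, `"min"`, `"max"`,
#'   `"product"`.
#' @return a length-4 softmax vector.
#' @export
combine_rule <- function(vectors, rule = FUSION_RULES) {
  rule <- match.arg(rule)
  if (length(vectors) == 0L) stop("no softmax vectors to combine", call. = FALSE)
  M <- do.call(rbind, vectors)
  out <- switch(rule,
    mean = colMeans(M),
    median = apply(M, 2, stats::median),
    min = apply(M, 2, min),
    max = apply(M, 2, max),
    product = apply(M, 2, prod)
  )
  s <- sum(out)
  if (s <= 0) return(rep(1 / N_CLASSES, N_CLASSES))
  out / s
}

#' Five-rule softmax fusion
#'
#' Applies all five combination rules and averages their outputs.
#'
#' @param vectors list of length-4 softmax vectors.
#' @return a length-4 softmax vector.
#' @export
five_rule_fuse <- function(vectors) {
  outs <- lapply(FUSION_RULES, function(r) combine_rule(vectors, r))
  colMeans(do.call(rbind, outs))
}

#' Subject-level prediction through the fusion hierarchy
#'
#' Input leaves are softmax vectors indexed by phonetization, feature
#' kind and repetition. Level 1 fuses the repetitions per
#' (phonetization, feature kind) with the five rules; level 2 averages
#' the feature-kind softmaxes per phonetization; level 3 fuses across
#' phonetizations with the five rules. Argmax of the final softmax gives
#' the predicted class (ties broken toward the lower class).
#'
#' @param leaves nested list: `leaves[[phonetization]][[feature_kind]]`
#'   is a list of per-repetition softmax vectors. Missing feature kinds
#'   or phonetizations are skipped (ablation runs); at least one leaf is
#'   required.
#' @param true_class optional true mMRC class (0-3).
#' @return object of class `dysvox_prediction`: list with `final`
#'   (softmax), `predicted` (0-3), `per_phonetization` (list of level-2
#'   softmaxes), `per_leaf`, `true_class`.
#' @export
subject_score <- function(leaves, true_class = NA_integer_) {
  phon_scores <- list()
  per_leaf <- list()
  for (ph in names(leaves)) {
    kind_scores <- list()
    for (fk in names(leaves[[ph]])) {
      reps <- leaves[[ph]][[fk]]
      if (length(reps) == 0L) next
      lapply(reps, assert_softmax)
      fused <- five_rule_fuse(reps)
      kind_scores[[fk]] <- fused
      per_leaf[[paste(ph, fk, sep = ".")]] <- fused
    }
    if (length(kind_scores) == 0L) next
    phon_scores[[ph]] <- colMeans(do.call(rbind, kind_scores))
  }
  if (length(phon_scores) == 0L) stop("no leaf softmaxes provided", call. = FALSE)
  final <- five_rule_fuse(unname(phon_scores))
  predicted <- which.max(final) - 1L       # which.max takes the first max
  structure(list(final = final, predicted = predicted,
                 per_phonetization = phon_scores, per_leaf = per_leaf,
                 true_class = true_class),
            class = "dysvox_prediction")
}

#' Multiclass accuracy (percent)
#'
#' @param predicted,truth integer class vectors (0-3).
#' @return accuracy in percent.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0L) stop("no predictions", call. = FALSE)
  if (length(predicted) != length(truth)) stop("length mismatch", call. = FALSE)
  100 * mean(predicted == truth)
}

#' Binary healthy-vs-dyspnea AUC
#'
#' The binary score of a subject is the predicted probability of any
#' dyspnea, `1 - P(class 0)`; the positive group is mMRC 1-3. AUC is
#' computed by the rank-sum (Mann-Whitney) formulation with midranks for
#' ties.
#'
#' @param final_softmaxes list (or matrix rows) of final softmax
#'   vectors.
#' @param true_classes integer vector of true classes (0-3).
#' @return AUC in \[0, 1\].
#' @export
binary_auc <- function(final_softmaxes, true_classes) {
  if (is.list(final_softmaxes)) {
    final_softmaxes <- do.call(rbind, final_softmaxes)
  }
  scores <- 1 - final_softmaxes[, 1]
  pos <- true_classes > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both the healthy and the dyspnea group must be non-empty",
         call. = FALSE)
  }
  r <- rank(scores)                        # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
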