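# Evaluation: segmentation error metrics (ME, RAE), the 3-class confusion
# matrix, binary screening diagnostics with exact CIs, and rater agreement.

as_mask_matrix <- function(x) {
  if (inherits(x, "cortical_mask")) x$pixels else x
}

#' Misclassification error between two masks
#'
#' `ME = 1 - (|B_gt ∩ B_pred| + |F_gt ∩ F_pred|) / N`, the fraction of
#' pixels whose foreground/background assignment disagrees with ground
#' truth. 0 for identical masks, 1 for complementary masks; symmetric.
#'
#' @param gt,pred ground truth and predicted [cortical_mask]s (or 0/1
#'   matrices) of equal shape.
#' @return Real in `[0, 1]`.
#' @export
misclassification_error <- function(gt, pred) {
  g <- as_mask_matrix(gt); p <- as_mask_matrix(pred)
  if (!identical(dim(g), dim(p))) stop("mask shapes differ")
  1 - sum((g > 0) == (p > 0)) / length(g)
}

#' Relative foreground area error between two masks
#'
#' With ground-truth foreground area `A_g` and predicted area `A_p`:
#' `RAE = (A_g - A_p) / A_g` when `A_p < A_g`, else `(A_p - A_g) / A_p`;
#' always in `[0, 1]`.
#'
#' @inheritParams misclassification_error
#' @return Real in `[0, 1]`.
#' @export
relative_foreground_area_error <- function(gt, pred) {
  g <- as_mask_matrix(gt); p <- as_mask_matrix(pred)
  if (!identical(dim(g), dim(p))) stop("mask shapes differ")
  ag <- sum(g > 0); ap <- sum(p > 0)
  if (ag == 0) stop("ground truth has empty foreground: RAE undefined")
  if (ap < ag) (ag - ap) / ag else (ap - ag) / ap
}

#' Three-class confusion matrix
#'
#' Rows are actual classes, columns predicted, in the fixed order
#' normal, osteopenia, osteoporosis.
#'
#' @param actual,predicted vectors of class labels (character or factor).
#' @return Integer 3x3 matrix of class `confusion_matrix3`.
#' @export
confusion_matrix <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("label vectors differ in length")
  if (length(actual) == 0L) stop("empty label vectors")
  a <- factor(as.character(actual), levels = VALID_LABELS)
  p <- factor(as.character(predicted), levels = VALID_LABELS)
  if (anyNA(a) || anyNA(p)) stop("unknown class label")
  cm <- table(actual = a, predicted = p)
  structure(matrix(as.integer(cm), 3L, 3L,
                   dimnames = list(actual = VALID_LABELS,
                                   predicted = VALID_LABELS)),
            class = c("confusion_matrix3", "matrix"))
}

#' Binary screening diagnostics from a 3-class confusion matrix
#'
#' Collapses the matrix to positive vs negative (default positive = low
#' bone density, i.e. osteopenia plus osteoporosis) and reports
#' sensitivity, specificity, accuracy, likelihood ratios
#' (`LR+ = sens/(1-spec)`, `LR- = (1-sens)/spec`), and exact
#' Clopper-Pearson 95% confidence intervals for sensitivity and
#' specificity. Ratios whose denominator is zero are reported as `NA`.
#'
#' @param cm a `confusion_matrix3` (or plain 3x3 matrix in canonical order).
#' @param positive character vector of positive classes, a proper non-empty
#'   subset of the three.
#' @return List with `sensitivity`, `specificity`, `accuracy`, `lr_pos`,
#'   `lr_neg`, `tp`, `fp`, `tn`, `fn`, `sens_ci`, `spec_ci`.
#' @export
binary_diagnostics <- function(cm, positive = c("osteopenia", "osteoporosis")) {
  if (!all(positive %in% VALID_LABELS) || length(positive) == 0L ||
      length(positive) >= 3L)
    stop("`positive` must be a non-empty proper subset of the three classes")
  pos <- VALID_LABELS %in% positive
  tp <- sum(cm[pos, pos]); fn <- sum(cm[pos, !pos])
  fp <- sum(cm[!pos, pos]); tn <- sum(cm[!pos, !pos])
  n <- tp + fn + fp + tn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  cp_ci <- function(x, m) {
    if (m == 0) return(c(NA_real_, NA_real_))
    c(if (x == 0) 0 else stats::qbeta(0.025, x, m - x + 1),
      if (x == m) 1 else stats::qbeta(0.975, x + 1, m - x))
  }
  list(sensitivity = sens, specificity = spec,
       accuracy = safe_div(tp + tn, n),
       lr_pos = if (!is.na(spec) && spec < 1) sens / (1 - spec) else NA_real_,
       lr_neg = if (!is.na(spec) && spec > 0) (1 - sens) / spec else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn,
       sens_ci = cp_ci(tp, tp + fn), spec_ci = cp_ci(tn, tn + fp))
}

#' Percent agreement between two raters' labels
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return Percentage of positions with equal labels.
#' @export
percent_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  if (length(labels_a) == 0L) stop("empty label vectors")
  100 * mean(as.character(labels_a) == as.character(labels_b))
}
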