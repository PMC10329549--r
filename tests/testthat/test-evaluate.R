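test_that("ME and RAE match hand-computed cases", {
  a <- cortical_mask(matrix(1L, 10, 10))
  b <- cortical_mask(matrix(0L, 10, 10))
  expect_equal(misclassification_error(a, a), 0)
  expect_equal(misclassification_error(a, b), 1)

  # 4-pixel strip, F_gt = {0,1}, F_pred = {1,2}: 2 of 4 pixels agree
  gt <- matrix(c(1L, 1L, 0L, 0L), 1)
  pred <- matrix(c(0L, 1L, 1L, 0L), 1)
  expect_equal(misclassification_error(gt, pred), 0.5)
  expect_equal(misclassification_error(pred, gt), 0.5)   # symmetric

  expect_equal(relative_foreground_area_error(a, a), 0)
  g4 <- matrix(c(1L, 1L, 1L, 1L, 0L, 0L), 1)
  p2 <- matrix(c(1L, 1L, 0L, 0L, 0L, 0L), 1)
  expect_equal(relative_foreground_area_error(g4, p2), 0.5)  # undersegmentation
  expect_equal(relative_foreground_area_error(p2, g4), 0.5)  # oversegmentation
  expect_error(relative_foreground_area_error(b, a), "empty foreground")
  expect_error(misclassification_error(a, cortical_mask(matrix(0L, 5, 5))),
               "differ")
})

test_that("ME and RAE agree with brute-force counting on sampled 3x3 mask pairs", {
  # (the exhaustive 512 x 512 enumeration runs in the acceptance suite)
  set.seed(9)
  for (rep in 1:400) {
    g <- matrix(rbinom(9, 1, 0.5), 3, 3)
    p <- matrix(rbinom(9, 1, 0.5), 3, 3)
    agree <- 0L
    for (i in 1:3) for (j in 1:3)
      agree <- agree + as.integer(g[i, j] == p[i, j])
    expect_equal(misclassification_error(g, p), 1 - agree / 9)
    if (sum(g) > 0) {
      ag <- sum(g); ap <- sum(p)
      ref <- if (ap < ag) (ag - ap) / ag else (ap - ag) / ap
      expect_equal(relative_foreground_area_error(g, p), ref)
    }
  }
})

test_that("RAE is symmetric under mask swap", {
  set.seed(17)
  for (i in 1:20) {
    a <- matrix(rbinom(64, 1, 0.4), 8, 8)
    b <- matrix(rbinom(64, 1, 0.6), 8, 8)
    if (sum(a) == 0 || sum(b) == 0) next
    expect_equal(relative_foreground_area_error(a, b),
                 relative_foreground_area_error(b, a))
  }
})

test_that("confusion matrix counts and marginals are correct", {
  acts <- rep(c("normal", "osteopenia", "osteoporosis"), each = 3)
  cm <- confusion_matrix(acts, acts)
  expect_equal(diag(unclass(cm)), c(normal = 3, osteopenia = 3,
                                    osteoporosis = 3))
  expect_equal(sum(cm), 9L)
  expect_error(confusion_matrix(acts, acts[-1]), "length")
  expect_error(confusion_matrix(character(0), character(0)), "empty")
  expect_error(confusion_matrix("normal", "porotic"), "unknown")
})

test_that("binary diagnostics reproduce textbook identities", {
  perfect <- confusion_matrix(rep(c("normal", "osteoporosis"), each = 5),
                              rep(c("normal", "osteoporosis"), each = 5))
  d <- binary_diagnostics(perfect)
  expect_equal(d$sensitivity, 1)
  expect_equal(d$specificity, 1)
  expect_equal(d$accuracy, 1)
  expect_equal(d$lr_neg, 0)
  expect_true(is.na(d$lr_pos))          # 1 - spec = 0: undefined, not error
  # lr identities against direct TP/FP/TN/FN arithmetic
  cm <- matrix(c(50, 5, 3, 10, 30, 2, 8, 3, 12), 3, 3, byrow = TRUE,
               dimnames = list(actual = c("normal", "osteopenia",
                                          "osteoporosis"),
                               predicted = c("normal", "osteopenia",
                                             "osteoporosis")))
  d2 <- binary_diagnostics(cm)
  tp <- 30 + 2 + 3 + 12; fn <- 10 + 8; fp <- 5 + 3; tn <- 50
  expect_equal(d2$sensitivity, tp / (tp + fn))
  expect_equal(d2$specificity, tn / (tn + fp))
  expect_equal(d2$lr_pos, d2$sensitivity / (1 - d2$specificity))
  expect_equal(d2$lr_neg, (1 - d2$sensitivity) / d2$specificity)
  expect_error(binary_diagnostics(cm, positive = character(0)))
})

test_that("percent agreement is the matching fraction in percent", {
  expect_equal(percent_agreement(letters[c(1, 2, 3)], letters[c(1, 2, 3)]), 100)
  expect_equal(percent_agreement(rep(c("a", "b"), c(81, 19)),
                                 rep("a", 100)), 81)
  expect_equal(percent_agreement(c("a", "a"), c("b", "b")), 0)
  expect_error(percent_agreement("a", c("a", "b")), "length")
})
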