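# Subject-level classification: the canonical 8-feature vector (three width
# summaries per side + one texture mean per side) and a one-vs-one RBF-SVM
# with stratified k-fold cross-validation and an inner hyperparameter grid.

FEATURE_ORDER <- c("r_min_w", "r_max_w", "r_avg_w",
                   "l_min_w", "l_max_w", "l_avg_w",
                   "r_texture", "l_texture")

# Run `code` with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Assemble the canonical 8-feature vector
#'
#' Field order is fixed (right widths min/max/avg, left widths min/max/avg,
#' right texture, left texture) and is the order used for training,
#' persistence and CSV export.
#'
#' @param right,left per-side measurements: lists with `min`, `max`, `avg`
#'   (px) and `texture` (mean normalized gray).
#' @return Named numeric vector of length 8 in canonical order.
#' @export
build_features <- function(right, left) {
  for (s in list(right, left))
    if (!all(c("min", "max", "avg", "texture") %in% names(s)))
      stop("each side needs min, max, avg and texture")
  stats::setNames(c(right$min, right$max, right$avg,
                    left$min, left$max, left$avg,
                    right$texture, left$texture), FEATURE_ORDER)
}

#' Select a feature subset
#'
#' @param features data.frame or matrix with the canonical 8 columns.
#' @param subset `"width_and_texture"` (all 8), `"width_only"` (6 width
#'   columns) or `"texture_only"` (2 texture columns).
#' @return The selected columns, canonical order preserved.
#' @export
feature_subset <- function(features,
                           subset = c("width_and_texture", "width_only",
                                      "texture_only")) {
  subset <- match.arg(subset)
  keep <- switch(subset,
    width_and_texture = FEATURE_ORDER,
    width_only = FEATURE_ORDER[1:6],
    texture_only = FEATURE_ORDER[7:8])
  features[, keep, drop = FALSE]
}

#' Train a multiclass RBF-SVM on standardized features
#'
#' Features are standardized to zero mean / unit variance using statistics
#' of the training set only; the SVM is the one-vs-one multiclass
#' radial-basis-function machine. Deterministic for fixed inputs.
#'
#' @param features numeric matrix/data.frame (rows = subjects).
#' @param labels class labels (factor or character).
#' @param C regularization constant.
#' @param gamma RBF kernel width.
#' @return A `trained_model` with the fitted SVM and the standardization
#'   offsets/scales.
#' @export
train_svm <- function(features, labels, C = 1, gamma = 0.1) {
  x <- as.matrix(features)
  y <- factor(as.character(labels), levels = intersect(VALID_LABELS,
                                                       unique(as.character(labels))))
  if (nlevels(y) < 2L) stop("need at least 2 classes to train")
  if (nrow(x) < 6L) stop("need at least 6 training subjects")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  xs <- scale(x, center = mu, scale = sdv)
  fit <- e1071::svm(x = xs, y = y, kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  structure(list(kernel = "rbf", C = C, gamma = gamma, center = mu,
                 scale = sdv, fit = fit, classes = levels(y),
                 features = colnames(x)),
            class = "trained_model")
}

#' Predict classes with a trained model
#'
#' @param object a `trained_model`.
#' @param newdata feature matrix/data.frame with the training columns.
#' @param ... unused.
#' @return Factor of predicted class labels.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$features, drop = FALSE]
  xs <- scale(x, center = object$center, scale = object$scale)
  stats::predict(object$fit, xs)
}

# Stratified fold assignment: per class, members are shuffled then dealt
# cyclically into folds 1..k.
stratified_folds <- function(labels, k, seed) {
  y <- as.character(labels)
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k)
        stop(sprintf("class '%s' has %d members, fewer than k = %d; use a smaller k",
                     cl, length(idx), k))
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Inner grid search over (C, gamma) by stratified 3-fold accuracy on the
# training split; first grid entry wins ties. Training splits too small to
# stratify the inner folds fall back to mid-grid defaults.
tune_svm <- function(x, y, C_grid, gamma_grid, inner_k, seed) {
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  inner_k <- min(inner_k, min(table(as.character(y))))
  if (inner_k < 2L || floor(length(y) * (inner_k - 1) / inner_k) < 6L)
    return(data.frame(C = C_grid[which.min(abs(log(C_grid)))],
                      gamma = gamma_grid[which.min(abs(log(gamma_grid) -
                                                       log(0.1)))]))
  fold <- stratified_folds(y, inner_k, seed)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L
    for (f in seq_len(inner_k)) {
      tr <- fold != f
      m <- train_svm(x[tr, , drop = FALSE], y[tr],
                     C = grid$C[g], gamma = grid$gamma[g])
      correct <- correct + sum(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  grid[which.max(acc), ]
}

#' Stratified k-fold cross-validation of the RBF-SVM
#'
#' Folds are stratified by class from a seeded shuffle. Within each fold the
#' SVM hyperparameters are chosen by an inner stratified 3-fold grid search
#' (`C` in `{0.1, 1, 10, 100}`, `gamma` in `{0.001, 0.01, 0.1, 1}`) on the
#' training split only; standardization statistics are likewise computed on
#' the training split only. Reproducible: the same seed yields an identical
#' report.
#'
#' @param features data.frame/matrix with the canonical feature columns.
#' @param labels class labels.
#' @param k number of folds (>= 2; every class must have >= k members).
#' @param subset feature subset, see [feature_subset].
#' @param seed integer seed controlling fold assignment.
#' @param C_grid,gamma_grid hyperparameter grids.
#' @param inner_k inner folds for the grid search.
#' @return A `cv_report`: `k`, `feature_subset`, `per_fold_accuracy` (in
#'   `[0, 1]`), `mean_accuracy`, `predictions` (held-out predicted vs
#'   actual label per subject, with fold ids), and `fold_models` (per-fold
#'   chosen hyperparameters and standardization statistics).
#' @export
cross_validate <- function(features, labels, k = 10L,
                           subset = "width_and_texture", seed = 1L,
                           C_grid = c(0.1, 1, 10, 100),
                           gamma_grid = c(0.001, 0.01, 0.1, 1),
                           inner_k = 3L) {
  x <- as.matrix(feature_subset(as.data.frame(features), subset))
  y <- factor(as.character(labels), levels = VALID_LABELS)
  fold <- stratified_folds(y, k, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = VALID_LABELS)
  per_fold <- numeric(k)
  fold_models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    best <- tune_svm(x[tr, , drop = FALSE], y[tr], C_grid, gamma_grid,
                     inner_k, seed = seed * 131L + f)
    m <- train_svm(x[tr, , drop = FALSE], y[tr], C = best$C, gamma = best$gamma)
    ph <- predict(m, x[!tr, , drop = FALSE])
    pred[!tr] <- as.character(ph)
    per_fold[f] <- mean(ph == y[!tr])
    fold_models[[f]] <- list(C = best$C, gamma = best$gamma,
                             center = m$center, scale = m$scale)
  }
  structure(list(k = as.integer(k), feature_subset = subset,
                 per_fold_accuracy = per_fold,
                 mean_accuracy = mean(per_fold),
                 predictions = data.frame(actual = y, predicted = pred,
                                          fold = fold),
                 fold_models = fold_models,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report k=%d subset=%s mean accuracy=%s%%>\n", x$k,
              x$feature_subset,
              format_accuracy(100 * x$mean_accuracy)))
  invisible(x)
}

#' Arithmetic mean of accuracies
#'
#' @param accuracies non-empty numeric vector (any scale).
#' @return The arithmetic mean. Use [format_accuracy] to print it rounded
#'   half-up to two decimals, the convention of the reporting tables.
#' @export
mean_accuracy <- function(accuracies) {
  if (length(accuracies) == 0L) stop("empty accuracy vector")
  mean(accuracies)
}

#' Format an accuracy rounded half-up to two decimals
#'
#' @param x numeric.
#' @return Character, e.g. `"86.27"`.
#' @export
format_accuracy <- function(x) {
  sprintf("%.2f", round_half_up(x, 2))
}
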