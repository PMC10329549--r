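# Batch pipeline over a dataset manifest: segmentation with error reporting,
# feature extraction, and cross-validated classification. These functions
# are the programmatic surface behind the command-line wrapper in
# inst/cli/mandicort.R. Per-record failures are isolated: a bad image is
# reported, not fatal to the batch.

#' Segment every ROI of a manifest
#'
#' Runs [segment_cortical] on each subject's left and right ROI. When
#' ground-truth masks are present, per-image ME and RAE are reported.
#'
#' @param manifest a `dataset_manifest` from [read_manifest] (or
#'   [generate_dataset]).
#' @param params [line_operator_params].
#' @param gradient_threshold,top_k segmentation parameters.
#' @param out_dir optional directory for predicted-mask PNGs.
#' @return data.frame with one row per (subject, side): `subject_id`,
#'   `side`, `me`, `rae` (NA without ground truth), `mask_path`, `error`.
#' @export
pipeline_segment <- function(manifest, params = line_operator_params(),
                             gradient_threshold = 3, top_k = 5L,
                             out_dir = NULL) {
  if (nrow(manifest) == 0L) stop("empty manifest")
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    for (side in c("right", "left")) {
      roi_col <- paste0(side, "_roi"); mask_col <- paste0(side, "_mask")
      row <- data.frame(subject_id = manifest$subject_id[i], side = side,
                        me = NA_real_, rae = NA_real_,
                        mask_path = NA_character_, error = NA_character_)
      res <- tryCatch({
        roi <- load_roi(manifest[[roi_col]][i], side)
        pred <- segment_cortical(roi, params, gradient_threshold, top_k)
        if (mask_col %in% names(manifest) && !is.na(manifest[[mask_col]][i])) {
          gt <- load_mask(manifest[[mask_col]][i])
          row$me <- misclassification_error(gt, pred)
          row$rae <- relative_foreground_area_error(gt, pred)
        }
        if (!is.null(out_dir)) {
          p <- file.path(out_dir, sprintf("%s_%s_pred.png",
                                          manifest$subject_id[i],
                                          toupper(substr(side, 1, 1))))
          write_roi(pred, p)
          row$mask_path <- p
        }
        row
      }, error = function(e) { row$error <- conditionMessage(e); row })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}

measure_one_side <- function(roi_path, mask_path, side, params,
                             gradient_threshold, top_k) {
  roi <- load_roi(roi_path, side)
  mask <- if (!is.null(mask_path) && !is.na(mask_path)) load_mask(mask_path)
          else segment_cortical(roi, params, gradient_threshold, top_k)
  widths <- measure_side(roi, mask)
  norm <- normalize_intensity(roi)
  list(min = widths$min, max = widths$max, avg = widths$avg,
       texture = mean_cortical_intensity(norm, mask))
}

#' Extract the 8-feature table for a manifest
#'
#' For every subject, measures both sides (segmenting on the fly when the
#' manifest carries no mask for a side — set `use_gt_masks = FALSE` to
#' always segment) and assembles the canonical feature vector.
#'
#' @inheritParams pipeline_segment
#' @param use_gt_masks use manifest ground-truth masks when present
#'   (default TRUE); otherwise run the segmentation stage.
#' @return data.frame: `subject_id`, the 8 canonical feature columns,
#'   `label`. Failed subjects are dropped with a warning.
#' @export
pipeline_features <- function(manifest, params = line_operator_params(),
                              gradient_threshold = 3, top_k = 5L,
                              use_gt_masks = TRUE) {
  if (nrow(manifest) == 0L) stop("empty manifest")
  rows <- list(); failed <- character()
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch({
      gm <- function(col) if (use_gt_masks && col %in% names(manifest))
        manifest[[col]][i] else NA_character_
      right <- measure_one_side(manifest$right_roi[i], gm("right_mask"),
                                "right", params, gradient_threshold, top_k)
      left <- measure_one_side(manifest$left_roi[i], gm("left_mask"),
                               "left", params, gradient_threshold, top_k)
      fv <- build_features(right, left)
      cbind(data.frame(subject_id = manifest$subject_id[i]),
            as.data.frame(t(fv)),
            data.frame(label = as.character(manifest$label[i])))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failed <- c(failed, sprintf("%s: %s",
                                                       manifest$subject_id[i], res))
    else rows[[length(rows) + 1L]] <- res
  }
  if (length(failed))
    warning(sprintf("%d subject(s) failed feature extraction: %s",
                    length(failed), paste(failed, collapse = "; ")))
  if (length(rows) == 0L) stop("no subject produced features")
  do.call(rbind, rows)
}

#' Cross-validated classification report over k and feature subsets
#'
#' Runs [cross_validate] for every requested `k` and feature subset and
#' assembles the standard accuracy summary (one row per `k` plus an
#' `Average` row; one column per subset, percentages). Also pools the
#' held-out predictions of the largest `k` (all-features run) into a
#' confusion matrix and binary low-bone-density diagnostics.
#'
#' @param features feature table from [pipeline_features] (needs the 8
#'   canonical columns and `label`).
#' @param k_values folds to evaluate (default `c(2, 3, 5, 10)`); a `k`
#'   larger than the smallest class is skipped with a warning.
#' @param subsets feature subsets to evaluate.
#' @param seed integer seed.
#' @param ... passed on to [cross_validate] (e.g. `C_grid`, `gamma_grid`).
#' @return List: `reports` (nested `cv_report`s), `summary` (accuracy table
#'   in percent, rounded half-up to 2 decimals), `confusion`
#'   ([confusion_matrix]), `diagnostics` ([binary_diagnostics]).
#' @export
pipeline_classify <- function(features, k_values = c(2L, 3L, 5L, 10L),
                              subsets = c("width_and_texture", "width_only",
                                          "texture_only"),
                              seed = 1L, ...) {
  labels <- features$label
  k_ok <- k_values[k_values <= min(table(factor(labels, VALID_LABELS)))]
  if (length(k_ok) < length(k_values))
    warning("skipping k larger than the smallest class: ",
            paste(setdiff(k_values, k_ok), collapse = ", "))
  if (length(k_ok) == 0L) stop("no feasible k for this class distribution")
  reports <- lapply(subsets, function(s)
    lapply(k_ok, function(k) cross_validate(features, labels, k = k,
                                            subset = s, seed = seed, ...)))
  names(reports) <- subsets
  acc <- vapply(reports, function(rs)
    vapply(rs, function(r) 100 * r$mean_accuracy, numeric(1)),
    numeric(length(k_ok)))
  acc <- matrix(acc, nrow = length(k_ok), ncol = length(subsets),
                dimnames = list(k_ok, subsets))
  summary <- rbind(acc, Average = colMeans(acc))
  summary <- as.data.frame(round_half_up(summary, 2))
  summary <- cbind(k = rownames(summary), summary)
  rownames(summary) <- NULL
  main <- reports[[subsets[1L]]][[length(k_ok)]]
  cm <- confusion_matrix(main$predictions$actual, main$predictions$predicted)
  list(reports = reports, summary = summary, confusion = cm,
       diagnostics = binary_diagnostics(cm), seed = seed)
}
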