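# Porosity-sensitive texture feature: percentile-anchored intensity
# normalization followed by the mean gray level over the cortical mask.
# Porous (osteoporotic) cortical bone contains more dark cavities, so its
# mean normalized intensity is lower.

#' Normalize ROI intensity for cross-image comparability
#'
#' Panoramic radiographs suffer uneven illumination, so raw gray levels are
#' not comparable across ROIs. This applies the affine map sending the
#' image's `low_percentile`/`high_percentile` gray levels (defaults 1st and
#' 99th, robust to the bright cortical band) to `target_low`/`target_high`
#' (defaults 0 and 255), clipping to `[0, 255]`. A constant image maps to
#' the midpoint of the target range.
#'
#' @param roi an [roi_image] or numeric matrix.
#' @param low_percentile,high_percentile anchor percentiles in `[0, 100]`.
#' @param target_low,target_high target gray levels.
#' @return Numeric matrix in `[0, 255]`.
#' @export
normalize_intensity <- function(roi, low_percentile = 1, high_percentile = 99,
                                target_low = 0, target_high = 255) {
  if (!(low_percentile >= 0 && low_percentile < high_percentile &&
        high_percentile <= 100))
    stop("need 0 <= low_percentile < high_percentile <= 100")
  if (target_low >= target_high) stop("target_low must be < target_high")
  img <- if (inherits(roi, "roi_image")) roi$pixels else roi
  q <- stats::quantile(img, c(low_percentile, high_percentile) / 100,
                       names = FALSE)
  if (q[2] - q[1] <= .Machine$double.eps)
    return(matrix((target_low + target_high) / 2, nrow(img), ncol(img)))
  out <- target_low + (img - q[1]) * (target_high - target_low) / (q[2] - q[1])
  pmin(pmax(out, 0), 255)
}

#' Mean normalized intensity over the cortical mask
#'
#' The texture feature: the arithmetic mean of the normalized image over the
#' segmented cortical foreground (optionally over the whole ROI for
#' ablation).
#'
#' @param normalized numeric matrix from [normalize_intensity].
#' @param mask a [cortical_mask]; ignored when `use_mask = FALSE`.
#' @param use_mask restrict the mean to mask foreground (default TRUE).
#' @return Mean gray level (real).
#' @export
mean_cortical_intensity <- function(normalized, mask, use_mask = TRUE) {
  if (!use_mask) return(mean(normalized))
  m <- if (inherits(mask, "cortical_mask")) mask$pixels else mask
  if (!identical(dim(m), dim(normalized))) stop("mask/image shape mismatch")
  if (sum(m) == 0) stop("empty mask: texture undefined")
  mean(normalized[m > 0])
}
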