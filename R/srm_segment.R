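# Seeded statistical region merging: watershed over-segmentation, automatic
# object/background sample-area selection, then iterative agglomeration of
# regions into the two classes by a gray-level distance.

sobel_gradient <- function(image) {
  gx <- shift_reflect(image, 0, -1) - shift_reflect(image, 0, 1)
  gx <- gx + 0.5 * (shift_reflect(image, -1, -1) - shift_reflect(image, -1, 1) +
                    shift_reflect(image,  1, -1) - shift_reflect(image,  1, 1))
  gy <- shift_reflect(image, -1, 0) - shift_reflect(image, 1, 0)
  gy <- gy + 0.5 * (shift_reflect(image, -1, -1) - shift_reflect(image, 1, -1) +
                    shift_reflect(image, -1,  1) - shift_reflect(image, 1,  1))
  sqrt(gx^2 + gy^2)
}

#' Initial over-segmentation for statistical region merging
#'
#' Partitions the (enhanced) image into fine regions by a marker-free
#' watershed of the Sobel gradient magnitude; basins separated by ridges
#' shallower than `gradient_threshold` gray levels are merged. Every pixel
#' belongs to exactly one region.
#'
#' @param image numeric matrix (typically the gray-preserving multiplication
#'   result).
#' @param gradient_threshold minimum ridge depth, in gray levels, for two
#'   basins to stay distinct (default 3: the threshold acts on the enhanced
#'   product image, whose background sits near 0, so transitions at the
#'   band's blurred margin are shallow and a coarse threshold would fold
#'   the margin into band-edge basins and thicken the mask).
#' @return A `region_partition`: `label_map` (integer matrix, labels
#'   `1..n`) and `regions`, a data.frame with `id`, `area`, `mean_gray`,
#'   `centroid_row`, `centroid_col` (0-based centroids).
#' @export
initial_partition <- function(image, gradient_threshold = 3) {
  if (any(!is.finite(image))) stop("image must be finite")
  grad <- sobel_gradient(image)
  if (diff(range(grad)) <= .Machine$double.eps) {
    lab <- matrix(1L, nrow(image), ncol(image))
  } else {
    # invert so basins of the gradient become peaks; +1 keeps all pixels
    # positive so the watershed labels the full grid
    topo <- max(grad) - grad + 1
    lab <- EBImage::imageData(EBImage::watershed(topo,
                                                 tolerance = gradient_threshold))
    storage.mode(lab) <- "integer"
    if (any(lab == 0L)) {
      # watershed lines / unlabeled pixels: absorb into an adjacent region
      # by nearest-neighbour propagation
      while (any(lab == 0L)) {
        for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          nb <- shift_reflect(lab, sh[1], sh[2])
          fill <- lab == 0L & nb != 0L
          lab[fill] <- nb[fill]
        }
      }
    }
    # relabel compactly
    lab <- matrix(match(lab, sort(unique(as.vector(lab)))),
                  nrow(image), ncol(image))
  }
  region_partition(lab, image)
}

region_partition <- function(label_map, image) {
  ids <- sort(unique(as.vector(label_map)))
  f <- factor(label_map, levels = ids)
  area <- as.integer(table(f))
  mean_gray <- as.numeric(tapply(as.vector(image), f, mean))
  rows0 <- row(label_map) - 1L
  cols0 <- col(label_map) - 1L
  centroid_row <- as.numeric(tapply(as.vector(rows0), f, mean))
  centroid_col <- as.numeric(tapply(as.vector(cols0), f, mean))
  structure(list(label_map = label_map,
                 regions = data.frame(id = as.integer(ids), area = area,
                                      mean_gray = mean_gray,
                                      centroid_row = centroid_row,
                                      centroid_col = centroid_col)),
            class = "region_partition")
}

#' Automatic object/background seed selection
#'
#' Object candidates are drawn from the bright regions (mean gray at or
#' above the global area-weighted mean — candidate areas must be "brightly
#' colored", otherwise on noisy inputs large smooth *dark* basins would
#' outrank small bright ones) and ranked jointly by size and brightness
#' (sum of the descending ranks of area and of mean gray); the object seed
#' is the `top_k`-candidate whose centroid lies nearest the image centre.
#' The background seed is the darkest region among those whose centroid is
#' farther from the centre than the median centroid distance (ties broken
#' by smaller area, then smaller id).
#'
#' @param partition a `region_partition`.
#' @param top_k number of object candidates (default 5).
#' @return A `seed_assignment` list with `object_seed_id` and
#'   `background_seed_id`.
#' @export
select_seeds <- function(partition, top_k = 5L) {
  reg <- partition$regions
  if (nrow(reg) < 2L) stop("degenerate partition: fewer than 2 regions")
  nr <- nrow(partition$label_map); nc <- ncol(partition$label_map)
  center <- c((nr - 1) / 2, (nc - 1) / 2)
  dist_center <- sqrt((reg$centroid_row - center[1])^2 +
                      (reg$centroid_col - center[2])^2)
  global_mean <- sum(reg$area * reg$mean_gray) / sum(reg$area)
  pool <- which(reg$mean_gray >= global_mean)
  if (length(pool) == 0L) pool <- seq_len(nrow(reg))
  rank_sum <- rank(-reg$area[pool], ties.method = "min") +
              rank(-reg$mean_gray[pool], ties.method = "min")
  cand <- pool[order(rank_sum, reg$id[pool])][seq_len(min(top_k,
                                                          length(pool)))]
  object_idx <- cand[order(dist_center[cand], reg$id[cand])[1L]]
  far <- which(dist_center > stats::median(dist_center))
  far <- setdiff(far, object_idx)
  if (length(far) == 0L) far <- setdiff(seq_len(nrow(reg)), object_idx)
  bg_idx <- far[order(reg$mean_gray[far], reg$area[far], reg$id[far])[1L]]
  structure(list(object_seed_id = reg$id[object_idx],
                 background_seed_id = reg$id[bg_idx]),
            class = "seed_assignment")
}

#' Construct a seed assignment explicitly
#'
#' Mainly useful for manual seed override; [select_seeds] builds one
#' automatically.
#'
#' @param object_seed_id,background_seed_id distinct region ids.
#' @return A `seed_assignment`.
#' @export
seed_assignment <- function(object_seed_id, background_seed_id) {
  if (object_seed_id == background_seed_id)
    stop("object and background seeds must differ")
  structure(list(object_seed_id = as.integer(object_seed_id),
                 background_seed_id = as.integer(background_seed_id)),
            class = "seed_assignment")
}

#' Gray-level distance between a region and a class
#'
#' The absolute difference between the region's mean gray and the class's
#' area-weighted mean gray.
#'
#' @param region_mean_gray region mean gray level.
#' @param class_mean_gray area-weighted mean gray level of the regions
#'   already merged into the class.
#' @return Non-negative real.
#' @export
region_distance <- function(region_mean_gray, class_mean_gray) {
  abs(region_mean_gray - class_mean_gray)
}

#' Merge all regions into object and background classes
#'
#' Iterative agglomeration: at each step, over all unlabeled regions and
#' both classes, the (region, class) pair with the smallest
#' [region_distance] is merged (ties: lowest region id, then the object
#' class); class statistics are updated area-weighted after every merge.
#' Terminates when every region is labeled. Merging is deliberately not
#' restricted to regions touching a labeled class: the cortical band spans
#' the ROI and disconnects the background above it from the background
#' below, so an adjacency-constrained background class could never reach
#' the far side (connectivity of the final mask is restored afterwards by
#' [segment_cortical]'s largest-component step).
#'
#' @param partition a `region_partition`.
#' @param seeds a `seed_assignment`.
#' @return A [cortical_mask] covering the object class.
#' @export
merge_all <- function(partition, seeds) {
  reg <- partition$regions
  n <- nrow(reg)
  idx_of <- match(c(seeds$object_seed_id, seeds$background_seed_id), reg$id)
  if (any(is.na(idx_of)) || idx_of[1L] == idx_of[2L])
    stop("seeds must be two distinct regions of the partition")
  assign <- integer(n)                   # 0 unlabeled, 1 object, 2 background
  assign[idx_of] <- c(1L, 2L)
  cls_sum <- c(reg$area[idx_of[1L]] * reg$mean_gray[idx_of[1L]],
               reg$area[idx_of[2L]] * reg$mean_gray[idx_of[2L]])
  cls_area <- reg$area[idx_of]
  n_left <- n - 2L
  while (n_left > 0L) {
    open <- which(assign == 0L)
    d1 <- abs(reg$mean_gray[open] - cls_sum[1L] / cls_area[1L])
    d2 <- abs(reg$mean_gray[open] - cls_sum[2L] / cls_area[2L])
    allc <- c(open, open)
    alld <- c(d1, d2)
    allk <- rep(1:2, each = length(open))
    best <- order(alld, reg$id[allc], allk)[1L]
    r <- allc[best]; k <- allk[best]
    assign[r] <- k
    cls_sum[k] <- cls_sum[k] + reg$area[r] * reg$mean_gray[r]
    cls_area[k] <- cls_area[k] + reg$area[r]
    n_left <- n_left - 1L
  }
  obj_ids <- reg$id[assign == 1L]
  cortical_mask(matrix(as.integer(partition$label_map %in% obj_ids),
                       nrow(partition$label_map)))
}

# Keep the largest 4-connected foreground component and fill enclosed
# background holes of at most `max_hole` pixels.
clean_mask <- function(mask, max_hole = 10L) {
  m <- mask$pixels
  lab <- label_components4(m)
  if (max(lab) > 1L) {
    areas <- tabulate(lab[lab > 0L])
    m <- matrix(as.integer(lab == which.max(areas)), nrow(m))
  }
  holes <- label_components4(1L - m)
  if (max(holes) > 0L) {
    border_ids <- unique(c(holes[1L, ], holes[nrow(holes), ],
                           holes[, 1L], holes[, ncol(holes)]))
    areas <- tabulate(holes[holes > 0L])
    fill_ids <- setdiff(which(areas <= max_hole), border_ids)
    if (length(fill_ids)) m[holes %in% fill_ids] <- 1L
  }
  cortical_mask(m)
}

#' Segment the cortical band of an ROI
#'
#' Full segmentation stage: multiscale line enhancement, gray-preserving
#' multiplication, watershed over-segmentation, automatic seed selection,
#' and statistical region merging. The returned mask is the largest
#' 4-connected component of the object class, with enclosed holes of at
#' most 10 px filled (the width stage needs a single solid band).
#'
#' @param roi an [roi_image].
#' @param params [line_operator_params].
#' @param gradient_threshold watershed merge depth in gray levels.
#' @param top_k number of object-seed candidates.
#' @return A [cortical_mask], same shape as `roi`.
#' @export
segment_cortical <- function(roi, params = line_operator_params(),
                             gradient_threshold = 3, top_k = 5L) {
  enhanced <- multiply_preserve_gray(roi, multiscale_line_response(roi, params))
  part <- initial_partition(enhanced, gradient_threshold)
  seeds <- select_seeds(part, top_k)
  clean_mask(merge_all(part, seeds))
}
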