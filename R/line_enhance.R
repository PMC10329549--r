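#' Line operator parameters
#'
#' Parameters of the multiscale line operator that enhances the bright,
#' elongated cortical band before segmentation. The line strength of a pixel
#' is the largest, over a set of orientations, of the mean gray level along
#' an oriented line segment through the pixel minus the mean gray level of
#' the square neighbourhood around it; computing it on a Gaussian pyramid
#' lets thick bands respond as strongly as thin ones.
#'
#' @param line_length odd segment length in pixels (default 5).
#' @param n_orientations number of evenly spaced angles in `[0, 180)`
#'   (default 12, i.e. 15 degree steps).
#' @param neighborhood_size odd side of the local-mean square, at least
#'   `line_length` (default 5).
#' @param pyramid_levels number of pyramid levels including the original
#'   (default 4: a band up to ~35 px wide must shrink below the line length
#'   before its interior responds, which needs the 1/8-scale level for
#'   128 px ROIs).
#' @return A `line_operator_params` list.
#' @export
line_operator_params <- function(line_length = 5L, n_orientations = 12L,
                                 neighborhood_size = 5L, pyramid_levels = 4L) {
  if (line_length < 3L || line_length %% 2L == 0L)
    stop("line_length must be odd and >= 3")
  if (n_orientations < 4L) stop("n_orientations must be >= 4")
  if (neighborhood_size < line_length || neighborhood_size %% 2L == 0L)
    stop("neighborhood_size must be odd and >= line_length")
  if (pyramid_levels < 1L) stop("pyramid_levels must be >= 1")
  structure(list(line_length = as.integer(line_length),
                 n_orientations = as.integer(n_orientations),
                 neighborhood_size = as.integer(neighborhood_size),
                 pyramid_levels = as.integer(pyramid_levels)),
            class = "line_operator_params")
}

#' Gaussian image pyramid
#'
#' Level 1 is the input; each further level is binomially smoothed
#' (`[1 4 6 4 1]/16`, separable) then decimated by 2, with each dimension
#' `ceiling(previous / 2)`.
#'
#' @param image numeric matrix.
#' @param levels number of levels (>= 1).
#' @return List of matrices, coarsest last.
#' @export
gaussian_pyramid <- function(image, levels) {
  if (levels < 1L) stop("levels must be >= 1")
  if (min(dim(image)) < 2^(levels - 1) * 8)
    stop(sprintf("image of min dimension %d too small for %d pyramid levels",
                 min(dim(image)), levels))
  out <- vector("list", levels)
  out[[1L]] <- image
  for (i in seq_len(levels - 1L)) {
    sm <- binomial_smooth(out[[i]])
    out[[i + 1L]] <- sm[seq(1L, nrow(sm), by = 2L),
                        seq(1L, ncol(sm), by = 2L), drop = FALSE]
  }
  out
}

# Integer pixel offsets of a rasterized line segment of `len` pixels through
# the origin at angle `theta` (radians, measured in (col,row) image axes).
line_offsets <- function(len, theta) {
  half <- (len - 1L) / 2
  t <- seq(-half, half)
  # snap near-half-integers (sin(pi/6) evaluates just below 0.5 while
  # cos(2*pi/3) lands just above -0.5), then round half away from zero, so
  # the offset set for theta + 90 degrees is the exact 90-degree rotation
  # of the set for theta (rotation equivariance)
  dr <- round_half_up(round(t * sin(theta), 9))
  dc <- round_half_up(round(t * cos(theta), 9))
  unique(cbind(dr, dc))
}

#' Line strength map at a single scale
#'
#' For every pixel: maximum over orientations of (mean gray along the
#' oriented line segment) minus (mean gray over the neighbourhood square),
#' with mirror-reflected borders. Positive responses mark bright elongated
#' structure; a uniform image scores 0 everywhere.
#'
#' @param image numeric matrix.
#' @param params [line_operator_params].
#' @return Numeric matrix of raw (unnormalized, possibly negative) strengths.
#' @export
line_strength <- function(image, params = line_operator_params()) {
  if (any(!is.finite(image))) stop("image must be finite")
  nb <- box_mean(image, (params$neighborhood_size - 1L) / 2L)
  thetas <- seq(0, pi, length.out = params$n_orientations + 1L)[
    seq_len(params$n_orientations)]
  best <- matrix(-Inf, nrow(image), ncol(image))
  for (th in thetas) {
    offs <- line_offsets(params$line_length, th)
    acc <- matrix(0, nrow(image), ncol(image))
    for (k in seq_len(nrow(offs)))
      acc <- acc + shift_reflect(image, offs[k, 1L], offs[k, 2L])
    best <- pmax(best, acc / nrow(offs))
  }
  best - nb
}

#' Multiscale line response of an ROI
#'
#' Computes [line_strength] at every level of the Gaussian pyramid, bilinearly
#' upsamples coarse responses back to the base resolution, fuses them by
#' pixelwise maximum, clamps negative (dark-line) responses to zero, and
#' min-max normalizes into `[0, 1]`. An all-equal response maps to all zeros.
#'
#' @param roi an [roi_image] (or bare matrix).
#' @param params [line_operator_params].
#' @return A `line_response` list with `values` (matrix in `[0, 1]`) and
#'   `params`.
#' @export
multiscale_line_response <- function(roi, params = line_operator_params()) {
  img <- if (inherits(roi, "roi_image")) roi$pixels else roi
  pyr <- gaussian_pyramid(img, params$pyramid_levels)
  fused <- matrix(-Inf, nrow(img), ncol(img))
  for (lev in pyr) {
    resp <- line_strength(lev, params)
    if (!identical(dim(resp), dim(img)))
      resp <- bilinear_resize(resp, nrow(img), ncol(img))
    fused <- pmax(fused, resp)
  }
  fused <- pmax(fused, 0)
  rng <- range(fused)
  values <- if (rng[2] > rng[1]) (fused - rng[1]) / (rng[2] - rng[1])
            else matrix(0, nrow(img), ncol(img))
  structure(list(values = values, params = params), class = "line_response")
}

#' Gray-preserving multiplication of ROI and line response
#'
#' Pixelwise product of the original ROI with the normalized line response,
#' reinforcing cortical structure while retaining gray-level information;
#' the result lies in `[0, 255]` and feeds segmentation.
#'
#' @param roi an [roi_image] (or matrix in `[0, 255]`).
#' @param response a `line_response` (or matrix in `[0, 1]`).
#' @return Numeric matrix in `[0, 255]`.
#' @export
multiply_preserve_gray <- function(roi, response) {
  img <- if (inherits(roi, "roi_image")) roi$pixels else roi
  val <- if (inherits(response, "line_response")) response$values else response
  if (!identical(dim(img), dim(val)))
    stop("ROI and response shapes differ")
  img * val
}
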