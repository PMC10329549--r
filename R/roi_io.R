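#' ROI image objects
#'
#' An `roi_image` wraps one grayscale region-of-interest crop taken below the
#' left or right mental foramen of a panoramic radiograph. Pixels are stored
#' as a numeric matrix in `[0, 255]`, row 1 at the top of the image
#' (user-facing coordinates throughout the package are 0-based `(row, col)`
#' with row 0 at the top).
#'
#' @param pixels numeric matrix of gray values in `[0, 255]`.
#' @param side `"left"` or `"right"`.
#' @param source_id opaque identifier carried through reports.
#' @return An object of class `roi_image` with fields `pixels`, `height`,
#'   `width`, `side`, `source_id`.
#' @export
roi_image <- function(pixels, side = c("right", "left"), source_id = "") {
  side <- match.arg(side)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 32L || ncol(pixels) < 32L)
    stop("ROI must be at least 32 x 32 pixels")
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 255))
    stop("pixel values must be finite and within [0, 255]")
  structure(list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
                 side = side, source_id = as.character(source_id)),
            class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image %dx%d side=%s id=%s gray=[%.0f, %.0f]>\n",
              x$height, x$width, x$side, x$source_id,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Read a PNG/TIFF into a gray matrix scaled to [0, 255]; rejects true-colour
# images rather than silently mixing channels.
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format (need PNG or TIFF): ", path))
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    ch <- lapply(seq_len(min(nch, 3L)), function(i) arr[, , i])
    if (length(ch) > 1L) {
      for (i in 2:length(ch)) {
        if (max(abs(ch[[i]] - ch[[1]])) > 1e-6)
          stop("image has unequal colour channels; refusing implicit ",
               "grayscale conversion: ", path)
      }
    }
    arr <- ch[[1]]
  }
  # readPNG/readTIFF return [0,1] doubles regardless of bit depth, so a
  # linear rescale to [0,255] covers both 8- and 16-bit sources.
  arr * 255
}

#' Load an ROI image from PNG or TIFF
#'
#' Reads a single-channel (or channel-equal) image, rescales to `[0, 255]`
#' (16-bit sources linearly), and tags it with its jaw side.
#'
#' @param path path to a PNG or TIFF file.
#' @param side `"left"` or `"right"`.
#' @param source_id identifier; defaults to the file name.
#' @return An [roi_image].
#' @export
load_roi <- function(path, side = c("right", "left"),
                     source_id = basename(path)) {
  roi_image(read_gray_image(path), side = match.arg(side),
            source_id = source_id)
}

#' Write an ROI (or any gray matrix / mask) as an 8-bit PNG
#'
#' @param x an [roi_image], `cortical_mask`, or numeric matrix in `[0, 255]`
#'   (masks are written as 0/255).
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_roi <- function(x, path) {
  m <- if (inherits(x, "roi_image")) x$pixels
       else if (inherits(x, "cortical_mask")) x$pixels * 255
       else x
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Crop a square ROI out of a larger gray image
#'
#' Coordinates are 0-based `(row, col)` with row 0 at the top; the crop is
#' the half-open window of `size` pixels centred at
#' (`center_row`, `center_col`): rows `[center_row - size %/% 2,
#' center_row - size %/% 2 + size)`, likewise for columns.
#'
#' @param image numeric gray matrix.
#' @param center_col,center_row 0-based centre of the crop window.
#' @param size window side length in pixels.
#' @param side,source_id passed to [roi_image] when `size >= 32`; for smaller
#'   windows the bare matrix is returned.
#' @return An [roi_image] (or a matrix for sub-ROI-sized windows).
#' @export
crop_roi <- function(image, center_col, center_row, size,
                     side = "right", source_id = "crop") {
  r0 <- center_row - size %/% 2L
  c0 <- center_col - size %/% 2L
  if (r0 < 0L || c0 < 0L || r0 + size > nrow(image) || c0 + size > ncol(image))
    stop(sprintf("crop window rows [%d,%d) cols [%d,%d) exceeds %dx%d image",
                 r0, r0 + size, c0, c0 + size, nrow(image), ncol(image)))
  m <- image[(r0 + 1L):(r0 + size), (c0 + 1L):(c0 + size), drop = FALSE]
  if (size >= 32L) roi_image(m, side = side, source_id = source_id) else m
}

#' Binary cortical-bone mask paired with an ROI
#'
#' @param pixels matrix of 0/1 (logical or numeric) values.
#' @return Object of class `cortical_mask` with an integer 0/1 `pixels`
#'   matrix.
#' @export
cortical_mask <- function(pixels) {
  if (is.logical(pixels)) pixels <- pixels + 0L
  if (!is.matrix(pixels) || !all(pixels %in% c(0, 1)))
    stop("mask values must be 0/1")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, height = nrow(pixels), width = ncol(pixels)),
            class = "cortical_mask")
}

#' @export
print.cortical_mask <- function(x, ...) {
  cat(sprintf("<cortical_mask %dx%d foreground=%d px>\n",
              x$height, x$width, sum(x$pixels)))
  invisible(x)
}

#' Load a 0/255 (or 0/1) PNG mask
#'
#' @param path path to a PNG mask file.
#' @return A [cortical_mask].
#' @export
load_mask <- function(path) {
  m <- read_gray_image(path)
  cortical_mask((m > 127) + 0L)
}

VALID_LABELS <- c("normal", "osteopenia", "osteoporosis")

#' Read a dataset manifest CSV
#'
#' The manifest pairs each subject's left/right ROI images with a BMD class
#' label and, optionally, ground-truth masks. Columns:
#' `subject_id,left_roi,right_roi,label[,left_mask,right_mask]`. Paths are
#' resolved relative to the manifest's directory.
#'
#' @param path CSV file path.
#' @return A data.frame of class `dataset_manifest` with absolute paths and a
#'   factor `label`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "left_roi", "right_roi", "label")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$subject_id)) {
    dup <- df$subject_id[duplicated(df$subject_id)][1]
    stop("duplicate subject_id in manifest: ", dup)
  }
  bad <- which(!df$label %in% VALID_LABELS)
  if (length(bad))
    stop(sprintf("row %d: unknown label '%s' (expected %s)", bad[1],
                 df$label[bad[1]], paste(VALID_LABELS, collapse = "/")))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(is.na(p) | p == "", NA_character_,
                                file.path(base, p))
  for (col in intersect(c("left_roi", "right_roi", "left_mask", "right_mask"),
                        names(df))) {
    df[[col]] <- resolve(df[[col]])
    missing <- which(!is.na(df[[col]]) & !file.exists(df[[col]]))
    if (length(missing))
      stop(sprintf("row %d: file not found for %s: %s", missing[1], col,
                   df[[col]][missing[1]]))
  }
  df$label <- factor(df$label, levels = VALID_LABELS)
  message(sprintf("manifest: %d subjects (%s)", nrow(df),
                  paste(sprintf("%s=%d", VALID_LABELS,
                                tabulate(df$label, 3L)), collapse = ", ")))
  class(df) <- c("dataset_manifest", "data.frame")
  df
}
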