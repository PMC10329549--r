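# Phantom ROI generator: class-conditional synthetic ROI pairs with ground
# truth. Each phantom shows a bright, gently curved cortical band of known
# constant perpendicular thickness over band-passed trabecular texture, with
# class-dependent porosity (punched dark holes), an illumination gradient
# and pixel noise — the statistical structure the pipeline assumes, with
# known ground truth to recover.

#' WHO T-score class binning
#'
#' `t <= -2.5` is osteoporosis (the cut itself included), `-2.5 < t < -1`
#' osteopenia, `t >= -1` normal.
#'
#' @param t T-score in SD units.
#' @return `"normal"`, `"osteopenia"` or `"osteoporosis"`.
#' @export
label_from_tscore <- function(t) {
  if (!is.finite(t)) stop("T-score must be finite")
  if (t <= -2.5) "osteoporosis" else if (t < -1) "osteopenia" else "normal"
}

# Class-conditional generator parameters. Width means/SDs (px) follow the
# per-class, per-side average-width statistics of the reference population;
# band gray and porosity are chosen to give cortical/trabecular contrast and
# a causal texture signal ordered normal > osteopenia > osteoporosis.
PHANTOM_DEFAULTS <- list(
  normal = list(
    right = list(width_mean = 27.7, width_sd = 6.4),
    left  = list(width_mean = 26.6, width_sd = 5.2),
    band_gray_mean = 190, band_gray_sd = 8,
    porosity_hole_rate = 0.5, hole_radius_range = c(1, 3)),
  osteopenia = list(
    right = list(width_mean = 25.7, width_sd = 5.6),
    left  = list(width_mean = 24.9, width_sd = 4.4),
    band_gray_mean = 178, band_gray_sd = 8,
    porosity_hole_rate = 1.5, hole_radius_range = c(1, 3)),
  osteoporosis = list(
    right = list(width_mean = 22.9, width_sd = 4.1),
    left  = list(width_mean = 21.6, width_sd = 4.4),
    band_gray_mean = 166, band_gray_sd = 8,
    porosity_hole_rate = 3.0, hole_radius_range = c(1, 3)))

#' Generator parameters for a class
#'
#' @param label class label.
#' @return List of per-side width distributions, band gray distribution and
#'   porosity parameters.
#' @export
class_params <- function(label = VALID_LABELS) {
  label <- match.arg(label)
  c(PHANTOM_DEFAULTS[[label]], list(label = label))
}

# Render one side: band of constant perpendicular thickness `w` under a mild
# degree-2 border polynomial. Returns list(image matrix, mask matrix, w).
render_side <- function(params_side, band_gray, porosity_rate, radius_range,
                        size, noise_sd, illumination) {
  H <- size; W <- size
  w <- NA_real_
  for (try in 1:100) {
    cand <- stats::rnorm(1, params_side$width_mean, params_side$width_sd)
    if (cand >= 5) { w <- cand; break }
  }
  if (!is.finite(w)) stop("width sample <= 0 after truncation retries")
  cx <- (W - 1) / 2
  a <- stats::runif(1, -0.002, 0.002)
  b <- stats::runif(1, -0.2, 0.2)
  r0 <- stats::runif(1, 0.40, 0.55) * H
  cols0 <- 0:(W - 1)
  slope <- 2 * a * (cols0 - cx) + b
  vert <- w * sqrt(1 + slope^2)           # vertical extent giving
                                          # perpendicular thickness w
  upper <- a * (cols0 - cx)^2 + b * (cols0 - cx) + r0
  # keep the whole band inside the frame with a safety border
  overflow <- max(upper + vert) - (H - 3)
  if (overflow > 0) upper <- upper - overflow
  underflow <- 2 - min(upper)
  if (underflow > 0) upper <- upper + underflow
  rows0 <- matrix(0:(H - 1), H, W)
  U <- matrix(upper, H, W, byrow = TRUE)
  V <- matrix(vert, H, W, byrow = TRUE)
  mask <- (rows0 >= U) & (rows0 < U + V)
  storage.mode(mask) <- "integer"

  # trabecular background: band-passed Gaussian noise around gray 80
  trab <- matrix(stats::rnorm(H * W), H, W)
  trab <- binomial_smooth(binomial_smooth(trab))
  trab <- 80 + trab / max(stats::sd(trab), 1e-9) * 12
  img <- trab
  img[mask == 1L] <- band_gray

  # porosity: dark circular holes punched into the band
  band_len <- sum(sqrt(1 + slope^2))      # arc length of the border
  n_holes <- stats::rpois(1, porosity_rate * band_len / 100)
  hole_gray <- max(band_gray - 90, 30)
  if (n_holes > 0) {
    for (h in seq_len(n_holes)) {
      hc <- stats::runif(1, 0, W - 1)
      depth <- stats::runif(1, 0.15, 0.85)
      ci <- round_half_up(hc) + 1
      hr0 <- upper[ci] + depth * vert[ci]
      rad <- stats::runif(1, radius_range[1], radius_range[2])
      rr <- pmax(1, round_half_up(hr0 - rad) + 1):pmin(H, round_half_up(hr0 + rad) + 1)
      cc <- pmax(1, round_half_up(hc - rad) + 1):pmin(W, round_half_up(hc + rad) + 1)
      for (r in rr) for (c2 in cc) {
        if ((r - 1 - hr0)^2 + (c2 - 1 - hc)^2 <= rad^2 && mask[r, c2] == 1L)
          img[r, c2] <- hole_gray
      }
    }
  }

  # uneven illumination: linear gradient of +/- `illumination` gray levels
  if (illumination > 0) {
    phi <- stats::runif(1, 0, 2 * pi)
    gcol <- (cols0 / (W - 1) - 0.5) * cos(phi)
    grow <- ((0:(H - 1)) / (H - 1) - 0.5) * sin(phi)
    img <- img + 2 * illumination * (outer(grow, gcol, `+`))
  }
  img <- img + stats::rnorm(H * W, 0, noise_sd)
  img <- pmin(pmax(round_half_up(img), 0), 255)
  list(image = img, mask = mask, width = w)
}

#' Generate one phantom ROI pair with ground truth
#'
#' Deterministic for a fixed seed. Each side gets its own sampled target
#' width (truncated at 5 px), border polynomial, porosity holes,
#' illumination gradient and pixel noise; the ground-truth mask is rendered
#' before any noise is added.
#'
#' @param label class label.
#' @param params generator parameters, default [class_params]`(label)`.
#' @param seed integer seed.
#' @param size ROI side length (default 128).
#' @param noise_sd Gaussian pixel noise SD in gray levels (default 4).
#' @param illumination illumination gradient half-range in gray levels
#'   (default 15; 0 disables).
#' @param subject_id identifier embedded in the ROIs.
#' @return A `phantom_record`: `left_roi`, `right_roi` ([roi_image]),
#'   `left_mask`, `right_mask` ([cortical_mask]), `true_widths` (per side
#'   min/max/avg, equal for the constant-thickness band), `label`,
#'   `params_used`, `seed`.
#' @export
generate_phantom_pair <- function(label, params = class_params(label),
                                  seed = 1L, size = 128L, noise_sd = 4,
                                  illumination = 15,
                                  subject_id = sprintf("phantom_%s_%d", label, seed)) {
  label <- match.arg(label, VALID_LABELS)
  rec <- with_local_seed(seed, {
    out <- list()
    for (side in c("right", "left")) {
      bg <- stats::rnorm(1, params$band_gray_mean, params$band_gray_sd)
      out[[side]] <- render_side(params[[side]], bg,
                                 params$porosity_hole_rate,
                                 params$hole_radius_range,
                                 size, noise_sd, illumination)
    }
    out
  })
  tw <- function(s) c(min = rec[[s]]$width, max = rec[[s]]$width,
                      avg = rec[[s]]$width)
  structure(list(
    right_roi = roi_image(rec$right$image, "right", paste0(subject_id, "_R")),
    left_roi = roi_image(rec$left$image, "left", paste0(subject_id, "_L")),
    right_mask = cortical_mask(rec$right$mask),
    left_mask = cortical_mask(rec$left$mask),
    true_widths = list(right = tw("right"), left = tw("left")),
    label = label, params_used = params, seed = seed,
    subject_id = subject_id), class = "phantom_record")
}

#' Generate a phantom dataset on disk
#'
#' Writes per-subject ROI and ground-truth mask PNGs plus a `manifest.csv`
#' in the layout the pipeline consumes. Default class counts follow the
#' reference population (68 normal, 38 osteopenia, 17 osteoporosis).
#' Per-record seeds are drawn once from the master seed, so the dataset is
#' reproducible as a whole.
#'
#' @param n_normal,n_osteopenia,n_osteoporosis class counts.
#' @param seed master seed.
#' @param out_dir output directory (created if needed).
#' @param size,noise_sd,illumination passed to [generate_phantom_pair].
#' @return The dataset manifest (via [read_manifest]).
#' @export
generate_dataset <- function(n_normal = 68L, n_osteopenia = 38L,
                             n_osteoporosis = 17L, seed = 1L, out_dir,
                             size = 128L, noise_sd = 4, illumination = 15) {
  counts <- c(normal = n_normal, osteopenia = n_osteopenia,
              osteoporosis = n_osteoporosis)
  if (any(counts < 0) || sum(counts) < 1) stop("need a positive total count")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  labels <- rep(names(counts), counts)
  rec_seeds <- with_local_seed(seed,
                               sample.int(.Machine$integer.max - 1L,
                                          length(labels)))
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sid <- sprintf("s%03d", i)
    rec <- generate_phantom_pair(labels[i], seed = rec_seeds[i], size = size,
                                 noise_sd = noise_sd,
                                 illumination = illumination,
                                 subject_id = sid)
    files <- c(R = paste0(sid, "_R.png"), L = paste0(sid, "_L.png"),
               Rm = paste0(sid, "_R_mask.png"), Lm = paste0(sid, "_L_mask.png"))
    write_roi(rec$right_roi, file.path(out_dir, files["R"]))
    write_roi(rec$left_roi, file.path(out_dir, files["L"]))
    write_roi(rec$right_mask, file.path(out_dir, files["Rm"]))
    write_roi(rec$left_mask, file.path(out_dir, files["Lm"]))
    rows[[i]] <- data.frame(subject_id = sid, left_roi = files[["L"]],
                            right_roi = files[["R"]], label = labels[i],
                            left_mask = files[["Lm"]], right_mask = files[["Rm"]],
                            true_right_avg_w = rec$true_widths$right[["avg"]],
                            true_left_avg_w = rec$true_widths$left[["avg"]])
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest_path, row.names = FALSE)
  suppressMessages(read_manifest(manifest_path))
}
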