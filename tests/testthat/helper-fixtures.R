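# Fixtures built in code: bands, rotated rectangles, synthetic feature
# tables. All deterministic (explicit seeds).

# Horizontal band mask: rows [top, top + thickness) foreground (0-based).
band_mask <- function(h = 128, w = 128, top = 50, thickness = 20) {
  m <- matrix(0L, h, w)
  m[(top + 1):(top + thickness), ] <- 1L
  cortical_mask(m)
}

# Rasterized rectangle of given perpendicular `thickness`, long axis at
# `angle_deg`, centred in an h x w grid. A pixel (row, col) is foreground if
# its centre lies inside the rotated rectangle.
rotated_rect_mask <- function(angle_deg, thickness, length = 110,
                              h = 128, w = 128) {
  th <- angle_deg * pi / 180
  u <- c(cos(th), sin(th))        # long-axis direction in (col, row)
  nvec <- c(-sin(th), cos(th))    # perpendicular
  cr <- (h - 1) / 2; cc <- (w - 1) / 2
  cols <- matrix(0:(w - 1), h, w, byrow = TRUE) - cc
  rows <- matrix(0:(h - 1), h, w) - cr
  along <- cols * u[1] + rows * u[2]
  across <- cols * nvec[1] + rows * nvec[2]
  cortical_mask((abs(along) <= length / 2 & abs(across) <= thickness / 2) + 0L)
}

# Three well-separated Gaussian clusters in the canonical 8-feature layout.
separable_features <- function(n_per_class = 40, sd = 0.3, seed = 1) {
  centers <- list(normal = c(28, 33, 30, 27, 32, 29, 52, 47),
                  osteopenia = c(21, 26, 23, 20, 25, 22, 44, 41),
                  osteoporosis = c(14, 19, 16, 13, 18, 15, 36, 33))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- lapply(names(centers), function(lab) {
    x <- matrix(rnorm(n_per_class * 8, mean = rep(centers[[lab]],
                                                  each = n_per_class),
                      sd = sd), n_per_class, 8)
    colnames(x) <- c("r_min_w", "r_max_w", "r_avg_w",
                     "l_min_w", "l_max_w", "l_avg_w",
                     "r_texture", "l_texture")
    cbind(as.data.frame(x), label = lab)
  })
  do.call(rbind, rows)
}

# Piecewise-constant band image with optional Gaussian noise.
band_image <- function(h = 128, w = 128, top = 50, thickness = 20,
                       band_gray = 180, bg_gray = 60, noise_sd = 0,
                       seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- matrix(bg_gray, h, w)
  m[(top + 1):(top + thickness), ] <- band_gray
  if (noise_sd > 0) m <- m + rnorm(h * w, 0, noise_sd)
  pmin(pmax(m, 0), 255)
}

# Rotate a matrix 90 degrees counterclockwise, and its inverse.
rot90 <- function(m) t(m)[nrow(t(m)):1, , drop = FALSE]
unrot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
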