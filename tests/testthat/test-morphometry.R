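test_that("upper border takes the topmost foreground pixel per column", {
  full <- cortical_mask(matrix(1L, 40, 40))
  ub <- upper_border(full)
  expect_equal(ub$row, rep(0, 40))
  expect_equal(ub$col, 0:39)

  band <- band_mask(top = 100, thickness = 20)
  expect_true(all(upper_border(band)$row == 100))

  holey <- band_mask(h = 64, w = 64, top = 20, thickness = 10)$pixels
  holey[, 8] <- 0L                      # empty column 7 (0-based)
  ub2 <- upper_border(cortical_mask(holey))
  expect_false(7 %in% ub2$col)
  expect_equal(nrow(ub2), 63)

  expect_error(upper_border(cortical_mask(matrix(0L, 40, 40))), "empty mask")
})

test_that("polynomial degree selection recovers exact low-order borders", {
  col <- 0:99
  quad <- data.frame(col = col, row = 0.01 * col^2 + 50)
  fit <- fit_border_polynomial(quad, 1:5)
  expect_equal(fit$degree, 2L)
  expect_equal(fit$coefficients, c(0.01, 0, 50), tolerance = 1e-6)
  expect_lt(fit$sse, 1e-10)
  expect_equal(fit$domain, c(0, 99))

  line <- data.frame(col = col, row = 0.3 * col + 10)
  expect_equal(fit_border_polynomial(line, 1:5)$degree, 1L)

  expect_error(fit_border_polynomial(quad[1:3, ], 5), "at least 6")

  # selected degree never has larger CV error than any rejected candidate
  set.seed(3)
  noisy <- data.frame(col = col, row = 0.005 * col^2 + rnorm(100, sd = 2))
  f <- fit_border_polynomial(noisy, 1:5)
  expect_true(all(f$cv_error[paste0("degree", f$degree)] <=
                  f$cv_error + 1e-12))
})

test_that("width profile measures flat bands to sub-pixel accuracy", {
  mask <- band_mask(top = 100, thickness = 20)
  curve <- fit_border_polynomial(upper_border(mask), 1:5)
  prof <- width_profile(mask, curve, margin_frac = 0.1, step = 1)
  expect_true(all(abs(prof$samples$width - 20) <= 0.5))
  expect_lte(prof$max_width - prof$min_width, 0.51)
  expect_equal(prof$avg_width, 20, tolerance = 0.5)
  # summary stats are recomputable from the samples
  expect_equal(prof$min_width, min(prof$samples$width))
  expect_equal(prof$avg_width, mean(prof$samples$width))
})

test_that("width is measured perpendicular to the border, not as column height", {
  # 30-degree tilt: perpendicular thickness 20, column height 20/cos30 = 23.1
  mask <- rotated_rect_mask(30, 20)
  curve <- fit_border_polynomial(upper_border(mask), 1:5)
  prof <- width_profile(mask, curve, margin_frac = 0.15, step = 1)
  expect_equal(prof$avg_width, 20, tolerance = 1.0)
  expect_lt(abs(prof$avg_width - 20), abs(prof$avg_width - 20 / cos(pi / 6)))
})

test_that("perpendicular width recovery holds within 5% across angles and thicknesses", {
  for (ang in c(0, 10, 20, 30, 40)) {
    for (thick in c(10, 20, 30)) {
      mask <- rotated_rect_mask(ang, thick)
      curve <- fit_border_polynomial(upper_border(mask), 1:5)
      prof <- width_profile(mask, curve, margin_frac = 0.15, step = 1)
      expect_lt(abs(prof$avg_width - thick) / thick, 0.05,
                label = sprintf("angle %d thickness %d: avg %.2f",
                                ang, thick, prof$avg_width))
    }
  }
})

test_that("width profile rejects degenerate geometry", {
  mask <- band_mask(top = 100, thickness = 20)
  curve <- fit_border_polynomial(upper_border(mask), 1:5)
  # a curve far above the band starts every march on background
  off <- curve; off$coefficients <- c(0, 5)
  expect_error(width_profile(mask, off), "too sparse")
  one_col <- matrix(0L, 64, 64); one_col[10:30, 5] <- 1L
  expect_error(measure_side(NULL, cortical_mask(one_col)))
})

test_that("widths ignore gray offsets and phantom round trips stay within 10%", {
  rec <- generate_phantom_pair("osteopenia", seed = 21)
  m <- measure_side(rec$right_roi, rec$right_mask)
  tw <- rec$true_widths$right[["avg"]]
  expect_lt(abs(m$avg - tw) / tw, 0.10)
  # constant perpendicular thickness: narrow spread on the ground-truth mask
  expect_lte(m$max - m$min, 2)
  # widths are a mask-only computation
  shifted <- roi_image(pmin(rec$right_roi$pixels + 20, 255), "right")
  m2 <- measure_side(shifted, rec$right_mask)
  expect_equal(m2$avg, m$avg)
})
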