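test_that("T-score binning follows the WHO cuts with the stated boundary handling", {
  expect_equal(label_from_tscore(-2.5), "osteoporosis")
  expect_equal(label_from_tscore(-3.7), "osteoporosis")
  expect_equal(label_from_tscore(-1.7), "osteopenia")
  expect_equal(label_from_tscore(-1), "normal")
  expect_equal(label_from_tscore(0), "normal")
  expect_error(label_from_tscore(NaN), "finite")
})

test_that("phantom pairs are deterministic and carry consistent ground truth", {
  a <- generate_phantom_pair("osteopenia", seed = 99)
  b <- generate_phantom_pair("osteopenia", seed = 99)
  expect_identical(a$right_roi$pixels, b$right_roi$pixels)
  expect_identical(a$left_mask$pixels, b$left_mask$pixels)
  expect_identical(a$true_widths, b$true_widths)
  c2 <- generate_phantom_pair("osteopenia", seed = 100)
  expect_false(identical(a$right_roi$pixels, c2$right_roi$pixels))
  # band is brighter than background in expectation
  expect_gt(mean(a$right_roi$pixels[a$right_mask$pixels == 1]),
            mean(a$right_roi$pixels[a$right_mask$pixels == 0]))
})

test_that("a requested width is rendered into the mask within a pixel", {
  p <- class_params("normal")
  p$right$width_mean <- 25; p$right$width_sd <- 0
  p$left$width_mean <- 25; p$left$width_sd <- 0
  for (s in 1:3) {
    rec <- generate_phantom_pair("normal", params = p, seed = s)
    m <- rec$right_mask$pixels
    # independent column-count oracle: per-column pixel count divided by the
    # local slope factor estimated from the mask's own upper border
    tops <- apply(m, 2, function(col) which(col > 0)[1])
    slopes <- (c(tops[-1], tops[length(tops)]) -
               c(tops[1], tops[-length(tops)])) / 2
    per_col <- colSums(m) / sqrt(1 + slopes^2)
    expect_equal(mean(per_col), 25, tolerance = 1)
    expect_equal(rec$true_widths$right[["avg"]], 25)
  }
})

test_that("generated widths order the classes as expected over many draws", {
  w_of <- function(lab, seeds) vapply(seeds, function(s)
    generate_phantom_pair(lab, seed = s)$true_widths$right[["avg"]],
    numeric(1))
  seeds <- 1:200
  expect_gt(mean(w_of("normal", seeds)), mean(w_of("osteoporosis", seeds)))
})

test_that("width and texture feature distributions order the three classes", {
  measure <- function(lab, seeds) {
    t(vapply(seeds, function(s) {
      rec <- generate_phantom_pair(lab, seed = s)
      norm <- normalize_intensity(rec$right_roi)
      c(w = rec$true_widths$right[["avg"]],
        tex = mean_cortical_intensity(norm, rec$right_mask))
    }, numeric(2)))
  }
  seeds <- 1:100
  nor <- measure("normal", seeds)
  pen <- measure("osteopenia", seeds)
  por <- measure("osteoporosis", seeds)
  expect_gt(mean(nor[, "w"]), mean(pen[, "w"]))
  expect_gt(mean(pen[, "w"]), mean(por[, "w"]))
  expect_gt(mean(nor[, "tex"]), mean(pen[, "tex"]))
  expect_gt(mean(pen[, "tex"]), mean(por[, "tex"]))
})

test_that("easy-mode phantoms are recovered end to end", {
  # low noise, no illumination gradient: segmentation and width recovery
  # should be nearly exact
  for (s in 1:4) {
    rec <- generate_phantom_pair(c("normal", "osteoporosis")[s %% 2 + 1],
                                 seed = 50 + s, noise_sd = 1,
                                 illumination = 0)
    pred <- segment_cortical(rec$right_roi)
    expect_lte(misclassification_error(rec$right_mask, pred), 0.05)
    w <- measure_side(rec$right_roi, pred)$avg
    tw <- rec$true_widths$right[["avg"]]
    expect_lte(abs(w - tw) / tw, 0.05)
  }
})

test_that("dataset generation writes a loadable manifest with the right counts", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(1, 1, 1, seed = 5, out_dir = dir)
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(man$left_roi, man$right_roi,
                              man$left_mask, man$right_mask)))
  expect_equal(as.character(man$label),
               c("normal", "osteopenia", "osteoporosis"))
  # round trip: a stored mask equals the in-memory ground truth it came from
  m <- load_mask(man$right_mask[1])
  expect_true(all(m$pixels %in% c(0L, 1L)))
  expect_error(generate_dataset(0, 0, 0, seed = 1, out_dir = dir),
               "positive total")
})
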