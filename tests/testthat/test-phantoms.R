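test_that("phantom generation is deterministic under a fixed seed", {
  a <- make_jaw_phantom(shape = 128L, seed = 7L)
  b <- make_jaw_phantom(shape = 128L, seed = 7L)
  expect_identical(a$image_truth, b$image_truth)
  expect_identical(a$image_with_metal, b$image_with_metal)
  expect_identical(a$tissue_labels, b$tissue_labels)
  c <- make_jaw_phantom(shape = 128L, seed = 8L)
  expect_false(identical(a$image_truth, c$image_truth))
  h1 <- make_hip_phantom(shape = 128L, seed = 3L)
  h2 <- make_hip_phantom(shape = 128L, seed = 3L)
  expect_identical(h1$image_with_metal, h2$image_with_metal)
})

test_that("labels partition the grid and metal fields are consistent", {
  for (ph in list(small_jaw(), small_hip())) {
    lv <- attr(ph$tissue_labels, "levels")
    expect_true(all(ph$tissue_labels %in% lv))
    # metal mask is exactly the metal-labeled set
    expect_identical(ph$metal_mask == 1L, ph$tissue_labels == lv[["metal"]])
    # metal pixels carry metal_hu; elsewhere the truth is untouched
    expect_true(all(ph$image_with_metal[ph$metal_mask == 1L] == ph$metal_hu))
    expect_identical(ph$image_with_metal[ph$metal_mask == 0L],
                     ph$image_truth[ph$metal_mask == 0L])
    # truth never reaches the metal segmentation threshold
    expect_lt(max(ph$image_truth), 2500)
    expect_true(all(is.finite(ph$image_truth)))
  }
})

test_that("empty metal spec yields a metal-free phantom", {
  ph <- make_jaw_phantom(shape = 128L, metal_spec = list(), seed = 7L)
  expect_true(all(ph$metal_mask == 0L))
  expect_identical(ph$image_with_metal, ph$image_truth)
  expect_message(m <- segment_metal(ph$image_truth), "empty")
  expect_true(all(m == 0L))
})

test_that("default jaw phantom has two metal components; hip has two inserts", {
  ph <- make_jaw_phantom(shape = 256L, seed = 7L)
  expect_equal(count_components(ph$metal_mask), 2L)
  hp <- make_hip_phantom(shape = 256L, seed = 7L)
  expect_equal(count_components(hp$metal_mask), 2L)
})

test_that("hip phantom has sane composition: air fraction and HU modes", {
  ph <- small_hip()
  fr_air <- mean(ph$tissue_labels == 0L)
  expect_gt(fr_air, 0)
  expect_lt(fr_air, 1)
  # histogram modes at -1000 (air) and near 0 (soft tissue)
  h <- hist(ph$image_truth, breaks = seq(-1050, 1550, by = 100), plot = FALSE)
  top2 <- order(h$counts, decreasing = TRUE)[1:2]
  modes <- sort(h$mids[top2])
  expect_lt(abs(modes[1] - (-1000)), 100)
  expect_lt(abs(modes[2]), 150)
})

test_that("insert_metal validates placement and rasterizes discs", {
  ph <- make_jaw_phantom(shape = 256L, metal_spec = list(), seed = 7L)
  # identity on empty spec
  expect_identical(insert_metal(ph, list()), ph)
  # a 3-pixel-radius disc: mask size within 15% of pi r^2
  r_px <- 3 * ph$pixel_spacing
  ph2 <- insert_metal(ph, list(list(center = c(0, 52), radius_mm = r_px)))
  npix <- sum(ph2$metal_mask)
  expect_lt(abs(npix - pi * 9) / (pi * 9), 0.15)
  expect_true(all(ph2$image_with_metal[ph2$metal_mask == 1L] == 3000))
  expect_identical(ph2$image_truth, ph$image_truth)
  # outside the anatomy (air) and overlap are rejected
  expect_error(insert_metal(ph, list(list(center = c(95, 95), radius_mm = 2))),
               "anatomy")
  expect_error(insert_metal(ph2, list(list(center = c(0, 52), radius_mm = 2))),
               "overlap")
  expect_error(make_jaw_phantom(shape = 32L), "64")
})

test_that("auto-placed ROIs are pure-class blocks clear of metal", {
  # the 20 x 20 pixel blocks need a 256-px grid to fit the hip anatomy
  roi_hip <- fixture("roi_hip_256", function() make_hip_phantom(shape = 256L,
                                                                seed = 7L))
  for (ph in list(small_jaw(), roi_hip)) {
    expect_gt(length(ph$rois), 0)
    for (r in ph$rois) {
      blk <- ph$tissue_labels[r$row:(r$row + r$height - 1L),
                              r$col:(r$col + r$width - 1L)]
      expect_equal(length(unique(as.integer(blk))), 1L)
      expect_true(all(blk != 3L))
      mblk <- ph$metal_mask[r$row:(r$row + r$height - 1L),
                            r$col:(r$col + r$width - 1L)]
      expect_true(all(mblk == 0L))
    }
  }
})
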