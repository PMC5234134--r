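test_that("segment_metal thresholds exactly at the given HU", {
  img <- matrix(0, 8, 8)
  img[3, 5] <- 4000
  m <- segment_metal(img, 2500)
  expect_equal(sum(m), 1L)
  expect_equal(m[3, 5], 1L)
  expect_message(m0 <- segment_metal(img * 0), "empty")
  expect_true(all(m0 == 0L))
  # on the phantom's own metal image the mask recovers the ground truth
  ph <- small_jaw()
  expect_identical(segment_metal(ph$image_with_metal), ph$metal_mask)
})

test_that("make_metal_only_image paints metal on an air background", {
  m <- matrix(0L, 6, 6); m[2, 2] <- 1L
  img <- make_metal_only_image(m)
  expect_equal(img[2, 2], 3000)
  expect_equal(sum(img == 3000), 1L)
  expect_true(all(img[m == 0L] == -1000))
  # air background converts to exactly zero attenuation
  expect_true(all(hu_to_mu(img)[m == 0L] == 0))
  expect_equal(make_metal_only_image(matrix(0L, 3, 3)),
               matrix(-1000, 3, 3))
  expect_error(make_metal_only_image(matrix(0.5, 2, 2)), "binary")
})

test_that("compute_trace flags exactly the rays through metal", {
  geom <- small_geom()
  empty <- compute_trace(make_metal_only_image(matrix(0L, 64, 64)), geom)
  expect_true(all(empty$omega == 0L))
  expect_true(all(empty$keep == 1L))

  # a centered disc subtends the same fan width at every view
  m <- matrix(0L, 64, 64)
  x <- (seq_len(64) - 32.5) * geom$pixel_spacing
  r <- sqrt(outer(x^2, x^2, `+`))
  m[r <= 15] <- 1L
  tr <- compute_trace(make_metal_only_image(m), geom)
  expect_true(all(tr$omega + tr$keep == 1L))
  per_view <- rowSums(tr$omega)
  expect_true(all(per_view >= 1))
  expect_lte(max(per_view) - min(per_view), 2)
})

test_that("prior classification follows the threshold recipe", {
  img <- matrix(c(-950, 40, 800, 20), 2, 2)
  pr <- build_prior_image(img, smooth_sigma = 0)
  expect_equal(pr$values[1, 1], -1000)   # air
  expect_equal(pr$values[2, 1], 0)       # soft
  expect_equal(pr$values[1, 2], 800)     # bone keeps its value
  expect_equal(pr$values[2, 2], 0)
  expect_equal(pr$class_map, matrix(c(0L, 1L, 2L, 1L), 2, 2))
  expect_error(build_prior_image(img, air_upper = 400, soft_upper = 300),
               "air_upper")

  # idempotence of the classification with smoothing disabled
  pr2 <- build_prior_image(pr$values, smooth_sigma = 0)
  expect_identical(pr2$class_map, pr$class_map)
  expect_identical(pr2$values, pr$values)
})

test_that("prior classification of the metal-free truth is piecewise constant", {
  ph <- small_jaw()
  pr <- build_prior_image(ph$image_truth, smooth_sigma = 0)
  # air and soft regions collapse to their class values away from boundaries
  expect_true(all(pr$values[ph$tissue_labels == 0L] == -1000))
  expect_true(all(pr$values[ph$tissue_labels == 1L] == 0))
  # bone pixels keep their HU
  bone <- ph$tissue_labels == 2L
  expect_identical(pr$values[bone], ph$image_truth[bone])
})

test_that("metal pixels are neutralized from their neighborhood before classification", {
  img <- matrix(30, 20, 20)       # soft tissue
  img[10:12, 10:12] <- 3000       # metal block
  mask <- matrix(0L, 20, 20); mask[10:12, 10:12] <- 1L
  pr <- build_prior_image(img, smooth_sigma = 0, metal_mask = mask)
  # the metal footprint takes its neighbors' class (soft -> 0 HU)
  expect_true(all(pr$values[mask == 1L] == 0))
  expect_true(all(pr$class_map[mask == 1L] == 1L))
})

test_that("prior_sinogram composes conversion and projection", {
  geom <- small_geom()
  air <- matrix(-1000, 64, 64)
  expect_equal(prior_sinogram(air, geom), matrix(0, 96, 128))
  ph <- fixture("small_jaw_64", function() make_jaw_phantom(shape = 64L, seed = 7L))
  ps <- prior_sinogram(ph$image_truth, geom)
  expect_equal(ps, forward_project(hu_to_mu(ph$image_truth), geom))
  expect_true(all(ps >= 0))
})
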