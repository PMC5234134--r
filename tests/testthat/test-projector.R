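test_that("projection of zero and nonnegative images behaves linearly", {
  geom <- small_geom()
  z <- matrix(0, 64, 64)
  expect_equal(forward_project(z, geom), matrix(0, 96, 128))
  set.seed(4)
  a <- matrix(runif(64 * 64), 64)
  b <- matrix(runif(64 * 64), 64)
  pa <- forward_project(a, geom)
  pb <- forward_project(b, geom)
  pc <- forward_project(2.5 * a - 0.75 * b, geom)
  expect_equal(pc, 2.5 * pa - 0.75 * pb, tolerance = 1e-9)
  expect_true(all(forward_project(a, geom) >= 0))
  expect_error(forward_project(matrix(0, 32, 32), geom), "shape")
})

test_that("centered disk projects to its chord length at the central ray", {
  geom <- medium_geom()
  n <- 128; sp <- geom$pixel_spacing
  x <- (seq_len(n) - (n + 1) / 2) * sp
  r <- sqrt(outer(x^2, x^2, `+`))
  img <- matrix(0, n, n)
  img[r <= 40] <- 0.01
  s <- forward_project(img, geom)
  # the two central bins straddle u = 0; their mean approximates the
  # iso ray, which crosses the disk along a full diameter at every view
  mid <- (s[, 128] + s[, 129]) / 2
  expect_equal(mean(mid), 2 * 40 * 0.01, tolerance = 0.01)
  expect_lt(sd(mid) / mean(mid), 0.01)
})

test_that("both integrators agree with the dense-sampling oracle", {
  geom <- fixture("tiny_geom", function()
    fan_geometry(n_detectors = 48L, n_views = 24L, image_shape = c(32L, 32L),
                 pixel_spacing = 200 / 32))
  set.seed(17)
  img <- gaussian_blur_ref <- matrix(runif(32 * 32), 32)
  img <- sinomar:::gaussian_blur(img, 1.2)   # smooth content
  oracle <- oracle_forward_project(img, geom)
  pj <- forward_project(img, geom, method = "joseph")
  pf <- forward_project(img, geom, method = "fine")
  scale <- max(oracle)
  expect_lt(max(abs(pj - oracle)) / scale, 0.01)
  expect_lt(max(abs(pf - oracle)) / scale, 0.01)
})

test_that("an off-center hot pixel traces the fan-beam sinusoid", {
  geom <- small_geom()
  img <- matrix(0, 64, 64)
  img[20, 45] <- 1   # row 20, col 45
  s <- forward_project(img, geom)
  n <- 64; sp <- geom$pixel_spacing
  px <- (45 - (n + 1) / 2) * sp
  py <- ((n + 1) / 2 - 20) * sp
  for (v in seq(1, geom$n_views, by = 7)) {
    hits <- which(s[v, ] > 1e-9)
    expect_gt(length(hits), 0)
    # support is one small contiguous bin range
    expect_lte(max(hits) - min(hits) + 1, length(hits) + 1)
    expect_lt(max(hits) - min(hits), 6)
    # centroid follows the geometric detector-coordinate oracle within a bin
    pred <- oracle_bin_index(
      oracle_detector_coord(px, py, geom$view_angles[v], geom), geom)
    cen <- sum(hits * s[v, hits]) / sum(s[v, hits])
    expect_lt(abs(cen - pred), 1)
  }
})

test_that("FBP is linear and inverts the projector on a smooth phantom", {
  geom <- medium_geom()
  n <- 128; sp <- geom$pixel_spacing
  x <- (seq_len(n) - (n + 1) / 2) * sp
  r <- sqrt(outer(x^2, x^2, `+`))
  img <- 0.02 * 0.5 * (1 + cos(pi * pmin(r / 60, 1)))
  s <- forward_project(img, geom)
  rec <- fbp_reconstruct(s, geom)
  fov <- r <= 0.5 * n * sp * 0.95
  rel_rmse <- sqrt(mean((rec[fov] - img[fov])^2)) / sqrt(mean(img[fov]^2))
  expect_lt(rel_rmse, 0.05)
  # linearity: zero and scaling
  expect_equal(fbp_reconstruct(matrix(0, 180, 256), geom),
               matrix(0, 128, 128))
  expect_equal(fbp_reconstruct(3 * s, geom), 3 * rec, tolerance = 1e-9)
  expect_error(fbp_reconstruct(s * NA, geom), "finite")
})

test_that("round-trip error decreases as the view count doubles", {
  n <- 128
  sp <- 200 / n
  x <- (seq_len(n) - (n + 1) / 2) * sp
  r <- sqrt(outer(x^2, x^2, `+`))
  img <- 0.02 * 0.5 * (1 + cos(pi * pmin(r / 60, 1)))
  fov <- r <= 0.5 * n * sp * 0.95
  err <- sapply(c(180L, 360L, 720L), function(nv) {
    g <- fan_geometry(n_detectors = 256L, n_views = nv,
                      image_shape = c(n, n), pixel_spacing = sp)
    rec <- fbp_reconstruct(forward_project(img, g), g)
    sqrt(mean((rec[fov] - img[fov])^2))
  })
  expect_true(all(diff(err) < 0))
})
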