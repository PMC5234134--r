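test_that("gaussian_weight evaluates the edge-stopping function", {
  expect_equal(gaussian_weight(0, 4), 1)
  expect_equal(gaussian_weight(4, 4), exp(-0.5), tolerance = 1e-12)
  expect_equal(gaussian_weight(-3.7, 2.2), gaussian_weight(3.7, 2.2))
  s <- seq(0, 20, by = 0.5)
  expect_true(all(gaussian_weight(s, 4) > 0 & gaussian_weight(s, 4) <= 1))
  expect_error(gaussian_weight(1, 0), "positive")
})

test_that("sino_gradient is the forward difference with trailing zeros", {
  x <- matrix(0, 4, 5)
  g <- sino_gradient(x)
  expect_equal(g$dv, x)
  expect_equal(g$dd, x)
  ramp <- matrix(rep(1:5, each = 4), 4)
  g <- sino_gradient(ramp)
  expect_equal(g$dd[, 1:4], matrix(1, 4, 4))
  expect_equal(g$dd[, 5], rep(0, 4))
  expect_equal(g$dv, matrix(0, 4, 5))
})

test_that("gradient and transpose satisfy the adjoint identity", {
  set.seed(21)
  for (rep in 1:25) {
    x <- matrix(rnorm(42), 6, 7)
    yv <- matrix(rnorm(42), 6, 7)
    yd <- matrix(rnorm(42), 6, 7)
    g <- sino_gradient(x)
    lhs <- sum(g$dv * yv) + sum(g$dd * yd)
    rhs <- sum(x * sino_gradient_transpose(list(dv = yv, dd = yd)))
    expect_lt(abs(lhs - rhs), 1e-10)
  }
  # transpose of the gradient of a constant is zero
  z <- sino_gradient_transpose(sino_gradient(matrix(3.3, 5, 6)))
  expect_equal(z, matrix(0, 5, 6))
})

test_that("build_weight_field maps prior gradients into (0, 1]", {
  w <- build_weight_field(matrix(2, 8, 9), delta = 4)
  expect_equal(w, matrix(1, 8, 9))
  edge <- cbind(matrix(0, 8, 4), matrix(10, 8, 5))
  w <- build_weight_field(edge, delta = 4)
  expect_true(all(w > 0 & w <= 1))
  expect_lt(w[1, 4], w[1, 2])   # sharp edge damps diffusion
})

test_that("diffusion_step reproduces the hand-computed 1-D update", {
  # (x_k - x_p) = [0, 1, 0] on one row, unit weights: the update equals
  # lambda * (grad-transpose of grad), worked out by hand below
  x_p <- matrix(0, 1, 3)
  x_k <- matrix(c(0, 1, 0), 1)
  x_base <- matrix(c(5, 5, 5), 1)
  w <- matrix(1, 1, 3)
  cfg <- diffusion_config(step_lambda = 0.03)
  # forward diff of [0,1,0]: [1,-1,0]; adjoint: [0-1, 1-(-1), -1-0] = [-1,2,-1]
  expect_equal(diffusion_step(x_base, x_k, x_p, w, cfg),
               x_base - 0.03 * matrix(c(-1, 2, -1), 1))
  # zero diffusion term when x_k equals mu * x_p
  expect_equal(diffusion_step(x_base, 0 * x_k, x_p, w, cfg), x_base)
  expect_error(diffusion_step(x_base, matrix(0, 2, 3), x_p, w, cfg), "shape")
})

test_that("pocs_project selects measured values on the keep mask bit-exactly", {
  set.seed(5)
  xt <- matrix(rnorm(20), 4, 5)
  xo <- matrix(rnorm(20), 4, 5)
  om <- matrix(rbinom(20, 1, 0.4), 4, 5)
  tr <- list(omega = om, keep = 1L - om)
  out <- pocs_project(xt, xo, tr)
  expect_identical(out[om == 0], xo[om == 0])
  expect_identical(out[om == 1], xt[om == 1])
  expect_equal(pocs_project(xt, xo, list(omega = om * 0, keep = om * 0 + 1)), xo)
  expect_equal(pocs_project(xt, xo, list(omega = om * 0 + 1, keep = om * 0)), xt)
  expect_error(pocs_project(xt, xo, list(keep = om * 0.5)), "binary")
})

test_that("momentum sequence starts at 1, follows the closed form, increases", {
  expect_equal(momentum_update(1), (1 + sqrt(5)) / 2, tolerance = 1e-12)
  t <- 1
  for (k in 1:50) {
    t2 <- momentum_update(t)
    expect_gt(t2, t)
    t <- t2
  }
  expect_error(momentum_update(0.5), "at least 1")
})

test_that("extrapolate forms the stated affine combination", {
  x1 <- matrix(2, 2, 2); x0 <- matrix(0, 2, 2)
  expect_equal(extrapolate(x1, x1, 1.7, 2.1), x1)
  expect_equal(extrapolate(x1, x0, 1, 5), x1)   # zero coefficient at t = 1
  t1 <- momentum_update(1)
  t2 <- momentum_update(t1)
  expect_equal(extrapolate(x1, x0, t1, t2),
               x1 + ((t1 - 1) / t2) * (x1 - x0))
  expect_equal(extrapolate(matrix(2, 1, 1), matrix(0, 1, 1), 1.618, 2.096)[1, 1],
               2 + (0.618 / 2.096) * 2, tolerance = 1e-3)
})

test_that("prior_energy is the quadratic whose gradient is the update term", {
  set.seed(9)
  xp <- matrix(rnorm(30), 5, 6)
  w <- matrix(runif(30, 0.2, 1), 5, 6)
  x <- matrix(rnorm(30), 5, 6)
  expect_equal(prior_energy(xp, xp, w, mu = 1), 0)
  expect_gte(prior_energy(x, xp, w, mu = 1), 0)
  # directional derivative matches <grad U, d> by central differences
  grad <- sino_gradient(x - xp)
  gU <- sino_gradient_transpose(list(dv = w * grad$dv, dd = w * grad$dd))
  for (rep in 1:5) {
    d <- matrix(rnorm(30), 5, 6)
    h <- 1e-5
    fd <- (prior_energy(x + h * d, xp, w) - prior_energy(x - h * d, xp, w)) / (2 * h)
    expect_equal(fd, sum(gU * d), tolerance = 1e-5)
  }
})

test_that("run_inpainting preserves untraced bins bit-exactly and honors fixed points", {
  set.seed(33)
  x <- matrix(runif(15 * 20, 1, 6), 15, 20)
  xp <- x + matrix(rnorm(300, 0, 0.2), 15, 20)
  om <- matrix(0L, 15, 20); om[, 8:12] <- 1L
  tr <- list(omega = om, keep = 1L - om)
  res <- run_inpainting(x, xp, tr, diffusion_config(max_iter = 400))
  expect_identical(res$sinogram[om == 0], x[om == 0])

  # empty trace: data consistency restores everything after one iteration
  tr0 <- list(omega = om * 0L, keep = om * 0L + 1L)
  res0 <- run_inpainting(x, xp, tr0)
  expect_identical(res0$sinogram, x)
  expect_identical(res0$state$k, 1L)

  # if x_ori already equals mu * x_p the iterate never changes
  resfix <- run_inpainting(xp, xp, tr, diffusion_config(mu = 1))
  expect_equal(resfix$sinogram, xp)
  expect_identical(resfix$state$k, 1L)
})

test_that("converged single-row solution solves the weighted-Laplacian system", {
  # 1x8 sinogram with a 2-bin trace: at convergence, the traced values must
  # satisfy the Dirichlet problem grad^T(w grad(x - x_p)) = 0 on the trace,
  # solved directly as a 2x2 linear system
  x <- matrix(c(4, 4.2, 9, 9.5, 4.4, 4.1, 4.3, 4.2), 1)
  xp <- matrix(c(4, 4.1, 4.0, 4.2, 4.3, 4.0, 4.2, 4.1), 1)
  om <- matrix(0L, 1, 8); om[1, 3:4] <- 1L
  tr <- list(omega = om, keep = 1L - om)
  w <- build_weight_field(xp, delta = 4)
  res <- run_inpainting(x, xp, tr,
                        diffusion_config(eta = 1e-10, max_iter = 50000))
  # direct solve for z = x - x_p on bins 3:4 with Dirichlet boundary:
  # row residual z has gradient dd_j = w_j (z_{j+1} - z_j); stationarity at
  # bins 3 and 4 of 0.5 * sum w_j (z_{j+1}-z_j)^2 gives a tridiagonal system
  z <- (x - xp)[1, ]
  A <- matrix(0, 2, 2)
  b <- numeric(2)
  # d/dz3: w2(z3-z2) - w3(z4-z3) = 0 ; d/dz4: w3(z4-z3) - w4(z5-z4) = 0
  A[1, ] <- c(w[2] + w[3], -w[3]); b[1] <- w[2] * z[2]
  A[2, ] <- c(-w[3], w[3] + w[4]); b[2] <- w[4] * z[5]
  z_sol <- solve(A, b)
  expect_equal(as.numeric(res$sinogram[1, 3:4] - xp[1, 3:4]), z_sol,
               tolerance = 1e-4)
})

test_that("energy is non-increasing without momentum at the stated step size", {
  set.seed(14)
  x <- matrix(runif(12 * 18, 1, 5), 12, 18)
  xp <- x + matrix(rnorm(216, 0, 0.5), 12, 18)
  om <- matrix(0L, 12, 18); om[, 7:11] <- 1L
  tr <- list(omega = om, keep = 1L - om)
  res <- run_inpainting(x, xp, tr,
                        diffusion_config(use_momentum = FALSE, max_iter = 300,
                                         eta = 1e-12))
  e <- res$state$energy_trace
  expect_true(all(diff(e) <= 1e-9 * max(abs(e))))
})

test_that("compiled and reference engines produce identical iterates", {
  set.seed(42)
  x <- matrix(runif(30 * 40, 0, 5), 30, 40)
  xp <- x + matrix(rnorm(1200, 0, 0.3), 30, 40)
  om <- matrix(0L, 30, 40); om[, 15:22] <- 1L
  tr <- list(omega = om, keep = 1L - om)
  for (gb in c("iterate_k", "extrapolated")) {
    cfg <- diffusion_config(max_iter = 40, eta = 1e-12, gradient_base = gb)
    a <- run_inpainting(x, xp, tr, cfg, engine = "cpp")
    b <- run_inpainting(x, xp, tr, cfg, engine = "r")
    expect_equal(a$sinogram, b$sinogram, tolerance = 1e-12)
    expect_equal(a$state$energy_trace, b$state$energy_trace, tolerance = 1e-10)
    expect_identical(a$state$k, b$state$k)
  }
})

test_that("diffusion_config validates its parameters", {
  expect_error(diffusion_config(step_lambda = 0), "positive")
  expect_error(diffusion_config(delta = -1), "positive")
  expect_error(diffusion_config(eta = 0), "positive")
  expect_error(diffusion_config(max_iter = 0), "at least 1")
  cfg <- diffusion_config()
  expect_equal(cfg$step_lambda, 0.03)
  expect_equal(cfg$delta, 4)
  expect_equal(cfg$mu, 1)
  expect_equal(cfg$eta, 1e-4)
  expect_equal(cfg$max_iter, 2000L)
})
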