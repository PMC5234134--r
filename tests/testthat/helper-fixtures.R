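# Shared fixtures, built once per test run and memoised.  Small geometries
# keep unit tests fast; the acceptance tests build full-scale runs through
# the same accessors.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small geometry: 64x64 image, 96 views x 128 detectors
small_geom <- function() fixture("small_geom", function() {
  fan_geometry(n_detectors = 128L, n_views = 96L, image_shape = c(64L, 64L),
               pixel_spacing = 200 / 64)
})

# medium geometry for round-trip style checks: 128x128 image
medium_geom <- function() fixture("medium_geom", function() {
  fan_geometry(n_detectors = 256L, n_views = 180L,
               image_shape = c(128L, 128L), pixel_spacing = 200 / 128)
})

small_jaw <- function() fixture("small_jaw", function() {
  make_jaw_phantom(shape = 128L, seed = 7L)
})

small_hip <- function() fixture("small_hip", function() {
  make_hip_phantom(shape = 128L, seed = 7L)
})

# jaw phantom + simulated dataset + pipeline intermediates at reduced scale,
# shared by the priors/baseline/diffusion tests
small_jaw_case <- function() fixture("small_jaw_case", function() {
  ph <- small_jaw()
  geom <- fan_geometry(n_detectors = 256L, n_views = 180L,
                       image_shape = dim(ph$image_truth),
                       pixel_spacing = ph$pixel_spacing)
  sim <- simulate_dataset(ph, geom)
  img_unc <- mu_to_hu(fbp_reconstruct(sim$uncorrected, geom))
  mask <- segment_metal(ph$image_with_metal)
  trace <- compute_trace(make_metal_only_image(mask), geom)
  prior <- build_prior_image(img_unc, metal_mask = mask)
  list(phantom = ph, geom = geom, sim = sim, img_unc = img_unc,
       mask = mask, trace = trace, prior = prior,
       prior_sino = prior_sinogram(prior, geom))
})

# dense-sampling line-integral oracle, independent of the C++ projectors:
# integrates a bilinearly interpolated image along each source-bin ray at a
# step of 1/10 pixel spacing
oracle_forward_project <- function(image, geom, step = geom$pixel_spacing / 10) {
  nr <- nrow(image); nc <- ncol(image)
  sp <- geom$pixel_spacing
  sample_img <- function(x, y) {
    jf <- x / sp + 0.5 * (nc - 1)
    ifr <- 0.5 * (nr - 1) - y / sp
    j0 <- floor(jf); i0 <- floor(ifr)
    fj <- jf - j0; fi <- ifr - i0
    val <- 0
    for (di in 0:1) for (dj in 0:1) {
      i <- i0 + di; j <- j0 + dj
      ok <- i >= 0 & i < nr & j >= 0 & j < nc
      wgt <- (if (di == 1) fi else 1 - fi) * (if (dj == 1) fj else 1 - fj)
      v <- numeric(length(x))
      v[ok] <- image[cbind(i[ok] + 1, j[ok] + 1)]
      val <- val + wgt * v
    }
    val
  }
  out <- matrix(0, geom$n_views, geom$n_detectors)
  rmax <- 0.5 * sp * sqrt(nr^2 + nc^2)
  for (v in seq_len(geom$n_views)) {
    b <- geom$view_angles[v]
    sx <- geom$source_to_iso * cos(b); sy <- geom$source_to_iso * sin(b)
    for (d in seq_len(geom$n_detectors)) {
      u <- (d - (geom$n_detectors + 1) / 2) * geom$detector_bin_width
      px <- sx - geom$source_to_detector * cos(b) - u * sin(b)
      py <- sy - geom$source_to_detector * sin(b) + u * cos(b)
      dl <- sqrt((px - sx)^2 + (py - sy)^2)
      dx <- (px - sx) / dl; dy <- (py - sy) / dl
      bq <- sx * dx + sy * dy
      disc <- bq^2 - (sx^2 + sy^2 - rmax^2)
      if (disc <= 0) next
      t0 <- -bq - sqrt(disc); t1 <- -bq + sqrt(disc)
      nstep <- ceiling((t1 - t0) / step)
      h <- (t1 - t0) / nstep
      tt <- t0 + (seq_len(nstep) - 0.5) * h
      out[v, d] <- sum(sample_img(sx + tt * dx, sy + tt * dy)) * h
    }
  }
  out
}

# expected detector coordinate (virtual, at iso) of a point (x, y) at view b
oracle_detector_coord <- function(x, y, b, geom) {
  D <- geom$source_to_iso
  U <- D - (x * cos(b) + y * sin(b))
  D * (-x * sin(b) + y * cos(b)) / U
}

# detector bin index (1-based, fractional) for a virtual detector coordinate
oracle_bin_index <- function(up, geom) {
  du <- geom$detector_bin_width * geom$source_to_iso / geom$source_to_detector
  up / du + (geom$n_detectors + 1) / 2
}

# label connected components of a binary matrix by flood fill (4-neighbour)
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (s in which(mask == 1)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    nr <- nrow(mask)
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      i <- (q - 1L) %% nr + 1L; j <- (q - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] >= 1 && nb[1] <= nr && nb[2] >= 1 && nb[2] <= ncol(mask)) {
          qq <- (nb[2] - 1L) * nr + nb[1]
          if (mask[qq] == 1 && lab[qq] == 0L) { lab[qq] <- cur; queue <- c(queue, qq) }
        }
      }
    }
  }
  cur
}
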