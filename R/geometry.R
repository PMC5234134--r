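#' Fan-beam acquisition geometry
#'
#' Describes a single-slice fan-beam CT scanner with a flat, equispaced
#' detector, binding image space to sinogram space. The image is centred on
#' the isocenter with pixel-centre coordinates; the column index increases
#' with x and the row index increases downward (decreasing y). View angles
#' are uniformly spaced over \code{angular_range} without a duplicate
#' endpoint; the source for view angle \eqn{\beta} sits at
#' \eqn{(D\cos\beta, D\sin\beta)} with \eqn{D} = \code{source_to_iso}.
#'
#' @param n_detectors Number of detector channels (default 1024).
#' @param n_views Number of angular samples (default 720).
#' @param angular_range Angular span of the orbit in degrees (default 360).
#' @param source_to_iso Source-to-isocenter distance in mm.
#' @param source_to_detector Source-to-detector distance in mm.
#' @param detector_bin_width Detector bin width in mm. If \code{NULL}, the
#'   width is chosen so that the fan covers the inscribed field-of-view
#'   circle of the image with a 10 percent angular margin.
#' @param image_shape Integer vector of length 2, image rows and columns
#'   (default \code{c(512, 512)}).
#' @param pixel_spacing Pixel size in mm/pixel. The default spans a
#'   200 mm x 200 mm field with the default 512 x 512 grid.
#'
#' @return An object of class \code{fan_geometry}: a list with the fields
#'   above plus \code{view_angles} (radians).
#' @export
fan_geometry <- function(n_detectors = 1024L,
                         n_views = 720L,
                         angular_range = 360,
                         source_to_iso = 600,
                         source_to_detector = 1100,
                         detector_bin_width = NULL,
                         image_shape = c(512L, 512L),
                         pixel_spacing = 200 / 512) {
  n_detectors <- as.integer(n_detectors)
  n_views <- as.integer(n_views)
  image_shape <- as.integer(rep(image_shape, length.out = 2))
  stopifnot(n_detectors >= 2L, n_views >= 2L)
  if (!(source_to_iso > 0 && source_to_detector > 0 && pixel_spacing > 0))
    stop("all geometry distances must be positive")
  if (source_to_detector <= source_to_iso)
    stop("source_to_detector must exceed source_to_iso")
  if (angular_range <= 0 || angular_range > 360)
    stop("angular_range must lie in (0, 360] degrees")
  r_fov <- fov_radius_mm(image_shape, pixel_spacing)
  if (r_fov >= source_to_iso)
    stop("field of view must fit inside the source orbit")
  if (is.null(detector_bin_width)) {
    gamma_max <- asin(min(1, 1.1 * r_fov / source_to_iso))
    detector_bin_width <- 2 * source_to_detector * tan(gamma_max) / n_detectors
  }
  if (detector_bin_width <= 0) stop("detector_bin_width must be positive")
  # fan coverage of the inscribed FOV circle, checked at construction
  u_max <- 0.5 * n_detectors * detector_bin_width
  sin_gamma_max <- sin(atan2(u_max, source_to_detector))
  if (sin_gamma_max * source_to_iso < r_fov)
    stop(sprintf(
      "detector fan (half-width %.1f mm at the detector) does not cover the %.1f mm FOV radius",
      u_max, r_fov))
  view_angles <- seq(0, angular_range * pi / 180, length.out = n_views + 1L)[seq_len(n_views)]
  structure(list(
    n_detectors = n_detectors,
    n_views = n_views,
    angular_range = angular_range,
    source_to_iso = source_to_iso,
    source_to_detector = source_to_detector,
    detector_bin_width = detector_bin_width,
    image_shape = image_shape,
    pixel_spacing = pixel_spacing,
    view_angles = view_angles
  ), class = "fan_geometry")
}

#' @export
print.fan_geometry <- function(x, ...) {
  cat("<fan_geometry>\n")
  cat(sprintf("  detector : %d bins x %.4f mm (flat, equispaced)\n",
              x$n_detectors, x$detector_bin_width))
  cat(sprintf("  views    : %d over %g deg\n", x$n_views, x$angular_range))
  cat(sprintf("  distances: source-iso %g mm, source-detector %g mm\n",
              x$source_to_iso, x$source_to_detector))
  cat(sprintf("  image    : %d x %d px, %.4f mm/px\n",
              x$image_shape[1], x$image_shape[2], x$pixel_spacing))
  invisible(x)
}

# radius (mm) of the inscribed field-of-view circle of the image grid
fov_radius_mm <- function(image_shape, pixel_spacing) {
  0.5 * min(image_shape) * pixel_spacing
}

check_image_shape <- function(image, geom) {
  if (!identical(dim(image), as.integer(geom$image_shape)))
    stop(sprintf("image shape %s does not match geometry %s",
                 paste(dim(image), collapse = "x"),
                 paste(geom$image_shape, collapse = "x")))
  invisible(TRUE)
}

check_sino_shape <- function(sino, geom) {
  if (!identical(dim(sino), c(geom$n_views, geom$n_detectors)))
    stop(sprintf("sinogram shape %s does not match geometry %dx%d",
                 paste(dim(sino), collapse = "x"), geom$n_views, geom$n_detectors))
  invisible(TRUE)
}

#' Convert Hounsfield units to linear attenuation
#'
#' Applies the affine CT-number map
#' \eqn{\mu = \mu_w (1 + \mathrm{HU}/1000)} and clamps negative attenuation
#' (HU below -1000) to zero.
#'
#' @param image Numeric matrix in Hounsfield units.
#' @param mu_water Attenuation of water in 1/mm (default 0.0206, about
#'   60 keV).
#' @return Matrix of linear attenuation coefficients, 1/mm.
#' @export
hu_to_mu <- function(image, mu_water = 0.0206) {
  if (mu_water <= 0) stop("mu_water must be positive")
  if (!all(is.finite(image))) stop("image contains non-finite values")
  pmax(mu_water * (1 + image / 1000), 0)
}

#' Convert linear attenuation to Hounsfield units
#'
#' Exact inverse of [hu_to_mu()] on its range (HU >= -1000).
#'
#' @inheritParams hu_to_mu
#' @param image Numeric matrix of attenuation coefficients, 1/mm.
#' @return Matrix in Hounsfield units.
#' @export
mu_to_hu <- function(image, mu_water = 0.0206) {
  if (mu_water <= 0) stop("mu_water must be positive")
  1000 * (image / mu_water - 1)
}

#' Fan-beam forward projection
#'
#' Computes line integrals of a 2D attenuation map along every source-to-bin
#' ray of the geometry. The default \code{"joseph"} integrator marches each
#' ray one pixel line at a time along its major axis with linear
#' interpolation along the minor axis; \code{"fine"} uses midpoint-rule
#' sampling with bilinear interpolation at step \code{step} (at most half
#' the pixel spacing). Both are linear in the image and map nonnegative
#' images to nonnegative sinograms.
#'
#' @param image Attenuation image (1/mm), matching \code{geom$image_shape}.
#' @param geom A [fan_geometry()].
#' @param method Ray integrator, \code{"joseph"} (default) or \code{"fine"}.
#' @param step Sampling step in mm for \code{method = "fine"} (default half
#'   the pixel spacing).
#' @return Sinogram matrix (\code{n_views} x \code{n_detectors}) of
#'   dimensionless line integrals.
#' @export
forward_project <- function(image, geom, method = c("joseph", "fine"),
                            step = geom$pixel_spacing / 2) {
  method <- match.arg(method)
  check_image_shape(image, geom)
  if (!all(is.finite(image))) stop("image contains non-finite values")
  if (method == "joseph")
    return(.forward_project_joseph_cpp(image, geom$pixel_spacing,
                                       geom$view_angles, geom$n_detectors,
                                       geom$source_to_iso,
                                       geom$source_to_detector,
                                       geom$detector_bin_width))
  if (step <= 0 || step > geom$pixel_spacing / 2)
    stop("step must be positive and at most half the pixel spacing")
  .forward_project_fine_cpp(image, geom$pixel_spacing, geom$view_angles,
                            geom$n_detectors, geom$source_to_iso,
                            geom$source_to_detector, geom$detector_bin_width,
                            step)
}

# Spatial-domain Ram-Lak (ramp) kernel sampled at spacing du, laid out in
# circular order for FFT convolution over n points.
ramp_kernel <- function(n, du) {
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  h <- numeric(n)
  h[k == 0] <- 1 / (4 * du^2)
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi^2 * k[odd]^2 * du^2)
  h
}

#' Fan-beam filtered backprojection
#'
#' Reconstructs an attenuation image from a fan-beam sinogram acquired with
#' a flat equispaced detector. The detector is rescaled to a virtual
#' detector through the isocenter, samples are cosine-weighted by
#' \eqn{D/\sqrt{D^2+u'^2}}, each view is ramp-filtered (Ram-Lak, FFT
#' convolution with zero padding; optional Hann apodization), and the result
#' is backprojected with the fan-beam \eqn{D^2/U^2} distance weighting. The
#' operator is linear in the sinogram.
#'
#' @param sino Sinogram matrix (\code{n_views} x \code{n_detectors}).
#' @param geom A [fan_geometry()].
#' @param filter \code{"ramp"} (default) or \code{"hann"}.
#' @return Reconstructed attenuation image (1/mm) of shape
#'   \code{geom$image_shape}.
#' @export
fbp_reconstruct <- function(sino, geom, filter = c("ramp", "hann")) {
  filter <- match.arg(filter)
  check_sino_shape(sino, geom)
  if (!all(is.finite(sino))) stop("sinogram contains non-finite values")
  D <- geom$source_to_iso
  mag <- D / geom$source_to_detector
  du <- geom$detector_bin_width * mag   # virtual detector spacing at iso
  nd <- geom$n_detectors
  up <- (seq_len(nd) - (nd + 1) / 2) * du
  # cosine ray weighting on the virtual detector
  w <- D / sqrt(D^2 + up^2)
  ws <- sweep(sino, 2, w, `*`)
  # ramp filtering by FFT convolution, zero-padded to >= 2 * nd
  npad <- 2^ceiling(log2(2 * nd))
  hf <- stats::fft(ramp_kernel(npad, du))
  if (filter == "hann") {
    f <- c(0:(npad %/% 2), (npad - npad %/% 2 - 1):1) / npad
    hf <- hf * (0.5 + 0.5 * cos(2 * pi * pmin(f, 0.5)))
  }
  pad <- matrix(0, npad, geom$n_views)
  pad[seq_len(nd), ] <- t(ws)
  filt <- Re(stats::mvfft(stats::mvfft(pad) * hf, inverse = TRUE)) / npad
  q_t <- filt[seq_len(nd), , drop = FALSE] * du   # detectors x views
  dbeta <- (geom$angular_range * pi / 180) / geom$n_views
  bp <- .backproject_cpp(q_t, geom$pixel_spacing, geom$image_shape[1],
                         geom$image_shape[2], geom$view_angles, D, du)
  # full 360-degree orbit measures every line twice
  scale <- if (geom$angular_range == 360) 0.5 else 1
  bp * dbeta * scale
}
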