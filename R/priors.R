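#' Threshold metal segmentation
#'
#' Marks pixels at or above \code{threshold} (default 2500 HU) as metal.
#'
#' @param image HU image matrix.
#' @param threshold Segmentation threshold in HU.
#' @return Binary 0/1 matrix of the image shape.
#' @export
segment_metal <- function(image, threshold = 2500) {
  if (!all(is.finite(image))) stop("image contains non-finite values")
  mask <- (image >= threshold) + 0L
  if (!any(mask == 1L))
    message("segment_metal: no pixels at or above the threshold; empty mask")
  mask
}

#' Metal-only image
#'
#' Builds the image whose forward projection delineates the metal trace:
#' metal pixels at \code{metal_hu} (default 3000 HU), all other pixels at
#' -1000 HU (air, zero attenuation).
#'
#' @param mask Binary 0/1 metal mask.
#' @param metal_hu CT value for metal pixels.
#' @return HU image matrix.
#' @export
make_metal_only_image <- function(mask, metal_hu = 3000) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  out <- matrix(-1000, nrow(mask), ncol(mask))
  out[mask == 1] <- metal_hu
  out
}

#' Metal trace in the sinogram domain
#'
#' Forward-projects the metal-only image and flags every bin whose line
#' integral exceeds \code{tol}: these are the metal-corrupted bins
#' \eqn{\Omega}. The complement H = 1 - \eqn{\Omega} marks the bins to keep.
#'
#' @param metal_only HU image from [make_metal_only_image()].
#' @param geom A [fan_geometry()].
#' @param tol Absolute threshold on line integrals (default 1e-6, the
#'   projector's numerical noise floor).
#' @param mu_water Water attenuation used for the HU conversion.
#' @return A \code{trace_mask}: list with binary matrices \code{omega} and
#'   \code{keep} (\code{omega + keep == 1} everywhere).
#' @export
compute_trace <- function(metal_only, geom, tol = 1e-6, mu_water = 0.0206) {
  p <- forward_project(hu_to_mu(metal_only, mu_water), geom)
  omega <- (p > tol) + 0L
  structure(list(omega = omega, keep = 1L - omega), class = "trace_mask")
}

#' Tissue-classified prior image
#'
#' Gaussian-smooths the input, then classifies each pixel: below
#' \code{air_upper} it becomes air (-1000 HU), below \code{soft_upper} soft
#' tissue (0 HU), and otherwise bone, which keeps its smoothed value. Metal
#' pixels carry no tissue information, so before smoothing each one is
#' replaced by the median of the non-metal pixels within a 5-pixel radius
#' (widened until non-metal neighbours are found).
#'
#' @param image Uncorrected HU image.
#' @param smooth_sigma Gaussian smoothing sigma in pixels (default 1.5; 0
#'   disables smoothing).
#' @param air_upper Air/soft threshold in HU (default -500).
#' @param soft_upper Soft/bone threshold in HU (default 350).
#' @param metal_mask Optional binary metal mask to neutralize first.
#' @return A \code{prior_image}: list with the classified \code{values} (HU)
#'   and the integer \code{class_map} (air = 0, soft = 1, bone = 2).
#' @export
build_prior_image <- function(image, smooth_sigma = 1.5, air_upper = -500,
                              soft_upper = 350, metal_mask = NULL) {
  if (!(air_upper < soft_upper)) stop("thresholds must satisfy air_upper < soft_upper")
  if (!all(is.finite(image))) stop("image contains non-finite values")
  x <- image
  if (!is.null(metal_mask) && any(metal_mask == 1))
    x <- fill_metal_neighborhood(x, metal_mask)
  x <- gaussian_blur(x, smooth_sigma)
  class_map <- matrix(2L, nrow(x), ncol(x))
  class_map[x < soft_upper] <- 1L
  class_map[x < air_upper] <- 0L
  values <- x
  values[class_map == 0L] <- -1000
  values[class_map == 1L] <- 0
  structure(list(values = values, class_map = class_map),
            class = "prior_image")
}

# replace metal pixels by the median of non-metal neighbours within `radius`
# pixels (Euclidean), widening the window if a metal blob exceeds it
fill_metal_neighborhood <- function(image, metal_mask, radius = 5L) {
  out <- image
  idx <- which(metal_mask == 1, arr.ind = TRUE)
  nr <- nrow(image); nc <- ncol(image)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    r <- radius
    repeat {
      ri <- max(1, i - r):min(nr, i + r)
      ci <- max(1, j - r):min(nc, j + r)
      d2 <- outer((ri - i)^2, (ci - j)^2, `+`)
      win <- metal_mask[ri, ci] == 0 & d2 <= r^2
      if (any(win)) break
      r <- r * 2L
    }
    out[i, j] <- median(image[ri, ci][win])
  }
  out
}

#' Forward projection of a prior image
#'
#' Converts the prior image to attenuation and projects it, yielding the
#' prior sinogram that guides the diffusion inpainting and NMAR.
#'
#' @param prior A \code{prior_image} from [build_prior_image()] (or a plain
#'   HU matrix).
#' @param geom A [fan_geometry()].
#' @param mu_water Water attenuation for the HU conversion.
#' @return Sinogram matrix.
#' @export
prior_sinogram <- function(prior, geom, mu_water = 0.0206) {
  values <- if (inherits(prior, "prior_image")) prior$values else prior
  forward_project(hu_to_mu(values, mu_water), geom)
}
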