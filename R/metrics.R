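#' Signal-to-noise ratio in decibels
#'
#' \eqn{\mathrm{SNR} = 10 \log_{10}\big(\sum u_{truth}^2 / \sum (u -
#' u_{truth})^2\big)} over the evaluated pixels. By default the metric is
#' computed over all pixels; pass \code{exclude} (typically the metal mask,
#' absent from a metal-free truth) to drop pixels from the evaluation. A
#' zero error sum is reported as \code{Inf} with a message.
#'
#' @param u Corrected image (HU matrix).
#' @param truth Ground-truth image of the same shape.
#' @param exclude Optional binary mask of pixels to exclude.
#' @return SNR in dB.
#' @export
snr_db <- function(u, truth, exclude = NULL) {
  sel <- eval_selection(u, truth, exclude)
  num <- sum(truth[sel]^2)
  den <- sum((u[sel] - truth[sel])^2)
  if (den == 0) {
    message("snr_db: zero error on the evaluated set; reporting Inf")
    return(Inf)
  }
  10 * log10(num / den)
}

#' Normalized mean absolute deviation in percent
#'
#' \eqn{\mathrm{NMAD}(\%) = 100 \sum |u - u_{truth}| / \sum |u_{truth}|}
#' over the evaluated pixels.
#'
#' @inheritParams snr_db
#' @return NMAD in percent.
#' @export
nmad_pct <- function(u, truth, exclude = NULL) {
  sel <- eval_selection(u, truth, exclude)
  den <- sum(abs(truth[sel]))
  if (den == 0) stop("truth is all zero on the evaluated set")
  100 * sum(abs(u[sel] - truth[sel])) / den
}

eval_selection <- function(u, truth, exclude) {
  if (!identical(dim(u), dim(truth))) stop("image shapes differ")
  if (is.null(exclude)) return(matrix(TRUE, nrow(u), ncol(u)))
  if (!identical(dim(exclude), dim(u))) stop("exclude mask shape differs")
  exclude == 0
}

#' Per-ROI mean and standard deviation
#'
#' Arithmetic mean and population standard deviation (divide by n) of the
#' pixel values inside each region of interest.
#'
#' @param image HU image matrix.
#' @param rois List of [roi_spec()] objects.
#' @return Data frame with one row per ROI: \code{row}, \code{col},
#'   \code{height}, \code{width}, \code{label}, \code{mean}, \code{sd}.
#' @export
roi_stats <- function(image, rois) {
  rows <- lapply(rois, function(r) {
    if (r$row + r$height - 1L > nrow(image) || r$col + r$width - 1L > ncol(image))
      stop("ROI extends outside the image")
    v <- image[r$row:(r$row + r$height - 1L), r$col:(r$col + r$width - 1L)]
    data.frame(row = r$row, col = r$col, height = r$height, width = r$width,
               label = r$label, mean = mean(v),
               sd = sqrt(mean((v - mean(v))^2)))
  })
  do.call(rbind, rows)
}
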