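#' Linear-interpolation sinogram inpainting (LI)
#'
#' For each view (sinogram row), every maximal run of metal-trace bins is
#' replaced by linear interpolation between the nearest untraced bins on
#' either side; runs touching a detector edge are filled with the nearest
#' untraced value. Untraced bins are returned bit-exactly unchanged. A fully
#' traced row is filled with zeros and reported with a warning.
#'
#' @param sino Sinogram matrix.
#' @param trace A \code{trace_mask} from [compute_trace()].
#' @return Inpainted sinogram matrix.
#' @export
li_inpaint <- function(sino, trace) {
  if (!identical(dim(sino), dim(trace$omega)))
    stop("sinogram and trace shapes differ")
  out <- sino
  full_rows <- 0L
  for (v in seq_len(nrow(sino))) {
    om <- trace$omega[v, ] == 1
    if (!any(om)) next
    if (all(om)) {
      out[v, ] <- 0
      full_rows <- full_rows + 1L
      next
    }
    keep_idx <- which(!om)
    fill_idx <- which(om)
    out[v, fill_idx] <- approx(keep_idx, sino[v, keep_idx], xout = fill_idx,
                               method = "linear", rule = 2)$y
  }
  if (full_rows > 0)
    warning(sprintf("%d fully traced views were filled with zeros", full_rows))
  out
}

#' Normalized sinogram inpainting (NMAR)
#'
#' Normalizes the sinogram by a prior sinogram, linearly interpolates the
#' trace in the normalized domain, and denormalizes: traced bins become
#' \code{li_inpaint(sino / (prior + eps))[omega] * (prior + eps)[omega]};
#' untraced bins are returned bit-exactly unchanged.
#'
#' @param sino Sinogram matrix.
#' @param prior_sino Prior sinogram of the same shape.
#' @param trace A \code{trace_mask}.
#' @param eps Stabilizer added to the prior before division; default
#'   \code{1e-6 * max(prior_sino)} so the normalize/denormalize pair is
#'   invariant under joint rescaling.
#' @return Inpainted sinogram matrix.
#' @export
nmar_inpaint <- function(sino, prior_sino, trace, eps = NULL) {
  if (!identical(dim(sino), dim(prior_sino)))
    stop("sinogram and prior shapes differ")
  if (!all(is.finite(prior_sino))) stop("prior sinogram must be finite")
  if (is.null(eps)) eps <- 1e-6 * max(prior_sino)
  if (!(eps > 0)) stop("eps must be positive")
  denom <- prior_sino + eps
  norm <- sino / denom
  norm_fill <- suppressWarnings(li_inpaint(norm, trace))
  out <- sino
  om <- trace$omega == 1
  out[om] <- norm_fill[om] * denom[om]
  out
}
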