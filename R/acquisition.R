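#' Photon-statistics noise model
#'
#' Parameters of the projection-domain acquisition model: for a line
#' integral \eqn{p}, the detected count is
#' \deqn{I = \mathrm{Poisson}\{I_0 e^{-p} + S\} + \mathrm{Normal}(0, \sigma_e^2),}
#' with incident photons \eqn{I_0} per ray, a constant scatter count
#' \eqn{S}, and additive electronic noise of variance \eqn{\sigma_e^2}. The
#' model is monoenergetic at \code{energy_keV}.
#'
#' @param I0 Incident photons per ray (e.g. 5e6 for the jaw phantom, 5e5 for
#'   the hip phantom).
#' @param scatter Scattered photons per ray (default 150).
#' @param electronic_var Electronic noise variance in counts^2 (default 10).
#' @param energy_keV Beam energy (default 60 keV; informational).
#' @param seed Integer seed controlling all sampling.
#' @return An object of class \code{noise_model}.
#' @export
noise_model <- function(I0, scatter = 150, electronic_var = 10,
                        energy_keV = 60, seed = NULL) {
  if (!(I0 > 0)) stop("I0 must be positive")
  if (scatter < 0 || electronic_var < 0)
    stop("scatter and electronic_var must be nonnegative")
  structure(list(I0 = I0, scatter = scatter,
                 electronic_var = electronic_var,
                 energy_keV = energy_keV, seed = seed),
            class = "noise_model")
}

#' Simulate detector counts from line integrals
#'
#' Draws per-bin photon counts from the [noise_model()] given a sinogram of
#' line integrals. With \code{expectation = TRUE} no sampling occurs and the
#' exact mean \eqn{I_0 e^{-p} + S} is returned.
#'
#' @param line_integrals Sinogram matrix of nonnegative line integrals.
#' @param model A [noise_model()].
#' @param expectation Return the noiseless expected counts.
#' @return Matrix of counts with the shape of \code{line_integrals}.
#' @export
simulate_counts <- function(line_integrals, model, expectation = FALSE) {
  if (!all(is.finite(line_integrals))) stop("line integrals must be finite")
  if (any(line_integrals < 0)) stop("line integrals must be nonnegative")
  lambda <- model$I0 * exp(-line_integrals) + model$scatter
  if (expectation) return(lambda)
  n <- length(lambda)
  counts <- with_local_seed(model$seed, {
    k <- rpois(n, lambda)
    if (model$electronic_var > 0)
      k <- k + rnorm(n, 0, sqrt(model$electronic_var))
    k
  })
  matrix(counts, nrow(lambda), ncol(lambda))
}

#' Convert detector counts to line integrals
#'
#' Logarithmic conversion \eqn{\hat p = \ln(I_0 / \max(I, \mathrm{floor}))}.
#' Counts at or below zero are floored (default floor 1 count) so the output
#' is always finite; a warning reports how many bins were floored. Scatter is
#' not subtracted before the log, so any scatter in the model biases
#' \eqn{\hat p} low at strongly attenuated bins.
#'
#' @param counts Matrix of detector counts.
#' @param model A [noise_model()].
#' @param floor Minimum count substituted before the log (default 1).
#' @return Sinogram matrix of estimated line integrals.
#' @export
counts_to_sinogram <- function(counts, model, floor = 1) {
  if (!all(is.finite(counts))) stop("counts must be finite")
  n_floored <- sum(counts < floor)
  if (n_floored > 0)
    warning(sprintf("%d bins at or below zero counts were floored to %g",
                    n_floored, floor))
  log(model$I0 / pmax(counts, floor))
}
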