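# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

frobenius <- function(x) sqrt(sum(x * x))

# Separable Gaussian blur with kernel truncated at 4 sigma and replicated
# (nearest) edge padding. sigma in pixels; sigma = 0 returns the input.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(m) {
    n <- nrow(m)
    idx <- outer(seq_len(n), seq(-r, r), `+`)
    idx <- pmin(pmax(idx, 1L), n)
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(k)) out <- out + k[t] * m[idx[, t], , drop = FALSE]
    out
  }
  t(blur_1d(t(blur_1d(x))))
}

# Smooth seeded random field scaled to [-1, 1]: coarse white noise,
# bilinearly upsampled to the target shape. Used for tissue texture.
smooth_noise_field <- function(shape, coarse = 16L, seed = NULL) {
  g <- with_local_seed(seed, matrix(rnorm(coarse * coarse), coarse, coarse))
  interp_rows <- function(m, n_out) {
    pos <- seq(1, nrow(m), length.out = n_out)
    lo <- pmin(floor(pos), nrow(m) - 1)
    f <- pos - lo
    m[lo, , drop = FALSE] * (1 - f) + m[lo + 1, , drop = FALSE] * f
  }
  m <- interp_rows(g, shape[1])
  m <- t(interp_rows(t(m), shape[2]))
  m / max(1e-12, max(abs(m)))
}
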