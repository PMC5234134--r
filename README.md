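# sinomar — sinogram-inpainting metal artifact reduction for fan-beam CT

Metal implants (dental fillings, hip prostheses) absorb diagnostic X-rays
almost completely. The affected projection bins are unusable, and filtered
backprojection turns them into severe bright/dark streaks that obscure the
surrounding anatomy. `sinomar` is an R package for studying this problem in
2D fan-beam CT: it simulates metal-corrupted acquisitions of seeded jaw-like
and hip-like phantoms, repairs the corrupted sinogram region, and
quantifies the result against the metal-free ground truth.

Three sinogram-completion methods are implemented behind one pipeline:

* **LI** — per-view linear interpolation across the metal trace;
* **NMAR** — normalize by a prior sinogram, interpolate, denormalize;
* **gdiff** — the package's core: accelerated gradient descent on the prior
  energy
  $U(x) = \frac12 \sum f(\|\nabla x_p\|)\,\|\nabla(x - \mu x_p)\|^2$,
  $f(s) = e^{-s^2/2\delta^2}$, with a projection-onto-convex-sets step that
  re-imposes the measured data on uncorrupted bins every iteration:

  1. $t^{k+1} = \frac12\,(1 + \sqrt{1 + 4 (t^k)^2})$
  2. $\bar x = x^k + \frac{t^k-1}{t^{k+1}}(x^k - x^{k-1})$
  3. $\tilde x = \bar x - \lambda \nabla^T f(\|\nabla x_p\|)\nabla(x^k - \mu x_p)$
  4. $x^{k+1} = \tilde x + H(x_{ori} - \tilde x)$

  with defaults $\lambda = 0.03$, $\delta = 4$, $\mu = 1$, stopping when the
  relative iterate change over the trace falls below $\eta = 10^{-4}$
  (cap 2000 iterations).

The prior sinogram $x_p$ is the forward projection of a tissue-classified
image (air → −1000 HU, soft tissue → 0 HU, bone keeps its value, after
Gaussian smoothing), built by default from an initial LI-corrected
reconstruction. Supporting machinery includes a Joseph-style fan-beam
projector and flat-detector FBP (Rcpp), a Poisson + scatter + electronic
noise acquisition model, SNR/NMAD/ROI metrics, TIFF/PNG/YAML/raw I/O, and a
small CLI (`inst/cli/sinomar.R`) with `simulate`, `correct`, `evaluate` and
`sweep` verbs.

## Worked example

```r
library(sinomar)

phantom <- make_jaw_phantom(seed = 1)   # 512^2, 200 mm FOV, two fillings
run <- run_mar(phantom, methods = c("li", "nmar", "gdiff"))
run$report
#>        method   snr_db  nmad_pct iterations metal_excluded
#> 1 uncorrected 13.31098 20.819312         NA           TRUE
#> 2          li 22.92246  5.564620         NA           TRUE
#> 3        nmar 23.82351  4.983879         NA           TRUE
#> 4       gdiff 23.65012  5.048579       1326           TRUE
```

Reading the table: the uncorrected reconstruction of this phantom is badly
streaked (SNR 13.3 dB; its pixel values deviate from the truth by 20.8% of
the truth's mean absolute value). All three completions repair most of the
damage; the diffusion method recovers ~10.3 dB over the uncorrected image,
clearly beats interpolation, and sits within 0.2 dB of NMAR on this
narrow-trace dental case (on the wide-trace hip case it leads both, by
about +2.5 dB over LI and +0.9 dB over NMAR). Metal pixels are excluded
from both metrics (the truth contains no metal); `iterations` is the count
at which the diffusion stopping rule fired, below the 2000 cap.

Each per-method result carries the corrected sinogram, the corrected image,
and (for `gdiff`) the full iteration state, e.g.
`run$results$gdiff$state$energy_trace`. Passing `out_dir =` writes every
stage (TIFF/PNG/CSV/JSON plus a manifest) to a run directory.

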