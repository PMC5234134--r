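---
title: "Gaussian-diffusion sinogram inpainting for metal artifact reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-diffusion sinogram inpainting for metal artifact reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Metal implants attenuate diagnostic X-rays so strongly that the detector
receives almost no primary photons along rays through the implant. After
logarithmic conversion these projection bins are grossly wrong, and filtered
backprojection (FBP) spreads the inconsistency across the image as bright
and dark streaks. `sinomar` simulates this corruption for 2D fan-beam CT and
repairs it in the projection (sinogram) domain, comparing three completion
strategies: linear interpolation (LI), normalized inpainting (NMAR), and a
Gaussian-diffusion method driven by a tissue-classified prior image.

# The model

Write the measured sinogram as $x_{ori}$, the set of metal-corrupted bins
(the *metal trace*) as $\Omega$, and the elementwise mask that keeps
untraced bins as $H$ ($H = 1$ off the trace, $0$ on it). The uncorrupted
projections satisfy $y = Hx$; recovering $x$ on $\Omega$ from $y$ alone is
ill-posed, so a prior energy $U(x)$ selects among the consistent
completions:

$$\hat x = \arg\min_x U(x) \quad \text{subject to } Hx = Hx_{ori}.$$

The prior is built from a *prior sinogram* $x_p$, the forward projection of
a tissue-classified version of the reconstructed image, and

$$U(x) = \tfrac12 \sum_{\text{bins}} f(\|\nabla x_p\|)\,
  \|\nabla (x - \mu x_p)\|^2 ,
\qquad f(s) = e^{-s^2 / 2\delta^2},$$

with $\nabla$ the first-order forward-difference operator along views and
detector bins and $\mu$ the prior weight. The Gaussian factor $f$ is an
edge-stopping weight: where the prior sinogram itself has a strong edge,
diffusion across that edge is suppressed, so the completion respects the
anatomy the prior predicts. The closed form of $U$ is chosen as the unique
quadratic (up to constants) whose gradient with a frozen weight field is the
update actually iterated below; this makes "minimize the prior energy"
testable (`prior_energy()` has a finite-difference test against the update
term).

Minimization alternates an accelerated gradient-descent step with a
projection onto the constraint set (POCS):

1. $t^{k+1} = \tfrac12\big(1 + \sqrt{1 + 4 (t^k)^2}\big)$
2. $\bar x = x^k + \frac{t^k - 1}{t^{k+1}} (x^k - x^{k-1})$
3. $\tilde x = \bar x - \lambda \nabla^{T} f(\|\nabla x_p\|)
   \nabla (x^k - \mu x_p)$
4. $x^{k+1} = \tilde x + H (x_{ori} - \tilde x)$

starting from $x^{-1} = x^0 = x_{ori}$, $t^0 = 1$. Step 4 restores every
untraced bin to its measured value bit-exactly, so only the trace is ever
modified. At a fixed point the weighted Laplacian of $x - \mu x_p$ vanishes
on $\Omega$: the converged trace is the weighted-harmonic extension of the
measured boundary offsets around the prior — structure inside the trace
comes from $x_p$, continuity at the trace boundary from the data. The test
suite checks this against a direct linear solve on a single-row toy
problem.

# Parameters

| parameter | symbol | default | meaning |
|---|---|---|---|
| `step_lambda` | $\lambda$ | 0.03 | gradient step; stable since the weighted Laplacian has operator norm $\le 8 \max f \le 8$, well below $2/\lambda$ |
| `delta` | $\delta$ | 4 | diffusion scale in line-integral units; small values freeze diffusion at prior edges and slow convergence drastically (the `sweep` CLI verb reproduces this) |
| `mu` | $\mu$ | 1 | prior weight in the subtraction $x - \mu x_p$ |
| `eta` | $\eta$ | $10^{-4}$ | stopping tolerance on the relative iterate change |
| `max_iter` | — | 2000 | iteration cap |
| `use_momentum` | — | on | steps 1–2 above |
| `gradient_base` | — | `iterate_k` | where the step-3 gradient is evaluated (see below) |
| `gradient_scale` | $c$ | set by `run_mar()` | unit conversion inside $f$ (see below) |
| `stop_norm` | — | `omega` | domain of the stopping norm (see below) |

Three design points deserve explanation because the algorithm statement
leaves them open:

**Gradient evaluation point.** Step 3 as written evaluates the diffusion
gradient at $x^k$ while stepping from the momentum point $\bar x$. The
default reproduces exactly that. The standard accelerated-gradient variant
evaluates the gradient at $\bar x$; it is available as
`gradient_base = "extrapolated"` and converges noticeably faster (roughly
3x fewer iterations at tight tolerances in our experiments) to the same
fixed point. The discrepancy is deliberate and documented rather than
silently "fixed".

**Stopping norm.** The stopping rule compares
$\|x^{k+1} - x^k\| / \|x^k\|$ with $\eta$. Because step 4 holds every
untraced bin constant, a Frobenius norm over the *whole* sinogram makes the
statistic shrink with the fraction of metal-free bins: padding the detector
with air would spuriously trigger convergence, and on a phantom with small
fillings the rule can fire after a single iteration while the trace is
still far from stationary (we measured the stopped trace error at 4x its
converged value under such a reading). The default therefore measures the
relative change over the traced bins only — the variables the iteration
actually updates; `stop_norm = "full"` restores the whole-sinogram reading.

**Units inside the Gaussian weight.** $\delta$ has the units of the
prior-sinogram gradient, and the quoted operating points ($\delta = 4$
balanced, $\delta = 1$ nearly edge-frozen) correspond to the classical
simulation convention of attenuation-per-cm images projected over
pixel-length paths, whose sinogram values are an order of magnitude larger
than physical dimensionless line integrals. On raw physical line integrals
($\mu$ in 1/mm times path in mm, the unit this package stores) gradients
rarely exceed 2, so $f \approx 1$ everywhere and $\delta$ would be inert —
the diffusion scale study would show no effect at all, contrary to the
method's own behaviour. `run_mar()` therefore evaluates the weights as
$f(c\,\|\nabla x_p\|)$ with $c = 10/\text{pixel spacing}$, the exact
conversion between the two conventions. Because the scale enters only
through $f$, this is algebraically identical to running the printed
algorithm on classically scaled sinograms while keeping the measured data
(and the POCS step) bit-exact in physical units.

**Prior image.** The prior is built by Gaussian-smoothing a reconstruction
(`smooth_sigma` 1.5 px), then thresholding: below −500 HU becomes air
(−1000 HU), below 350 HU becomes soft tissue (0 HU), and bone keeps its
smoothed value, since bone density genuinely varies. Metal pixels carry no
tissue information and are first replaced by the median of their non-metal
neighbourhood (5 px radius, widened as needed). Which reconstruction to
classify matters greatly: classifying the raw uncorrected image lets
streaks masquerade as bone and punch air-valued holes into soft tissue
(4.3% of tissue pixels misclassified on the hip condition, enough to make
the prior-based methods lose to plain interpolation), whereas classifying
the reconstruction of the LI-completed sinogram — the two-pass scheme of
the original normalized-MAR method — reduces misclassification to 1.5% and
restores the expected method ordering. `run_mar(prior_source = "li")` is
the default; `"uncorrected"` is available for comparison.

# The simulated study conditions

The phantom factory builds two parametric anatomies on a 200 mm x 200 mm,
512 x 512 grid: a mandible-level head section (soft-tissue oval, horseshoe
bone arch carrying tooth-like ellipses, a vertebral body, two 2.5 mm metal
fillings) and a pelvis section (body oval, pelvic ring, sacrum, femoral
heads, two 9 mm prosthesis heads). Tissue values: air −1000 HU, soft tissue
0–80 HU with a smooth seeded texture, bone 800–1500 HU, metal 3000 HU.
Generation is deterministic given the seed.

The acquisition simulator projects attenuation along fan-beam rays (1024
detector bins, 720 views over 360°, source–isocenter 600 mm,
source–detector 1100 mm, flat equispaced detector) and draws detector
counts as
$$I = \mathrm{Poisson}\{I_0 e^{-p} + S\} + \mathcal{N}(0, \sigma_e^2),$$
with $I_0 = 5 \times 10^6$ (jaw) or $5 \times 10^5$ (hip), scatter $S =
150$ photons, electronic variance $\sigma_e^2 = 10$, at a single 60 keV
energy. Scatter is not subtracted before the log, so it biases strongly
attenuated bins low, one of the streak drivers.

One modelling choice is central: in the *image domain* metal is represented
at 3000 HU, the ceiling of the clinical CT scale, but the *simulator*
projects metal pixels at a physical attenuation (`metal_mu_mm`, 1.0/mm
cobalt-chrome-like for the dental fillings, 0.25/mm titanium-like for the
prostheses at the beam energy). Real implant alloys attenuate several times
more than the clamped CT number implies; projecting the display value
produces almost no corruption (uncorrected SNR ~25 dB), while the physical
values reproduce the severe-streak regime reported for simulated jaw and
hip studies (uncorrected SNR ~13 dB and ~10 dB here). These values were
fixed from material properties before any method comparison was run.

What the generator does *not* emulate: polychromatic beam-hardening (the
simulator is monoenergetic; an energy-dependent treatment would need a
spectrum the study conditions do not state), detector cross-talk, focal
spot blur, bowtie filtration, anatomical noise, or motion. Passing tests
therefore demonstrate correct behaviour under Poisson/Gaussian photon
statistics with scatter bias — not performance on clinical data, where
prior-image quality is known to be the limiting factor.

# Numerical choices

* **Projector.** Joseph-style ray-driven integration (march along the major
  axis, linear interpolation along the minor one) is the default; a
  fine-step sampler (midpoint rule, bilinear interpolation, step at most
  half a pixel) is retained as an independent discretization. They agree to
  ~1e-5 relative on smooth 512^2 images, and both are tested against a
  dense-sampling oracle at 1/10 pixel steps on small grids.
* **FBP.** Flat-detector fan-beam weighting: detector rescaled through the
  isocenter, cosine ray weighting $D/\sqrt{D^2+u'^2}$, Ram-Lak ramp by FFT
  convolution with zero-padding (optional Hann apodization), backprojection
  weighted by $D^2/U^2$, and the $\Delta\beta/2$ factor for the
  double-coverage 360° orbit. The round trip on a smooth disk reconstructs
  with ~3e-5 relative RMSE and unit scale with no empirical calibration
  factor.
* **Pixel convention.** Images are centred on the isocenter, coordinates
  refer to pixel centres, column index increases with x, row index
  increases downward. Masks and ROI positions inherit this convention.
* **Trace detection** thresholds the forward projection of the metal-only
  image at 1e-6 (absolute, line-integral units), the projector's numerical
  noise floor.
* **Log conversion** floors counts at 1 before the logarithm, reporting how
  many bins were floored; photon starvation is thereby preserved as a
  bounded but grossly biased measurement rather than an infinity.
* **Degenerate inputs.** An empty trace returns the measurement unchanged
  after one iteration; a zero-norm stopping denominator is treated as
  converged with a note; sustained energy growth (10x initial for 20
  consecutive iterations) aborts with a diagnostic.
* **Determinism.** All sampling flows through a single seed per noise
  model, restored after use; the inpainting iteration itself is
  deterministic, and the compiled loop is bit-identical to the R reference
  composition of the exported building blocks (tested).

# Problem sizes in the test suite

Unit tests run on 32–128 px grids with proportionally reduced detector and
view counts, chosen so the whole non-acceptance suite completes in well
under a minute. The acceptance tests and `scripts/acceptance.R` run the
full 512 x 512 / 720 x 1024 conditions: one seeded jaw and hip study each
for the convergence and diffusion-scale checks, and five seeds per phantom
for the method-ordering comparison.

# Known limitations

* Absolute SNR/NMAD values depend entirely on phantom composition, which is
  package-specific; comparisons should be read as orderings between methods
  under identical conditions, not as clinical performance numbers.
* The method inherits the prior's mistakes: where classification fails
  (e.g. streaks surviving the LI bootstrap), the diffusion completion is
  confidently wrong in the same way. On the jaw condition NMAR and the
  diffusion method are within ~0.2 dB of each other; the diffusion method's
  clearest advantage appears on the wide-trace hip condition (~+0.9 dB over
  NMAR, ~+2.5 dB over LI).
* Fan-beam, single-slice, flat equispaced detector only; no curved
  detectors, cone beams, or helical orbits.
* With `delta` well below 1 the edge-stopping weights freeze diffusion and
  the iteration cap, not the tolerance, ends the run — mirroring the
  reported behaviour of the method and visible in the `sweep` verb's
  output.
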