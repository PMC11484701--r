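---
title: "Self-supervised DWI denoising with a spatially variant SURE loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised DWI denoising with a spatially variant SURE loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diffusion-weighted MRI (DWI) trades signal for contrast: the stronger the
diffusion weighting (the b-value, in s/mm²), the lower the SNR. Clinical
protocols therefore repeat each acquisition several times per diffusion
direction and average. Clean reference images for supervised denoising do
not exist — the only data available are the noisy repetitions themselves.
`dwisure` implements a fully self-supervised route: the repetitions
provide both the training signal (through Stein's unbiased risk estimator)
and a per-pixel noise model (through their sample standard deviation), and
the residual the denoiser removes provides its own quality check.

## The model

A complex-valued reconstructed MR image is the unknown clean image
corrupted by zero-mean Gaussian noise whose standard deviation varies
across the image (parallel-imaging reconstruction amplifies noise
anisotropically, the "g-factor"). For a vectorised image $y \sim
\mathcal N(x, \Sigma)$ with diagonal $\Sigma_{dd} = \sigma_d^2$ and a
denoiser $f$, the expected per-pixel MSE against the unknown $x$ equals

$$\mathrm{E}\,\tfrac{1}{D}\lVert f(y)-x\rVert^2 =
  \mathrm{E}\,\tfrac{1}{D}\Bigl(\lVert f(y)-y\rVert^2
  - \textstyle\sum_d \sigma_d^2
  + 2\,\mathrm{div}_y(\sigma^2 \odot f(y))\Bigr),$$

which is observable: it involves only $y$, $f$ and the noise map
$\sigma$. The fidelity term pulls $f(y)$ towards $y$; the divergence term
penalises sensitivity of the denoiser to its input; the constant
$\sum_d\sigma_d^2$ does not affect gradients and is dropped during
training (`sure_config(include_constant = FALSE)`) but included whenever a
SURE value is compared with an MSE. The divergence is estimated by a
randomized finite difference,

$$\mathrm{div}_y(\sigma^2 \odot f(y)) \approx
  b^\top\!\Bigl(\sigma^2 \odot \frac{f(y+\varepsilon b)-f(y)}{\varepsilon}\Bigr),$$

with $b$ a zero-mean, unit-variance i.i.d. probe and
$\varepsilon = \max(y)\cdot 10^{-3}$. Rademacher probes are the default:
they are bounded and make the estimate *exact* for diagonal operators
(`mc_divergence(identity, ...)` returns $\sum_d\sigma_d^2$ to machine
precision), which the test suite exploits as an oracle. Gaussian probes
give the same expectation and are available for comparison. One fresh
probe is drawn per optimisation step — stochastic gradient training
averages over steps, so probe averaging is deferred to validation
(`n_probes`). $\max(y)$ is taken per batch over the target channel; the
alternative (per image) differs only in the third digit of $\varepsilon$
and was not pursued.

## Preprocessing: making the Gaussian model true

SURE needs Gaussian noise in the input. Magnitude images violate this
(Rician floor: in a zero-signal region the mean magnitude is
$\sqrt{\pi/2}\,\sigma \approx 1.2533\,\sigma$ rather than zero), so the
package operates on phase-corrected complex data:

1. **Low-frequency phase estimate** (`lowfreq_phase`): real and imaginary
   channels are boxcar-filtered (default 15×15, mirror boundary) and the
   phase of the filtered image is taken. The kernel size is a free
   parameter — large enough to average away the noise phase, small enough
   to follow the smooth background phase.
2. **Complex rotation** (`phase_correct`): the image is rotated by the
   estimated phase. The rotation is unitary, so the noise stays Gaussian
   with the same per-pixel $\sigma$; the signal moves into the real
   channel and the imaginary channel (noise only) is discarded.
3. **Averaging** (`average_repetitions`): the arithmetic mean of the $N$
   corrected real channels. Averaging before magnitude computation avoids
   the Rician bias; phase correction before averaging avoids the signal
   cancellation that repetition-to-repetition phase instabilities would
   otherwise cause.
4. **Noise map** (`noise_map_from_repetitions`): the per-pixel sample
   standard deviation across repetitions (denominator $N-1$, which keeps
   the estimator unbiased in variance at the small $N$ of low-b data),
   scaled by $1/\sqrt N$ for the average, then Gaussian-blurred
   (default $\sigma = 10$ pixels) to keep the broad spatial noise
   distribution rather than the sampling noise of the estimate. Scaling
   and blurring are both linear, so their order is immaterial; the
   package scales first. When fewer than two repetitions exist the
   function refuses and points to `accept_external_noise_map`, the entry
   point for maps propagated from a scanner noise prescan (consumed
   ready-made; propagation through the reconstruction chain is outside
   the package's scope).

For diagnosis the per-direction images are combined into a trace image —
the pixelwise geometric mean over directions (`trace_image`). Negative
pixels, which legitimately occur in phase-corrected data, are clipped to
zero *only* inside the trace computation; network inputs keep their
signed values, precisely because clipping would break the Gaussianity
SURE relies on.

## Training strategies

`fit_denoiser()` builds one sample per (slice, direction): the high-b
average as target channel, the matched-direction low-b average as an
optional guidance channel (higher SNR, sharper edges), and the noise map
of the target. Three strategies share the same architecture and
optimiser:

* **sure** — minimises the spatially variant SURE loss above, averaged
  over the batch and all diffusion directions.
* **noise2noise** — repetitions are split by position parity; the network
  maps the input-half average to the reference-half average under MSE.
* **half2full** — the network maps a 50%-repetition average to the
  full-repetition average under MSE; at inference the full average is the
  input. Because input and target share half their repetitions, the
  optimal predictor retains the correlated noise component — the method
  under-denoises by construction, which the residual evaluation makes
  visible.

Design choices that the problem leaves open, and how they were fixed:
guidance is the matched-direction low-b image only (one channel), not all
directions; the even/odd repetition split is positional; each sample and
its noise map are divided by one robust scale (99th percentile of the
guidance channel) — scaling $y$ and $\sigma$ jointly leaves the SURE
objective meaningful; slices are independent 2-D samples; early stopping
uses a held-out sample fraction with patience 10 (the validation SURE
probe is drawn once and reused so successive epochs are comparable);
training can tile samples into non-overlapping patches (`patch`), the
usual convolutional-denoiser regime, which multiplies optimisation steps
per epoch at constant cost — inference always runs on full images.

The denoisers are a DnCNN-style residual CNN (stacked 3×3 convolutions
and ReLU, global residual connection, no normalisation layers; the final
layer is initialised small so training starts near the identity) and a
U-Net-style encoder–decoder (average-pool contraction, nearest-neighbour
expansion, skip connections, no normalisation). Their published sizes
(300,675 and 17,259,332 parameters) are not reconstructible because the
exact depth/width behind them is unstated; the package defaults —
`dncnn(depth = 17, width = 64)` and a 4-level U-Net — are approximations,
and the small-profile `dncnn(depth = 6, width = 32)` is used throughout
the tests. Convolutions, their exact reverse-mode gradients and Adam are
implemented in-package on top of BLAS (shifted-gather im2col); gradient
correctness is pinned against finite differences in the test suite.
`learning_rate = 5e-5` and `batch_size = 64` are the paper-scale
defaults; the desk-scale runs below use `2e-3`/`2`, which converge in a
few thousand Adam steps on a single CPU.

## Self-supervised evaluation

If denoising is ideal, the removed residual is exactly the injected
noise, so $(y - f(y))/\sigma$ is standard normal on pixels with
appreciable noise. `residual_report()` gives its sample variance (ideal:
1; below 1 means noise was left behind, above 1 means image content was
removed) and its mean per-pixel Gaussian log-likelihood (maximal,
$-0.9189$, only for a zero residual; $-1.4189$ for an exactly standard
normal residual; decreasing under both inflation and non-Gaussian
leakage). Pixels where $\sigma$ falls below 5% of its maximum are masked
out to avoid dividing by near-zero noise. The statistics are computed on
per-direction images, where the Gaussian model actually holds — not on
the trace, whose geometric mean distorts the noise law. Evaluation never
touches ground truth; `oracle_mse()` exists solely for synthetic data.

## The synthetic phantom

`generate_phantom()` emulates what the method needs from a prostate DWI
acquisition: nested ellipses with distinct baseline signal S0 and ADC
(body ≈ 2.0·10⁻³ mm²/s, central zone ≈ 1.4·10⁻³, a small focal lesion
with restricted diffusion ≈ 0.7·10⁻³ — piecewise-smooth content with
edges, the regime where over-smoothing is visible); mono-exponential
per-direction decay $S_0 e^{-b\,\mathrm{ADC}}$ with mild (±10%)
directional anisotropy; a smooth polynomial background phase plus random
low-order per-repetition phase instabilities (default scale 0.3 rad — the
real magnitude is undocumented, so this is a package choice); and complex
Gaussian noise with one radial-ramp σ-map (default 0.02–0.08 against
S0 = 1) shared by the real and imaginary channels, a surrogate for
g-factor amplification. Defaults mirror a published protocol: b = 50 and
1000 s/mm², three directions, 4 and 12 repetitions.

Deliberately **not** modelled: k-space sampling, coil sensitivities, EPI
distortion, motion between repetitions, Rician statistics of magnitude
pipelines. Passing tests therefore demonstrate the estimator algebra, the
noise-model bookkeeping and the training machinery — not robustness to
motion, distortion or reconstruction artefacts in clinical data.

## Numerical choices and check sizes

Filters use mirror padding (a 64×64 field of view would visibly darken at
the edges under zero padding). Sample variances use $N-1$. The noise-free
σ = 0 phantom limit is admitted (the σ-map generator rejects only
negative bounds). Checks run at fixed sizes chosen for a single CPU: the
unit-variance property of the corrected residual pools ≈1.5·10⁵ pixels;
SURE unbiasedness uses 10³ noise draws on a 32×32 phantom against four
fixed denoisers (identity, constant, boxcar, linear shrinkage) with a
paired two-standard-error bound; the Monte-Carlo divergence uses 10⁴
probes against the trace oracle on a 16×16 linear operator; end-to-end
training uses four 64×64 training slices and two held-out slices with
`dncnn(depth = 6, width = 32)`, 32-pixel patches and at most 60 epochs,
after which the SURE strategy reduces the oracle MSE of the noisy input
by well over half while Half2Full's corrected-residual variance sits
markedly further below 1.

## Limitations

The noise map is itself an estimate; at very small $N$ its sampling error
(and the $\approx 2\%$ downward bias of a 12-sample standard deviation)
propagates into both the loss and the evaluation. The oracle-MSE floor on
the phantom is set by phase-correction bias, not noise: a boxcar phase
estimate cannot follow curvature exactly, so even a perfect denoiser
would not reach zero. Training is CPU-bound R; paper-scale models
(depth-17 DnCNN, 4-level U-Net on clinical volumes) are expressible but
not practical here — the package targets method-scale experiments, not
production training runs.
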