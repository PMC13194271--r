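---
title: "Workflow-optimized illumination calibration for surgical hyperspectral imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Workflow-optimized illumination calibration for surgical hyperspectral imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speccal)
```

## The calibration problem

Hyperspectral cameras used in open surgery record an `H x W x C` cube of
radiance values over tens to hundreds of contiguous wavelength channels.
Turning radiance into tissue reflectance requires dividing by a *white
reference*: an image of a standardized reflector under the same
illumination,

$$ I_{\mathrm{cal}} = I \oslash I_{\mathrm{white}}. $$

In an operating room the illumination changes whenever a surgical light is
moved, a blind is opened, or the ceiling lights are switched, and each
change invalidates the white reference. Physical re-measurement is
sterile-workflow-hostile, so this package predicts the white-reference
cube directly from the uncalibrated image with a 3D convolutional
encoder--decoder, and surrounds that predictor with everything needed to
train and evaluate it on synthetic data: cube arithmetic, a physics-based
illumination simulator, classical baselines, and a metric suite.

The element-wise inverse of calibration, *relighting*
(`relight(calibrated, white)`), synthesizes a raw acquisition of a known
scene under a chosen illumination. It is both the data-augmentation
primitive for training and the ground-truth machinery for evaluation:
every experiment below relights calibrated scenes with known white
references, so the correct answer is available by construction.

## Cube conventions

A `hypercube` stores nonnegative values in `(row, column, channel)` order
with a strictly increasing wavelength grid (default 100 channels,
500--995 nm at 5 nm, the range of Tivita-class cameras) and a role tag
(`raw`, `calibrated`, `white_reference`). Calibration clamps the divisor
at a floor (default `1e-6` of the white cube's maximum) so dark pixels
produce large finite values rather than infinities, and applies no upper
clipping: calibrated values above 1 are physically legitimate under
specular reflection or reference mismatch. Radiometric units are
arbitrary but must be consistent within a dataset; inputs are assumed
offset-free (dark-current subtraction, if needed, happens upstream).

## Physics-based illumination simulation

Measured white references are scarce, so plausible ones are synthesized.
One-dimensional light spectra are modeled by a four-parameter function
inspired by Planck's radiation law,

$$ f_{p_1,\dots,p_4}(\lambda) =
   \frac{(p_1\lambda - p_2)^3}{\exp(p_3\lambda - p_4) - 1}, $$

with $\lambda$ rescaled to micrometres so that $p_1,\dots,p_4$ are O(1)
-- the rescaling conditions the least-squares problem; the source of the
model gives no units. The simulation pipeline for halogen-camera systems
(`generate_halogen_set()`) is:

1. **Fit** $f$ to the spatially averaged spectrum of every library cube
   (`fit_spectrum()`, Levenberg--Marquardt via \pkg{minpack.lm}). The
   problem is non-convex; a moment-based initialization (canonical
   halogen shape, amplitude-matched through the cubic numerator) with 10
   seeded multi-starts keeps the best residual. Non-convergence is
   flagged on the result, never raised.
2. **Summarize** the fitted parameters by their mean $\mu_k$ and
   *population* standard deviation $\sigma_k$ (the intervals describe the
   observed set, not an inferential estimate).
3. **Sample** uniformly from $[\mu_k - n_\sigma\sigma_k,\,
   \mu_k + n_\sigma\sigma_k]$. The default $n_\sigma = 0.25$ balances
   realism against diversity; larger values produce increasingly
   unphysical spectra. Draws must keep $p_3\lambda - p_4 \ge 10^{-3}$
   (the denominator has a pole the model does not otherwise guard) and
   $f \ge 0$ on the whole grid; invalid draws are rejected with a cap of
   1000 attempts, and the observed rejection rate is reported on the
   result. Sampling is continuous by default; a discretized grid mode is
   available (`mode = "grid"`) since either reading of "sampling from the
   interval product" is defensible and continuous draws dominate in
   coverage.
4. **Spatialize** each sampled spectrum onto a randomly chosen library
   cube: $I_s(i,j,c) = f(\lambda_c)\, I(i,j,c) / \bar I(c)$, which forces
   the spatial mean spectrum to equal $f$ exactly while preserving the
   template's relative spatial variation.
5. **Augment** with pairwise convex interpolations drawn from the union
   of acquisitions and simulations.

For LED-camera systems, interference with LED surgical lights is
approximately constructive and spectra keep their local extrema, so plain
inter-cluster interpolation suffices (`generate_led_set()`): the library
is grouped into $K = 4$ clusters by K-means on spatially averaged spectra
(squared-Euclidean, 10 seeded restarts, no normalization -- intensity
differences are themselves illumination information) and each output
mixes two random members of two distinct clusters with a uniform weight.
Mixtures are pairwise only; nothing in the mechanism demands three-way
combinations. Halogen systems interfere destructively -- extrema shift --
which interpolation cannot produce; that is precisely what the parametric
simulation adds.

## The white-reference predictor

`build_model()` instantiates a 3D convolutional encoder--decoder that
maps a raw cube to its white-reference cube. Design choices, with the
reasoning where the design was genuinely open:

* **Volumetric interpretation.** The cube is a one-feature volume with
  axes (spectral, row, column); "3x3" kernels are realized as 3x3x3
  volumetric kernels. The input layer uses a 7x3x3 kernel -- a wider
  spectral receptive field at entry is the natural exemption from the
  3x3 rule.
* **Encoder.** Nine pre-activation residual blocks grow the feature
  dimension from 32 to a 256-dimensional latent space with the
  documented progression 32-32-32 / 64-64-64 / 128-256-256; every third
  block down-samples all three axes by a stride-2 convolution (whether
  striding includes the spectral axis is an open reading; all-axis
  striding is adopted). Identity shortcuts become 1x1x1 projections when
  shape changes.
* **Decoder.** Mirrors the encoder; resolution is restored by trilinear
  interpolation to the recorded encoder extents followed by
  convolutions, so arbitrary input sizes round-trip to identical output
  shapes. There are **no encoder-decoder skip connections**: all
  information flows through the bottleneck, which limits how much scene
  geometry can leak into the predicted illumination. The suite verifies
  this structurally by zeroing the latent and checking the output
  changes everywhere.
* **Output.** A softplus enforces the physical positivity of white
  references (the output non-linearity is otherwise unconstrained by the
  design).
* **Parameter budget.** The reference progression yields 13,683,745
  trainable parameters (~13.7 M); the progression is a documented
  constant validated through the parameter-count test, as exact
  per-block widths are not otherwise pinned down.
* **Initialization.** He-normal, seeded; the second convolution of each
  residual block starts at reduced scale ($\times 1/\sqrt{2\cdot 18}$) so
  the untrained 18-block network behaves near-identity instead of
  saturating its output activation, and the output layer starts with
  small weights and bias $\mathrm{softplus}^{-1}(1)$ so initial
  predictions sit at the scale of a normalized white reference.
* **Uniform ablation variant** (`mode = "uniform"`): the latent map is
  pooled over its spatial axes and decoded by 1D convolutional blocks
  along the spectral axis, producing a spatially constant prediction --
  the spatially uniform illuminant hypothesis expressed as an
  architecture.

The convolution kernels (im2col + GEMM, single precision) and trilinear
interpolation are implemented in C++ via \pkg{RcppArmadillo}; forward,
backward and the Adam optimizer are part of the package, making training
fully self-contained and bit-reproducible under a seed.

## Training paradigm

`train_whiteref()` implements two-dataset relighting augmentation: each
optimization step draws a random calibrated sample cube and a random
illumination cube, multiplies them into a synthetic raw input, and
minimizes the mean-squared error between the predicted and true white
reference -- never the calibrated image -- so supervision carries
illumination information only. Pairings are drawn fresh every step; the
augmentation space is the full product of the two datasets, and the
recorded pairing counts verify positive selection probability for every
pair. The validation split is by sample (illuminations are shared), which
matches the generalization axis that matters: unseen scenes under broad
illumination coverage.

Optimizer defaults -- Adam at `1e-3` decaying by 0.97 per epoch, global
gradient-norm clipping at 1 -- are documented constants chosen for stable
CPU-scale runs; the optimizer and scheduler types are fixed by design,
their values are not. Inputs are normalized by their global mean and the
target by the same constant, which is applied identically at training and
inference (the prediction is scaled back), keeping the learning problem
well-posed under the multiplicative image formation.

## Synthetic data: what it emulates, and what it does not

The generators (`make_camera_spectrum()`, `make_spatial_field()`,
`make_white_reference()`, `make_tissue_cube()`,
`make_colorchecker_cube()`, `make_scenario_suite()`) emulate the
*statistical structure* of surgical HSI data:

* halogen camera spectra are smooth and unimodal (drawn from a canonical
  valid box of the parametric model); LED spectra are positive mixtures
  of 3--6 separated Gaussian peaks, so their local extrema deliberately
  do not coincide with the halogen curve's single maximum -- the
  destructive-interference motif that motivates the halogen simulation
  strategy;
* white references are `camera + intensity * field * stray` with
  multiplicative truncated-Gaussian noise (default 1%, truncated at
  3 sd so positivity is algebraic, not clipped);
* the five named scenarios (`none`, `ceiling`, `side_spot`,
  `direct_spot`, `ceiling_plus_direct`) produce strictly increasing
  spatial non-uniformity under the default intensities (0, 0.3, 0.6,
  0.9, 1.2 relative to camera light);
* tissue scenes are seeded Voronoi partitions whose class reflectances
  are `exp(-)` of nonnegative mixtures of three smooth absorber shapes
  (a short-wavelength absorption edge, a near-infrared band, a
  long-wavelength ramp), giving spectra in (0, 1] that are smooth and
  pairwise distinguishable.

They are *not* optical tissue models: there is no chromophore database,
no scattering physics, no camera noise model beyond the multiplicative
term, and no quantitative match to any measured illumination diversity.
Passing tests therefore demonstrate that the pipeline's mechanisms are
correct and that its qualitative orderings (uniform-illuminant
degradation with spatial non-uniformity, oracle dominance, simulation
benefit) hold on data with the right structure -- not that any particular
accuracy level transfers to real acquisitions.

## Evaluation

The validation metric is mean spectral cosine similarity between the
recalibrated and the original cube -- scale-invariant per pixel, equal to
1 iff all pixel spectra are positively proportional. It is used for
*relative ranking* of methods; absolute values saturate near 1 and small
differences can matter downstream, so the suite asserts orderings rather
than absolute parity. Spatial non-uniformity of a white reference is
quantified by the per-channel population standard deviation over pixels,
averaged over channels. Classical baselines are Gray world (spatial
mean), Max-RGB adapted per channel (spatial maximum) and first-order Gray
edge (Minkowski p-norm of gradient magnitude; defaults `p = 5`, Gaussian
smoothing 1 px -- common literature constants; a constant scene returns a
flagged uniform estimate instead of dividing by zero). All produce
unit-mean spectra since the illuminant scale is unidentifiable.
Uncertainty is a 95% percentile bootstrap over sample images (1000
resamples, seeded).

`uniformity_study()` reproduces the spatial-uniformity analysis
synthetically: relight samples per scenario, recalibrate with (a) the
spatially averaged spectrum and (b) the true white reference; (a)
degrades monotonically with scenario spatial standard deviation
(Spearman $\rho = -1$ across the default suite) while (b) stays exact up
to the division floor. `benchmark_methods()` crosses methods with
scenarios; `latent_pca_density()` projects pooled 256-dimensional encoder
features onto two principal components (sign-canonicalized by forcing the
largest-magnitude loading positive) with per-group kernel density
estimates, and flags zero-variance degeneracy.

## Numerical choices and problem sizes

Seeds flow explicitly into every stochastic step (generation, fitting
restarts, sampling, clustering, training, bootstrap); identical seeds
give bit-identical results. Division guards: calibration floor
`1e-6 * max(white)`; spectrum-validity margin `1e-3` on the exponential
argument; rejection cap 1000. K-means ties are avoided by 10 restarts;
degenerate libraries with duplicated spectra are labeled by duplicate
group instead.

Test problem sizes are chosen for single-CPU budgets: 32x32x100 cubes
for the training smoke run (16 samples x 8 illuminations, a ~0.52 M
parameter model with progression 8-8-8/16-16-16/32-32-64, 200 Adam steps
at batch 1) and 12-16 pixel extents for the metric and simulation suites.
The reference 13.7 M-parameter model is exercised for construction,
parameter count and a full forward pass at 32x32x100. A forward pass at
64x64x100 is ~470 GFLOP and takes tens of seconds per cube on one CPU
core; deployment-scale inference is GPU territory and out of scope here.

## Known limitations

* Cosine similarity is insensitive to per-pixel scale by construction;
  a method that recovers spectral shape but not intensity scores
  perfectly. This mirrors the metric's role as a ranking tool.
* The simulator's four-parameter family cannot represent multi-peaked
  LED camera spectra; for LED systems only the interpolation strategy is
  appropriate, and `generate_halogen_set()` on an LED library would fit
  poorly (flagged by residuals and the rejection rate).
* The predictor assumes the training wavelength grid at inference
  (channel count is checked); cross-camera transfer is not modeled.
* Downstream clinical endpoints (segmentation quality, physiological
  parameter errors) require external models and data and are outside the
  package's scope; the evaluation suite stops at calibration fidelity.
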