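---
title: "Relative Patlak parametric imaging: models, noise and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative Patlak parametric imaging: models, noise and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relpatlak)
```

## The model

Irreversible FDG kinetics follow the two-tissue compartment model: plasma
tracer enters a free pool at rate $K_1$ (mL/min/cm^3^), leaves it at $k_2$
(1/min) and is phosphorylated — trapped — at $k_3$ (1/min). After an
equilibrium time $t^*$ the Patlak plot linearizes the dynamics: with
$C_T(t)$ the tissue and $C_p(t)$ the plasma activity concentration,

$$\frac{C_T(t)}{C_p(t)} \;=\; K_i\,
  \frac{\int_0^{t}C_p(\tau)\,d\tau}{C_p(t)} + b, \qquad t > t^*,$$

and the slope is the net influx rate $K_i = K_1 k_3/(k_2+k_3)$. The
intercept $b$ mixes blood volume and the free-tracer distribution volume.
The practical obstacle for whole-body parametric imaging is the abscissa:
it integrates the input from injection, so a full-hour input function is
needed even if only late frames are fitted.

The *relative* Patlak (RP) plot replaces the integral's lower limit by
$t^*$. Only the late-time input — exactly the data a short (e.g. 20-min)
late scan provides — enters the regression. Two identities make the RP
parameters interpretable:

* **Global scaling.** The RP slope satisfies $K_i' = \alpha K_i$ with a
  single subject-level constant $\alpha$ determined by the input shape:
  both abscissae differ only by $\int_0^{t^*}C_p/C_p(t)$, which for a
  slowly decaying tail is approximately affine in the relative abscissa.
  When the tail is exactly one exponential the affinity — and hence the
  per-voxel proportionality — is exact; `estimate_alpha()` measures
  $\alpha$ as the voxel-scatter regression slope.
* **Intercept = SUVr.** Setting $t = t^*$ zeroes the relative integral,
  so the RP intercept is $b' = C_T(t^*)/C_p(t^*)$: the late-uptake SUV
  ratio against plasma, computed independently by `suvr_image()`.

`patlak()` fits either plot for an ROI curve and returns a classed model
object (`coef`, `summary`, `predict`, `plot`, `residuals` all work);
`fit_parametric()` is the voxel-wise version, a single least-squares solve
per volume because the abscissa is global.

## What the phantom emulates, and what it does not

`build_phantom()` composes ellipsoids into a 48 × 48 × 96 label volume
with 4-mm voxels — a desk-scale stand-in for a total-body acquisition
(the data model accepts full 150 × 150 × 486 grids; tests and examples do
not require them). Organs carry literature-typical FDG rate constants;
three lesions (lung, liver, pelvis; radii 1–3 voxels) have $k_3$ high
enough that their $K_i$ exceeds the liver's. The simulated protocol is the
29-frame 1-h schedule (6 × 10 s, 2 × 30 s, 6 × 60 s, 5 × 120 s, 4 × 180 s,
6 × 300 s) or the 4 × 5-min late schedule starting at $t^* = 40$ min. The
input defaults to a Feng-type bolus-plus-biexponential curve peaking near
0.5 min at ~80 kBq/mL; all activities are decay-corrected by construction,
so no half-life enters the math.

Noise is additive Gaussian per frame with SD
$\,s\sqrt{\bar A_{\text{frame}}/\Delta t}$ ($\bar A$ = body-mean activity,
$\Delta t$ = frame duration, $s$ = `noise_scale`). This preserves the two
dependencies the short-scan problem needs — noisier short frames, noisier
high-activity frames — without modelling the projection domain; OSEM
reconstruction, attenuation/scatter corrections, motion and PSF effects
are deliberately out of scope. Consequences worth remembering: real PET
noise is spatially correlated and non-Gaussian at low counts, so passing
tests here demonstrate estimator algebra and pipeline behaviour, not
scanner-level image quality. Negative noisy values are kept — clamping
would bias low-activity Patlak fits — and masking is left to the fitting
stage (default mask: last-frame activity above 1% of the frame maximum).
At `noise_scale = 1` (the default regime studied) the non-denoised liver
$K_i'$ SD/mean is ≈ 0.5–0.6, the high-noise regime that motivates
denoising.

## The self-supervised deep-kernel denoiser

The denoiser is a row-stochastic neighbour-averaging operator
$x_{\text{denoised}} = K(\theta; Z)\,x_{\text{noise}}$ built from the
$n_z = 4$ composite 5-min late frames $Z = \{z_m\}$. Each voxel's feature
vector is its four composite values (z-scored per composite); neighbours
are the $k = 200$ nearest in feature space within a 9 × 9 × 9 spatial
window; weights are row-normalized Gaussians. Training minimizes

$$\sum_{m=1}^{n_z} \lVert z_a - K(\theta_l; Z)\, z_m \rVert^2,$$

with the frames' mean $z_a$ as the clean label — each noisy frame, pushed
through the kernel, should look like the mean. The learnable part
$\theta_l$ is a small residual two-layer perceptron (width 8, `tanh`) on
the feature vectors; the architecture is this package's minimal
realization of a trained kernel, chosen so the operator remains a
row-stochastic neighbour average. Design choices that matter:

* **Frozen topology.** Neighbours are found once from the raw features
  and kept; only the Gaussian weights are differentiated. This keeps the
  objective smooth and the operator's support fixed.
* **Identity initialization.** The residual branch starts at zero, so
  iteration 0 *is* the conventional kernel; training (Adam, learning rate
  10^-3^, 300 iterations) can only be assessed against a baseline it
  literally starts from. The traced objective is stored in `$losses`.
* **Domain mask.** The kernel operates on a body mask taken from the
  composite mean ($z_a >$ 2% of max) — averaging suppresses background
  noise before thresholding — and passes other voxels through unchanged.
* **Where it is applied.** By default the trained kernel filters the late
  dynamic frames before fitting, so SUV and Patlak pathways see the same
  denoised data; `post_smooth_parametric = TRUE` additionally filters the
  fitted maps.

Training is seeded, single-threaded and bit-reproducible. On the default
phantom at `noise_scale = 1` the pipeline cuts liver slope-map SD/mean by
roughly two thirds while moving every lesion ROI mean by ~1% or less, and
reaches a lower self-supervised objective than the conventional kernel.

## Numerical choices

* Input integrals use composite trapezoidal quadrature on a fixed 0.05-min
  lattice (the bolus is ~1 min wide); lattice nodes are global so
  integrals are exactly additive across abutting intervals. The sharp
  bolus limits the standard abscissa's accuracy to its $O(h^2)$
  truncation (~2 × 10^-4^ relative); the relative abscissa, integrating
  only the smooth tail, is accurate to ~10^-9^.
* The tissue solver integrates the free compartment with an
  exact-exponential recursion and the trapped compartment by cumulative
  quadrature; frame values are time-averages over the frame (mimicking
  count reconstruction) with mid-times as the fitting abscissa.
* A frame enters a fit iff its start time is at or after $t^*$, so the
  relative integral never extends over unacquired data.
* Regression is unweighted least squares by default; frame-duration
  weighting is available but off (late frames here share one duration).
* `suvr_image()` interpolates the per-frame $C_T/C_p$ ratios linearly
  between the two frame mid-times bracketing $t^*$. The nearest-mid-time
  alternative remains available but is not the default: with 5-min late
  frames the nearest mid-time sits 2.5 min after $t^*$, by which high-uptake
  voxels have climbed visibly off the intercept, tilting the $b'$-vs-SUVr
  scatter by ~5%; interpolation is exact for data on the Patlak line and
  restores the identity to ~0.1%.
* Degenerate inputs error early and explicitly: fewer than two usable
  frames, non-positive plasma activity at a retained mid-time, zero
  abscissa variance, empty ROIs and masks.

## The calibration cohort

`simulate_cohort()` emulates the cross-subject study design at ROI level:
12 healthy subjects and 10 patients, each with a subject-specific input
(log-normal jitter: bolus amplitude SD 0.35, bolus sharpness SD 0.175,
tail exponent SD 0.03) and organ kinetics jittered by 10%; ROI curves
carry count-scaled noise shrunk by a nominal 500-voxel ROI size. These
magnitudes were fixed once as a conservative reading of between-subject
variability; they yield a between-subject $\alpha$ CV of ≈ 3%. Each
subject's $\alpha$ comes from the organ-level $K_i'$-vs-$K_i$ regression;
dividing patient lesion $K_i'$ by the healthy-cohort mean $\alpha$
produces calibrated absolute $K_i$ without any early input data, assessed
by Bland–Altman analysis against the standard-Patlak reference. The
population-based input function (PIF) comparator averages the healthy
inputs normalized by their late-window ([$t^*$, end]) means and rescales
to each patient's measured late blood level.

A structural property of this error model is worth stating plainly: an
early-bolus perturbation changes $\int_0^{t^*} C_p$ and nothing else the
late-time fit can see, and that integral enters the $\alpha$-calibrated
and the PIF-based estimate identically — a ±35% bolus change moves both
by the same +0.8%. Tail-shape differences, by contrast, hit the
calibration about four times harder than the PIF, whose anchor rescaling
absorbs most of the mismatch. Under independent input-parameter jitter the
calibrated route therefore cannot show *narrower* limits of agreement
than the PIF route here, whatever the jitter mix — patient data, where
population input curves misrepresent individual physiology in richer ways
(timing, dispersion, correlated shape-and-clearance differences), can and
does order the two differently. The package reports both limits of
agreement and leaves the ranking to the data.

## Problem sizes and runtimes

The package's examples, tests and the acceptance script run the phantom at
its default 48 × 48 × 96 grid (≈ 47 000 body voxels), where a full
29-frame simulation takes well under a minute and a 300-iteration kernel
training about one minute on one CPU; the cohort simulation (22 subjects,
ROI level) takes a few seconds. These sizes were chosen so a complete
validation runs comfortably on a laptop while exercising every code path
at realistic organ geometry.

## Known limitations

* Reversible kinetics ($k_4 > 0$), input delay/dispersion correction and
  direct (reconstruction-domain) Patlak are out of scope.
* The noise model is uncorrelated Gaussian; kernel denoising performance
  on reconstruction-correlated noise will differ quantitatively.
* The PIF construction is a declared stand-in (normalized average,
  late-window anchor); site-specific PIF recipes differ.
* The phantom's organs are homogeneous; no intra-organ kinetic texture,
  partial-volume effects or motion.
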