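---
title: "Angular completion of HARDI acquisitions: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Angular completion of HARDI acquisitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-angular-resolution diffusion imaging (HARDI) needs many
motion-probing-gradient (MPG) directions — typically 60 or more at a
single high b-value — before crossing-fiber models such as Q-ball imaging
(QBI) or generalized q-sampling imaging (GQI) become reliable. The scan
time scales with the direction count. `hardigen` implements and evaluates
an *angular completion* strategy: acquire the b0 volume plus the first
half of the MPG directions, and let a 3D U-net predict the DWI volumes of
the remaining directions. Downstream analyses then run on three arms:

* **(a)** b0 + 32 measured directions (the short acquisition),
* **(b)** b0 + 32 measured + 32 predicted directions,
* **(c)** b0 + 64 measured directions (the reference).

If arm (b) is closer to arm (c) than arm (a) is — in diffusion-profile
divergence, angular correlation, and tractography overlap — the predicted
volumes carry real angular information and the acquisition could be
halved.

Clinical DWI cohorts cannot be redistributed, so the package evaluates
the whole chain on synthetic multi-tensor crossing-fiber phantoms whose
acquisition geometry mirrors a clinical HARDI protocol: b = 3000 s/mm²,
64 directions plus one b0, 2.5 mm isotropic voxels.

## Gradient scheme design

Directions are placed by minimizing the antipodal Coulomb energy

$$E = \sum_{i<j} \left( \frac{1}{\|d_i-d_j\|} + \frac{1}{\|d_i+d_j\|}
\right),$$

with projected gradient descent on the sphere, a step-halving line search
(energy is non-increasing by construction) and 100 random restarts by
default. The optimizer is validated against known optima: n = 3 returns
three orthogonal axes and n = 6 the icosahedral arrangement (minimum
folded angle 63.43°); at n = 64 independent restart batches agree in
energy to well under 1%, and the minimum folded angle (≈ 17°) is in the
range expected of electrostatic schemes. The stored order of designed
directions is the acquisition order; `split_scheme()` cuts after the
first k directions (b0 entries always travel with the first part), which
is exactly the "first half / second half" protocol of the three-arm
design.

## The phantom generator

`simulate_signal()` evaluates the standard multi-tensor model per voxel,

$$S(g,b) = S_0\left[\sum_k f_k\, e^{-b\, g^\top D_k g}
  + f_{bg}\, e^{-b\, d_{iso}}\right],$$

inside a spherical "tissue" region (zero signal outside, which gives the
b0 mask something real to find). Defaults, chosen once as typical
white-matter values at b = 3000 s/mm²: bundle eigenvalues
(1.7, 0.3, 0.3)×10⁻³ mm²/s, isotropic background
d_iso = 0.8×10⁻³ mm²/s, S0 = 100. Noise, when requested, is Rician:
$\sqrt{(S+n_1)^2+n_2^2}$ with $n_1,n_2 \sim N(0,\sigma^2)$ — the
Monte-Carlo mean of the pure-noise magnitude reproduces the Rayleigh
moment $\sigma\sqrt{\pi/2}$.

Each phantom contains two straight tubular bundles crossing at the grid
center, with crossing angle drawn from 50–90°, random in-plane azimuth,
tube radius 3–4 voxels and a small center offset; overlap voxels carry
equal fractions 0.5. The default grid is 32³ (a desk-scale stand-in for
the clinical 96×96×60 matrix; larger grids are a config entry away).
The generator emulates the *angular* structure of HARDI data — which is
what angular completion exploits — but not EPI distortion, motion, eddy
currents, gradient nonlinearity or anatomical variability, because the
preprocessing that handles those is out of scope here. Passing tests
therefore demonstrate internal consistency of the method at realistic
SNR-free conditions, not clinical performance.

The default experiment runs **noiseless** phantoms: the evaluation
targets the information content of the predicted volumes, and a noise
floor in the teaching data would bound the achievable training MSE from
below, confounding the capacity check. `noise_sigma` is a first-class
config entry for studying robustness.

## The 3D U-net

The network maps the 33-channel stack (b0 + first 32 MPG volumes) to the
32 remaining channels. Architecture: per level two 3×3×3 convolutions
(ReLU), stride-2 convolutional downsampling between levels, 2×2×2
transposed-convolution upsampling, skip connections by channel
concatenation, and a final 1×1×1 linear projection; defaults are 3
levels with 16 base filters — the smallest net that resolves crossing
geometry in 32³ phantoms — and everything is configurable. The final
projection is zero-initialized so the untrained model predicts zero
signal and the first recorded loss is the full signal energy; earlier
layers use He initialization.

Training minimizes the voxel-wise MSE with Adam. The learning-rate
schedule is a short linear warmup (6 epochs) into a half-cosine decay
from the peak rate 3×10⁻³ — the warmup is load-bearing: with the
zero-initialized output layer, peak rates above ~2×10⁻³ overshoot in
the first epochs without it, and the decay is what lets the loss settle
on noiseless data. The desk profile trains on the non-overlapping 16³
patch tiling of each 32³ volume (the `patch_shape` option; whole-volume
training is the module default): every epoch still visits every voxel
exactly once, but a 20-volume cohort yields 160 patches and therefore
80 optimizer steps per epoch instead of 10, which is what a small
cohort needs to converge within the 50-epoch budget. Because the
tiling partitions each volume, the
epoch-averaged patch MSE is the training-set MSE, directly comparable
to the whole-volume convention. Intensities are normalized per volume
by a robust b0 maximum (99th percentile) and the scale recorded, so
metrics are computed on the original intensity scale. Predictions are
clamped at zero because DWI magnitudes are nonnegative. Per-epoch
training MSE is the mean of minibatch losses evaluated *before* each
update; validation MSE is computed on whole volumes after each epoch
and the best-validation weights are the ones kept. Everything —
initialization, shuffling, patch schedule and the compute kernels — is
deterministic given the seeds, which is what makes the
byte-identical-report property testable.

The convolution kernels are compiled (RcppArmadillo): each output row is
gathered into a small reused im2col buffer so the working set stays
cache-resident and the arithmetic runs as mid-sized GEMMs. Analytic
gradients are verified against central differences in the test suite.

## Reconstruction

**DTI.** Weighted log-linear least squares (weights = squared signal)
per masked voxel; negative eigenvalues are clamped to zero and counted.
FA uses the standard normalized eigenvalue-dispersion formula; E1 is the
principal eigenvalue, reported in mm²/s ×10⁻³ (display units are a
formatting concern only). On noiseless phantoms the fit recovers the
ground-truth eigenvalues to 10⁻⁶ mm²/s, which is the cross-module
recovery property tying the phantom and reconstruction modules together.

**QBI.** Analytic Q-ball: least-squares fit of S/S0 in the real
even-order spherical-harmonic (SH) basis with Laplace–Beltrami
regularization (weight 0.006, the standard analytic-QBI choice),
followed by the Funk–Radon transform as the diagonal scaling
$c_{lm} = 2\pi P_l(0)\, s_{lm}$. Whether the original external tool
used numerical or analytic Q-ball is not recoverable from its name
alone; this package standardizes on the analytic form, which has a
closed-form oracle (P₀(0)=1, P₂(0)=−½, P₄(0)=⅜) and well-understood
regularization.

**GQI.** The spin distribution function is the kernel sum
$\psi(u) = \sum_i S_i\,\mathrm{sinc}(\sigma\sqrt{6 D_0 b_i}\, g_i\cdot u)$
over all acquired volumes, with the conventional free-water constant
6D₀ = 0.01506 and sampling-length ratio σ = 1.25 (the cited
formulation's convention). The SDF is evaluated on the sample sphere and
projected to SH so that peaks, divergences and correlations share one
code path. One measured caveat: with 64 directions at b = 3000 the
isotropic-voxel SDF retains ≈ 1% ripple from the truncated kernel sum
(max/min ≈ 1.011); the flatness test asserts < 1.02 because the ripple
is a property of the direction count, not of the implementation.

**lmax policy.** The largest even order with (l+1)(l+2)/2 coefficients
not exceeding the direction count, capped at 8 — so arm (a) with 32
directions uses lmax 6 while arms (b) and (c) use lmax 8. This is
deliberate: it reproduces the angular-resolution handicap of the short
acquisition that completion is meant to remove.

**The 181-point sphere.** Divergence and correlation metrics project
spherical functions onto 181 directions: the vertices of a frequency-6
subdivided icosahedron (362 points, antipodally symmetric by
construction) folded to one hemisphere — exactly 181 near-equal-area
points with ≈ 9.3° minimum spacing. Peak directions are refined beyond
this grid resolution by a shrinking-cap hill climb on the continuous SH
function (six halvings from a 6° cap), giving sub-degree peak accuracy
where the bare grid would be limited to ≈ 5°.

## Metrics

* **JSD** between two sampled ODFs (each clamped at zero and normalized
  to sum 1): $\mathrm{JSD}(P,Q) = [D_{KL}(P,M)+D_{KL}(Q,M)]/2$ with
  $M = (P+Q)/2$, natural log, reported in nats; bounded by ln 2.
  Zeros in a denominator are floored at 10⁻¹²; since M ≥ P/2 wherever
  P > 0 this floor only ever matters for degenerate all-zero inputs.
* **ACC**: the normalized inner product of SH coefficient vectors with
  the isotropic l = 0 term excluded (the summation starts at l = 1; with
  a real orthonormal basis the conjugate products are plain products).
  Voxels with no anisotropic energy have no defined ACC and are flagged,
  not zero-filled. When arms of different lmax are compared, the
  lower-order coefficient vector is zero-padded to the common order.
  Voxelwise JSD/ACC summaries are restricted to voxels whose
  *reference-arm* ODF has an anisotropic fraction above 1%: on noiseless
  phantoms the isotropic background's l ≥ 1 coefficients are pure
  floating-point residue, and because arms (a) and (c) share half their
  raw measurements that residue correlates spuriously between them — an
  unrestricted mean is dominated by this junk correlation and says
  nothing about diffusion profiles.
* **SSIM/PSNR** per predicted MPG axis against the same axis of the
  reference arm, inside the b0 mask. SSIM uses a 3D Gaussian window
  (11³ support, σ = 1.5, k₁ = 0.01, k₂ = 0.03, dynamic range = masked
  reference maximum) and averages the SSIM map over the mask restricted
  to the window-interior; the implementation agrees with an independent
  volumetric reference implementation to < 10⁻⁴ on random volumes.
  PSNR is 10·log₁₀(MAX²/MSE) with an `Inf` sentinel for identical
  volumes.
* **DSC**: 2|x∩y|/(|x|+|y|) on voxelized bundles.
* **Paired statistics**: Wilcoxon signed-rank (zero differences dropped;
  exact sign-flip enumeration up to n = 12, which stays valid under tied
  differences; normal approximation with tie correction beyond) with
  effect size r = |Z|/√N, and a Friedman route across the three arms
  with pairwise Wilcoxon tests judged at the Bonferroni threshold
  p < 0.0167 for the FA/E1 comparisons.

## Tractography

Deterministic streamline tracking in voxel coordinates: one seed per
seed voxel (at its center), Euler steps of 0.5 voxel in both directions
along the best-aligned ODF/SDF peak after antipodal folding, termination
on leaving the stop mask, losing all peaks, or turning more than 45° in
a step; streamlines shorter than 4 voxels are discarded. These defaults
are explicit and documented rather than inherited from any external
tool's version-dependent settings. Streamlines that miss the target ROI
or touch the avoidance ROI are removed; an empty surviving set is a
"bundle not visualized" flag. A bundle the *reference* arm cannot
visualize is excluded from DSC comparison (the comparison has no
referent); a test arm that fails where the reference succeeds scores
the formula's Dice of 0 — censoring those cases instead would hide
exactly the bundles the completed arm rescues. Voxelization marks every
voxel whose
closed cube intersects a streamline segment with positive length (grid
traversal with simultaneous-crossing handling, verified against an
exhaustive segment–box clipping oracle), not rounded vertices.

## The experiment and its scales

`run_experiment()` wires everything: design → simulate → split → train →
predict → three arms → SSIM/PSNR, voxelwise JSD/ACC on QBI profiles,
three-arm FA/E1 ROI statistics (single-fiber ROIs: each bundle minus the
other's tube), QBI and GQI tractography DSC — with paired tests on each.
The desk profile is 20 training / 3 validation / 5 test phantoms at 32³,
a 3-level 16-filter U-net and 50 epochs; it was sized so that a full run,
including both tractography models on all arms, completes in minutes on
a single core. The per-case voxel counts (≈ 12,000 masked voxels per
phantom) are reported alongside every mean. Per-voxel JSD/ACC maps and
voxel-pooled summaries are both available, since mask-averaged and
pooled summaries answer slightly different questions.

Two properties anchor the design and are asserted end to end: adding
the *true* second half (arm c) can only improve on arm (a) — the upper
bound predictions cannot beat — and on clean phantoms the trained
predictions land between the two, i.e. JSD(b,c) < JSD(a,c) and
ACC(b,c) > ACC(a,c), with DSC(b,c) ≥ DSC(a,c) on the majority of
bundles for both QBI and GQI.

## Numerical choices and degenerate inputs

* Voxel coordinates are 0-based, voxel extents half-open, affines map
  voxel centers; this is stated once in `dwi_volume()` and used
  everywhere.
* ODF samples are clamped at zero before normalization (SH truncation
  can produce small negative lobes).
* All-zero spherical functions sample to the uniform distribution and
  are flagged; all-zero voxels are excluded from tensor fits and
  flagged; coincident or antipodal direction pairs give an infinite
  design energy sentinel.
* Ties in the peak-finder are broken by amplitude order then greedy
  angular separation (25° minimum); the isotropic case yields no peaks
  because no sample strictly dominates its neighborhood.
* Every random operation consumes a named seed derived from the master
  seed; reports serialize without timing so identical runs are
  byte-identical.

## Known limitations

Straight-tube phantoms have no curvature, so the tracking angle
threshold is never stressed; the U-net mapping learned here is close to
voxel-wise and does not demonstrate anatomical-context learning; GQI's
isotropic ripple (above) is inherited by very low-anisotropy voxels;
and absolute clinical metric values (SSIM, JSD, ACC, DSC on patient
cohorts) are outside what synthetic phantoms can reproduce — the
package asserts orderings and recoveries, not those numbers.
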