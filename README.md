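# hardigen

Angular completion of HARDI diffusion MRI with a 3D U-net, evaluated end
to end on synthetic crossing-fiber phantoms.

## The problem

High-angular-resolution diffusion imaging (HARDI) resolves crossing
white-matter fibers only when many motion-probing-gradient (MPG)
directions are acquired — typically 64 at b = 3000 s/mm² — and scan time
grows with every direction. `hardigen` implements the strategy of
acquiring only the b0 volume plus the first 32 directions and *predicting*
the remaining 32 DWI volumes with a 3D U-net, then quantifies what the
predictions are worth for diffusion modeling and tractography. Evaluation
follows a three-arm design:

* **(a)** b0 + 32 measured directions (input only),
* **(b)** b0 + 32 measured + 32 predicted directions,
* **(c)** b0 + 64 measured directions (reference).

The package is aimed at diffusion-MRI methods researchers: it contains
the full chain — electrostatic-repulsion gradient design, multi-tensor
phantom simulation with Rician noise, the U-net (built on compiled
convolution kernels, trained with Adam on the MSE loss), DTI / analytic
Q-ball (QBI) / generalized q-sampling (GQI) reconstruction, diffusion-
profile similarity metrics, deterministic streamline tractography, and
paired statistics — with every stage testable without clinical data.

## Core quantities

For two orientation distribution functions sampled at 181 hemisphere
directions and normalized to probabilities P, Q:

- **JSD**(P, Q) = [D_KL(P, M) + D_KL(Q, M)]/2, M = (P+Q)/2, in nats;
  0 for identical profiles, at most ln 2.
- **ACC** = Σ_{l≥1,m} u_lm v_lm / (‖u‖_{l≥1} ‖v‖_{l≥1}) over spherical-
  harmonic coefficients, excluding the isotropic term; 1 for identical
  angular structure.
- **DSC**(x, y) = 2 V(x∩y) / (V(x)+V(y)) between voxelized bundles.
- **SSIM / PSNR** per predicted MPG axis against the reference axis.
- DTI **FA** and **E1** (principal diffusivity) over single-fiber ROIs,
  compared across the three arms.

Arms are compared as (a vs c) and (b vs c); the headline output is the
(b vs c) − (a vs c) delta with Wilcoxon signed-rank / Friedman-Bonferroni
statistics.

## Worked example

```r
library(hardigen)

# a desk-scale run of the full three-arm experiment:
# 20 train / 3 val / 5 test crossing-fiber phantoms at 32^3,
# 64-direction b = 3000 scheme split 32 + 32, 3-level U-net, 50 epochs
report <- run_experiment(default_experiment_config(seed = 1))
print(report)
```

```
<metric_report>
  training MSE: 0.002104 -> 1.986e-05 (drop 106x, best epoch 50)
  prediction: SSIM 0.9697, PSNR 29.27 dB
  JSD  (a vs c) 0.0001586   (b vs c) 7e-05
  ACC  (a vs c) 0.994688 (b vs c) 0.996335
  DSC QBI a 0.700 b 0.900 | GQI a 0.340 b 0.850
```

Reading this: the network's training loss fell 106-fold; the predicted
second-half volumes match the held-out measured ones at SSIM 0.97;
adding them moves the voxelwise diffusion profiles closer to the
reference — the JSD roughly halves and the angular correlation rises,
the same direction and order of magnitude as the clinical three-arm
comparisons this design comes from — and the mean tractography overlap
with the reference bundles rises sharply for both QBI (0.70 to 0.90)
and GQI (0.34 to 0.85), dominated by crossings near the angular
resolution limit of the 32-direction arm, where the completed arm
recovers bundles the input arm loses outright.
`report$comparisons` holds the paired test statistics,
`report$per_case` the per-phantom values, and
`write_report(report, dir)` serializes everything as JSON + CSV.

A command-line interface wrapping each stage (simulate / train / predict
/ evaluate / track / report, plus `run` for the whole experiment) lives
at `inst/cli/hardigen.R`:

```sh
Rscript inst/cli/hardigen.R simulate --n 5 --seed 1 --out-dir out/cases
Rscript inst/cli/hardigen.R run --seed 1 --out-dir out/experiment
```

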