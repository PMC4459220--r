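---
title: "Methods: voxel-mirrored homotopic connectivity with synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-mirrored homotopic connectivity with synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoconn)
```

## The measure and the inference chain

Voxel-mirrored homotopic connectivity (VMHC) quantifies inter-hemispheric
functional coupling as the Pearson correlation between the resting-state BOLD
time series at a voxel and at its geometric mirror in the opposite
hemisphere. On a left–right symmetric grid with an even left–right dimension,
mirroring is pure index reversal along the first axis, so every voxel has a
distinct partner and the resulting r map is exactly symmetric under flip.
Correlations are mapped to Fisher z (`atanh`, with |r| clipped at
`1 - 1e-7`), which approximately normalizes their sampling distribution;
all group statistics operate on these zVMHC maps.

The inference chain mirrors standard resting-state practice:

1. **Preprocessing** per subject, in fixed order: discard the first 10
   volumes (signal equilibration); framewise displacement (FD) and
   motion-based exclusion; nuisance regression (six rigid-motion parameters
   plus mean ventricle and deep-white-matter signals); 4 mm FWHM Gaussian
   smoothing; linear detrend; 0.01–0.08 Hz band-pass. Regression precedes
   filtering, the order used by the legacy resting-state toolboxes this
   pipeline is modeled on; the band-pass is an ideal frequency-domain mask (exactly
   idempotent, exactly testable against an FFT oracle) rather than an IIR
   filter.
2. **VMHC** within a gray-matter mask obtained by thresholding a symmetric
   gray-matter probability volume at 40%. Zero-variance voxels are flagged
   invalid and set to 0 rather than producing NaNs. The mask is applied at
   both the subject and the group level.
3. **Group statistics**: voxelwise one-way ANOVA across the three groups
   (AVH, NonAVH, Control) with mean FD as covariate, computed as a
   full-vs-reduced residual-sum-of-squares comparison (df = 2, n − 4);
   F values are probability-transformed to Z; supra-threshold clusters at
   Z > 2.3 receive familywise-corrected p values from Gaussian-random-field
   (GRF) cluster-extent theory; covariate-adjusted two-sample t maps handle
   the pairwise contrasts (both tails corrected separately). First-level
   one-sample maps use voxelwise t tests with Benjamini–Hochberg FDR at
   q = 0.01 and a 20-voxel extent filter.
4. **ROI statistics**: mean zVMHC in 5 mm spheres at the peaks of
   significant clusters (voxel-center membership, 19 voxels on a 3 mm grid
   when centered on a voxel center), pairwise group comparisons with pooled
   within-group variance and Bonferroni correction (×3, capped at 1), and
   the three-way classification — AVH-only / NonAVH-only / shared —
   according to which patient-vs-control contrasts are significant.
5. **Clinical correlations**: Pearson r between sphere means and PANSS
   subscale/total scores over all patients, and AHRS over AVH patients only,
   with two-tailed p from `t = r sqrt(n-2)/sqrt(1-r^2)` on n − 2 df.
   No multiple-comparison correction is applied across the region × score
   grid by default, the conventional presentation for exploratory
   region-by-score tables; a flag adds BH adjustment.

## Key parameters

| parameter | default | unit | role |
|---|---|---|---|
| `n_discard` | 10 | volumes | equilibration discard (240 → 230 retained at TR = 2 s) |
| `fd_radius_mm` | 50 | mm | rotation-to-arc-length radius in Power-style FD |
| `trans_limit_mm`, `rot_limit_deg` | 2.0, 2.0 | mm, deg | per-axis exclusion thresholds, strict inequality, excursion measured from the first retained frame |
| `fwhm_mm` | 4 | mm | spatial smoothing kernel |
| `band` | 0.01–0.08 | Hz | ideal band-pass (DC removed) |
| `gm_threshold` | 0.40 | — | gray-matter probability threshold |
| `first_level_q`, `first_level_extent` | 0.01, 20 | —, voxels | first-level FDR and extent filter |
| `cluster_forming_z`, `cluster_alpha` | 2.3, 0.05 | — | GRF cluster inference |
| `sphere_radius_mm` | 5 | mm | ROI sphere radius |

The FD definition is the Power-style scalar (sum of absolute backward
differences, rotations converted to arc length on a 50 mm sphere), the form
standard in the micro-motion literature that motivates using FD as a
covariate. The exclusion rule is applied per axis with strict inequality
("greater than" 2 mm / 2 degrees); a combined rotation magnitude would only
make exclusion stricter.

## The synthetic cohort generator

The package validates every stage against a generator with known ground
truth rather than against scan data, which a three-group clinical design of
this size cannot provide in a reproducible, redistributable form.

**Correlation construction.** Each mirror voxel pair receives
`x = sqrt(rho) c + sqrt(1 - rho) e1`, `y = sqrt(rho) c + sqrt(1 - rho) e2`
with `c, e1, e2` independent unit-variance AR(1) processes (lag-1
autocorrelation 0.3 by default), giving population correlation exactly `rho`
at linear cost — a covariance-matrix factorization would cost the same
exactness cubically. Regions are spheres on the right side of the grid (the
mirror is implied); gray-matter voxels outside regions receive a background
correlation of 0.2, other voxels 0. Because any linear filter applied
identically to both members of a pair scales the shared and idiosyncratic
components' variances equally in expectation, detrending, band-passing and
nuisance regression leave the planted correlation intact; smoothing mixes
only same-rho neighbors under a mirror-symmetric kernel, so it too preserves
the planted value away from region edges (edge voxels shrink toward the
background value, which dilutes region means slightly but identically across
groups). Optional spatial noise smoothing is applied within each hemisphere
separately so that it can never manufacture homotopic correlation across the
midline.

**Between-subject variability.** Subject-level true regional connectivity is
drawn as `tanh(atanh(rho_group) + N(0, sd))` with `sd = 0.17` on the Fisher-z
scale. The default is chosen so that published-scale ROI group comparisons
come out at realistic strength: with group means around 0.86/0.83/0.67 and
n = 54, a pooled within-group SD of 0.17 yields a one-way F near 6, typical
of reported regional zVMHC contrasts in cohorts of this size. This term is what makes
score–connectivity coupling well defined and gives the group comparisons
realistic, rather than degenerate, power.

**Scores.** Clinical scores are generated as
`mean + sd (target_r z_std + sqrt(1 - target_r^2) noise)` where `z_std` is
the standardized true regional z across the coupling's cohort, so the
population score–connectivity correlation equals `target_r`. AHRS is
generated for AVH subjects only. Default marginal means and SDs are
plausibility values for first-episode patient cohorts (e.g. PANSS total
≈ 97 ± 21 across patients, AHRS ≈ 26 ± 8) and are defaults, not assertions.

**Motion.** Traces are bounded random walks (each parameter rescaled to stay
strictly below 0.9 mm / 0.9°, so worst-case excursions stay strictly under
the 2.0 thresholds); planted outliers add a smooth 4.5-unit excursion on one
random axis, which guarantees exceedance under any reference frame.
Rotations are stored in degrees, matching the degree-based exclusion rule.
The default cohort is 18 AVH + 18 NonAVH + 20 Control subjects with two
outliers planted in the AVH group, so motion exclusion retains 16/18/20 = 54
— the generator's group sizes are pre-exclusion counts and exclusion itself
is what produces the analyzed cohort.

**What the generator does not emulate:** slice-timing offsets, susceptibility
distortion, scanner drift beyond a linear trend, physiological noise,
anatomical variability, or registration error (data are born on a common
symmetric grid, replacing the nonlinear warp to a symmetric template with
grid-level symmetry). Passing tests therefore demonstrate the correctness
and calibration of the statistical machinery under the stated noise model,
not robustness to registration or physiology-driven artifacts in real scans.

## Numerical choices

- **Smoothing boundaries** use half-sample reflective padding; the per-axis
  convolution operator is then symmetric, so the volume's total mass is
  conserved to machine precision (a testable contract).
- **Connected components** use 26-connectivity, the common toolbox default;
  labels are deterministic (largest component first, ties by scan order).
- **Peak ties** break by smallest linear index.
- **Smoothness estimation** pools the lag-1 spatial autocorrelation of
  model residuals per axis over the mask and inverts the Gaussian ACF
  (`rho = exp(-d^2/(4 sigma^2))`); resels are mask volume divided by the
  FWHM product. Estimates are clamped away from 0 and 1 so degenerate
  fields yield finite output.
- **GRF cluster p** combines the Euler-characteristic expected cluster count
  `E(m)` at the forming threshold with an exponential extent tail
  `P(S >= k) = exp(-k/E(n))` around the expected cluster size
  `E(n) = V Phi_c(u)/E(m)`, and
  `p = 1 - exp(-E(m) P(S >= k))`. The asymptotic stretched-exponential tail
  in `k^(2/3)` was evaluated first and found severely conservative at the
  Z = 2.3 forming threshold on lattices at realistic smoothness (empirical
  familywise error below 0.01 at nominal 0.05 even with the true smoothness
  supplied); the plain exponential tracks both the empirical familywise
  error and the permutation max-cluster null closely in the regimes tested,
  and the permutation oracle — label permutation with the covariate kept
  with its subject, maximum supra-threshold cluster size per permutation —
  remains the arbiter wherever the analytic approximation is in doubt.
- **Rank-deficient designs** (e.g. a constant covariate) are pruned
  deterministically, leftmost columns kept, with df adjusting accordingly;
  this is what reduces the ANCOVA to a plain ANOVA when the covariate is
  degenerate.
- **Degenerate inputs**: zero-variance voxel series are flagged invalid in
  VMHC; empty supra-threshold sets yield empty cluster results rather than
  errors; `|r| = 1` correlations return p = 0 with a warning.

## Problem sizes in the validation suite

The shipped checks run at sizes chosen to make their sampling error small
relative to the tolerances they assert: correlation recovery uses 50
replicate subjects per planted level at T = 230 on an 8³ grid; ANCOVA
type-I calibration uses 2000 null voxels at n = 54; familywise-error
calibration uses 500 null cohorts (two smoothness levels, 18³ grids at 2 mm);
the permutation comparison uses 2000 permutations on 16³ two-group fields;
and end-to-end classification uses 20 replicate cohorts of 54 subjects on a
14×16×14 grid with one planted region per dysconnectivity category
(connectivity reductions of 0.35 on the z scale, sized for near-unit
per-cohort recovery power). Region placement in that spec keeps region
surfaces well inside the gray-matter band and far enough apart that
supra-threshold blobs of different categories rarely touch; cluster–region
matching is nevertheless done by voxel overlap (peak taken within the
region), so occasional merging of adjacent clusters does not corrupt the
classification.

## Known limitations

- The GRF approximation is validated against permutation in the tested
  regimes (Z = 2.3, smoothness 2–4 voxels, small masks); far outside them —
  very high thresholds, very coarse smoothness, highly non-stationary
  fields — the permutation route should be preferred outright
  (`permutation_cluster_null`).
- Mirroring is index reversal on an already-symmetric grid; the package does
  not perform registration, so applying it to real scans requires prior
  normalization to a symmetric template by external tools.
- The Gaussianized F field is treated as a Gaussian field for cluster
  inference, as legacy toolboxes do; at very low df this slightly
  underestimates corrected p, which the permutation comparison bounds.
- Sphere membership is unweighted voxel-center inclusion; no partial-volume
  weighting.
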