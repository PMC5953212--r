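---
title: "Beam-dependent PTV margins: model, numerics and verification"
author: "bdptv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-dependent PTV margins: model, numerics and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bdptv)
```

## The problem

External-beam photon radiotherapy must deliver a prescribed dose to a
clinical target volume (CTV) whose position relative to the treatment beams
is uncertain: preparation (systematic) errors displace the whole treatment
course, execution (random) errors displace individual fractions. Clinical
practice compensates by expanding the CTV into a planning target volume
(PTV). The margin recipe used here,

$$ M = \alpha\,\Sigma + \beta\left(\sqrt{\sigma_r^2 + \sigma_p^2} -
\sigma_p\right), $$

sizes that expansion from the systematic SD $\Sigma$, the random SD
$\sigma_r$ and the Gaussian penumbra SD $\sigma_p$ of the beam.
$\alpha$ is the radius enclosing the desired probability mass of a standard
$d$-variate normal (the chi-distribution quantile; `coverageAlpha(3, 0.90)`
$= 2.50$) and $\beta$ the one-sided normal quantile of the minimum dose
level (`penumbraBeta(0.95)` $= 1.64$). The recipe targets 90% of the
patient population receiving at least 95% of the prescription throughout
the CTV.

A volumetric margin ignores beam geometry: displacements *along* a photon
beam barely change the delivered dose (attenuation is exponential and
shallow), while displacements *perpendicular* to it can move the target out
of the field. This package implements a beam-dependent margin concept that
expands the CTV only perpendicular to each beam:

1. the trivariate uncertainty Gaussian is collapsed (marginalised)
   analytically onto the plane perpendicular to each beam
   (`collapseUncertainty()`);
2. every CTV voxel is expanded in that plane by the 2D margin recipe
   ($\alpha_{2D} = 2.1460$, the 90% quantile of the 2D chi distribution),
   giving one beam-dependent PTV (bdPTV) per beam (`buildBdptv()`);
3. the per-voxel fraction of beams whose bdPTV covers a voxel forms the
   overlap map $o_k \in \{0, 1/B, \ldots, 1\}$ (`buildOverlapMap()`), which
   is 1 on the CTV;
4. the overlap map weights the voxel's target-versus-OAR character inside a
   piecewise-quadratic planning objective, so a voxel can be a fractional
   target and a fractional organ at risk at the same time.

## Margin generation details

**Plane basis.** For beam direction $\hat d$, $e_1 = \hat d \times
\hat z / \lVert\cdot\rVert$ (falling back to the LR axis for beams parallel
to SI) and $e_2 = \hat d \times e_1$; for coplanar beams $e_2$ is
(anti)parallel to the SI axis. This makes the collapsed covariance exactly
diagonal for coplanar beams with a diagonal patient covariance.

**Anisotropy.** The 2D recipe is applied per principal axis of the
collapsed systematic covariance; the collapsed random covariance is
projected onto those axes. This is exact for coplanar beams with diagonal
covariance and a controlled approximation otherwise. An isotropic variant
(`margins2D(..., isotropic = TRUE)`) uses the larger semi-axis for both.

**Rasterisation.** A voxel belongs to a bdPTV iff, relative to some CTV
voxel, its centre displacement has a beam-parallel component within that
voxel's half-extent along the beam and a perpendicular component inside the
margin ellipse. The 3D PTV is the Minkowski sum of the CTV voxel cubes with
the margin ellipsoid, rasterised by voxel-centre inclusion. Both are
evaluated by structuring-element dilation and are checked exactly against
brute-force per-voxel-pair oracles in the test suite. Voxel-centre
(not partial-volume) rasterisation is used throughout: the overlap map, not
sub-voxel geometry, carries the fractional information.

## Planning objective

The exclusive-VOI form assigns every voxel inside the external contour to
exactly one structure by priority (targets first, then rectum, bladder,
femoral heads, external normal tissue) and sums

$$E = \sum_{k \in T} s^u_k [d^{min}_k - d_k]_+^2 + s^o_k [d_k -
d^{max}_k]_+^2 \;+\; \sum_{k \in O} s^o_k [d_k - d^{max}_k]_+^2 .$$

The overlap-weighted form blends, per voxel,
$E_k = \sum_i o^i_k E^i_k + (1 - \sum_i o^i_k) E^{OAR}_k$, with
target-level thresholds in $E^i_k$ and voxel-assigned (margin-free cube)
parameters in $E^{OAR}_k$. With binary overlap values it reduces exactly to
the exclusive form; this equivalence is a test invariant.

**Per-VOI normalisation (design choice).** By default every structure's
penalty weights are divided by its voxel count (for overlap targets, by
$\sum_k o_k$, which equals the voxel count in the binary limit and
preserves the equivalence above). Without normalisation the stationary
point of the blended objective in a margin ring sits 1–2.5 Gy below the
95% prescription level — the externally-weighted overdose term of the vast
normal-tissue structure overwhelms the fractional target term — and no
optimiser could hold the margin near the prescription, defeating the
purpose of the margin. Inverse-planning systems in this objective family
conventionally normalise per structure volume for exactly this reason. The
un-normalised sums remain available via `normalize = FALSE`.

**Optimiser.** Fluence weights are optimised by projected gradient descent
with an exact quadratic line search along the negative gradient (the
objective is convex piecewise quadratic, so the directional curvature over
the active set gives the minimising step) plus a halving safeguard;
iterates are projected onto the nonnegative orthant, the accepted objective
trace is non-increasing, and sub-gradients at threshold kinks are taken as
zero (a measure-zero choice). Defaults: relative-change tolerance `1e-6`,
500 iterations; the packaged four-plan study uses `1e-5`/300, which
reproduces the intended contrasts while keeping the study desk-scale.
Deliverable aperture sequencing is out of scope: plans are fluence-only.

## Dose engine

A deliberately simple pencil-beam model supplies the sparse dose-influence
matrix: water-equivalent homogeneous patient, exponential depth attenuation
($\mu = 0.005\,\mathrm{mm^{-1}}$, a 6 MV effective value) measured from the
external-contour entry, and a separable error-function lateral profile of
finite beamlets ($5 \times 5\,\mathrm{mm^2}$, parallel rays) blurred by the
penumbra SD. $\sigma_p = 3.2$ mm is used both in the kernel and in the
margin recipe — the recipe's $\beta$ term presumes the planning system's
own penumbra. Beamlets are restricted per beam to cells covering the
aperture structure's beam's-eye-view projection plus one ring; kernel
entries below $10^{-4}$ of the column maximum are pruned. The 80%–20%
penumbra width of a broad field, $1.683\,\sigma_p$, is a test invariant.

## Monte-Carlo verification

Under the static-dose-cloud approximation the planned dose is fixed in
space and the anatomy samples it: each simulated patient draws one
systematic shift $a_s \sim N(0, \mathrm{diag}\,\Sigma^2)$ and per-fraction
random shifts $b_n \sim N(0, \mathrm{diag}\,\sigma_r^2)$, and accumulates
$d_{c,s}(x) = \tfrac1F \sum_{n=1}^F d(x + a_s + b_n)$ by trilinear
interpolation (positions outside the padded dose grid contribute zero).
DVH metrics use discrete definitions: $V_d$ is the percent of voxels at or
above $d$; $D_q$ is the largest dose with $V_d \ge q$ taken from the sorted
voxel doses without interpolation (reproducible and oracle-checkable).
Coverage probability is the passing fraction of the population; dose-volume
coverage maps (DVCM) accumulate the solid-under-the-DVH indicator over
samples on a 0.5 Gy × 1% grid by default, and DVCDMs are signed differences
of two DVCMs on identical bins. Random draws are per sample × per fraction
with no variance-reduction shortcuts; everything is reproducible from one
integer seed through an isolated RNG scope.

## The synthetic phantom

No patient data ships with the package; `phantomSpec()` emulates a prostate
case: a ~38 cm³ ellipsoidal CTV (semi-axes 21/19/23 mm), a posterior
rectum cylinder abutting the CTV (rasterised with a 2 mm analytic overlap
clipped against the CTV so face adjacency survives the ±1 mm seeded organ
jitter), an anterior-superior bladder, lateral femoral-head spheres and an
elliptic-cylinder external contour, on a 1.91 × 1.91 × 2.5 mm (LR, AP, SI)
lattice by default. The CTV size was chosen to sit in the realistic
prostate range; with the study margins (3.87/5.93/3.78 mm) the resulting 3D
PTV is ~80 cm³. The phantom reproduces geometry and abutment topology, not
CT intensities, inter-patient shape variation, rotations or deformations —
so passing tests demonstrate the machinery and its trends, not
patient-specific dosimetry.

The packaged study conditions are: systematic SDs 1.1/1.5/1.1 mm and random
SDs 2.2/3.2/2.1 mm along LR/AP/SI, seven equidistant coplanar beams from
gantry 0°, 78 Gy in 39 fractions, and the default objective table (prostate
74.5–82 Gy weight 10; rectum max 70/65/60 Gy weight 8; bladder max 70 Gy
weight 6; femoral heads max 50 Gy weight 2; external max 60 Gy weight 2).

## Problem sizes

The four-plan study and its verification are run on a 3 mm isotropic grid
(~73 × 63 × 53 voxels, ~770 beamlets) with an evaluation population of
2000 × 39 fractions; these sizes keep the complete pipeline at a few
minutes on one core while leaving Monte-Carlo standard errors near one
percentage point. The full-resolution lattice and the 50 000-sample
population remain the defaults of `defaultStudyFixture()` and
`evaluationConfig()` for users who want them.

## Known limitations

- **Delivery granularity.** Fluence-only optimisation can sculpt dose at
  the beamlet/penumbra scale. Fully converged, it drives overlap-ring doses
  to the underdose threshold exactly — the cheapest feasible solution —
  whereas a coarse, segment-limited delivery leaves those rings near the
  prescription. Population D98 coverage of the beam-dependent plans is
  therefore sensitive to the optimiser's convergence depth and delivery
  model, and a fluence-optimal plan can trade more coverage for OAR sparing
  than a deliverable plan would. The conventional 3D-margin plan is
  insensitive to this because its whole PTV carries the full underdose
  objective.
- Homogeneous water-equivalent dose model: no heterogeneity, scatter
  kernels or divergence; absolute dosimetry is schematic, trends are the
  product.
- Rigid translations only; no rotations, deformations or intrafraction
  motion.
- Dose is never recomputed per scenario (static dose cloud), which is the
  standard prostate-case approximation but fails near strong density
  gradients.
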