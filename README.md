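# bdptv — beam-dependent PTV margins and probabilistic plan evaluation

`bdptv` is an R package for studying a probabilistic alternative to the
conventional CTV-to-PTV safety margin in photon IMRT planning. It is aimed
at medical-physics researchers who want a self-contained, reproducible
sandbox for margin concepts without patient data.

## The idea

Geometric uncertainty in radiotherapy splits into systematic (preparation)
errors with SD Σ and random (execution) errors with SD σ_r. The classic
margin recipe expands the CTV by

    M = α Σ + β (√(σ_r² + σ_p²) − σ_p)

per axis, where σ_p is the Gaussian penumbra SD of the beam, α is the
radius enclosing the desired probability mass of a d-variate standard
normal (α = 2.50 in 3D for 90% population coverage) and β = 1.64 is the
one-sided normal quantile for the 95% dose level.

Because photon dose varies slowly *along* a beam but sharply *perpendicular*
to it, this package builds margins per beam: the uncertainty Gaussian is
collapsed analytically onto each beam's perpendicular plane, every CTV voxel
is expanded by the 2D recipe (α_2D = 2.1460) in that plane only, and the
union of the expansions forms a beam-dependent PTV (bdPTV). The per-voxel
fraction of beams covering a voxel — the overlap map o_k ∈ {0, 1/B, …, 1} —
then weights the target-vs-OAR character of each voxel inside a
piecewise-quadratic fluence optimisation objective. A Monte-Carlo
verification tool shifts the planned dose under sampled systematic and
per-fraction random errors, accumulates fractionated dose by trilinear
interpolation, and reports population probabilities of DVH objectives plus
dose-volume coverage maps (DVCM) and their differences (DVCDM).

All of it runs on a seeded synthetic prostate phantom (ellipsoidal ~38 cm³
CTV, abutting posterior rectum, anterior-superior bladder, femoral heads,
external contour).

## Worked example

```r
library(bdptv)

coverageAlpha(3, 0.90)   # 2.500278  -> the 3D margin coefficient, 2.50
penumbraBeta(0.95)       # 1.644854  -> the dose-level coefficient, 1.64

fx <- defaultStudyFixture(spacing = c(3, 3, 3))  # coarse desk-scale grid
vanHerkMargins(fx$uncertainty)
# [1] 3.874230 5.930643 3.782504   (mm margins along LR, AP, SI)

study <- runPlanStudy(fx)
study
# PlanStudy with plans: 3D_R70, 2D_R70, 2D_R65, 2D_R60
#   3D PTV 80.49 cm^3, bdPTV union 58.62 cm^3
```

The bdPTV union is markedly smaller than the conventional 3D PTV — the
margin lost is the one along each beam, where dose hardly changes. The
four plans share one dose-influence matrix: a conventional plan on the
3D-margin PTV and three overlap-weighted plans with rectum max dose
70/65/60 Gy. Verifying, e.g., the rectum V70Gy < 5% objective at population
2000:

```r
cfg <- evaluationConfig(populationSize = 2000, fractions = fx$fractions,
                        uncertainty = fx$uncertainty, seed = 101)
v70 <- dvhObjective("rectum", "V", dose = 70, volume = 5, comparator = "<")
coverageProbability(study@plans[["3D_R70"]], study@anatomy$rectum, cfg, v70)
# CoverageResult [rectum, V_70Gy < 5%]: 0.6805 (SE 0.0104, n = 2000)
coverageProbability(study@plans[["2D_R70"]], study@anatomy$rectum, cfg, v70)
# CoverageResult [rectum, V_70Gy < 5%]: 1.0000 (SE 0.0000, n = 2000)
```

The conventional plan pushes prescription dose into the rectum wherever the
PTV overlaps it, so it frequently violates the high-dose rectum objective;
the beam-dependent plans trade that high dose away. `evaluateStudy()` +
`writeStudyReport()` produce the full per-plan/per-objective CSV, and
`buildDvcm()` / `dvcmDifference()` the coverage-map surfaces.

A thin command-line front end over these functions is installed at
`inst/cli/bdptv.R` (subcommands `phantom`, `margins`, `plan`, `evaluate`,
`study`), configured by YAML files like `inst/extdata/default_study.yaml`.

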