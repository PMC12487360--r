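---
title: "Modeling normative fetal brain growth: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling normative fetal brain growth: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalgrowth)
```

This vignette documents the models implemented in **fetalgrowth**, the
assumptions behind them, the numerical choices that matter, and what the
synthetic validation data do and do not establish. The package targets the
second half of rhesus macaque gestation (conception to birth is about 165
days), where the fetal brain roughly quintuples in volume and the cortical
plate folds; all ages are days post-conception, volumes are mL, surface
areas cm², curvature 1/mm.

## Growth-curve families and BIC selection

Brain-region size versus age is fit with five candidate families:

* linear, `V(t) = m t + b`;
* quadratic, `V(t) = c0 + c1 t + c2 t²` (needed for the ventricles, whose
  volume follows a U-shaped trajectory);
* three-parameter logistic (3PL), `V(t) = A / (1 + exp(-Rg (t - tmid)))`,
  with asymptote `A`, maximal-rate parameter `Rg`, and inflection age
  `tmid`; the maximal absolute growth rate is `A·Rg/4`, attained at `tmid`;
* four-parameter logistic (4PL), which relaxes the 3PL's near-zero value at
  `t = 0` to an offset `B`;
* Gompertz, `V(t) = a·exp(-b·exp(-c t))`, suited to growth with a fast
  acceleration and a protracted deceleration; its descriptors are
  `tmid = ln(b)/c` and maximal rate `a·c/e`.

The family with the lowest BIC wins. We use the Gaussian-likelihood form
`BIC = n·ln(rss/n) + k·ln(n)` and count the residual variance as a free
parameter, so `k` is the number of free curve parameters plus one; whether
the variance parameter is counted is a convention, and it does not change
the ranking between two models fit to the same data (it shifts all BICs by
the same constant within a fixed `n`). Non-converged families are excluded
from the ranking and recorded with infinite BIC; ties below `1e-6` go to
the family with fewer parameters.

Sigmoid fits use bounded Levenberg-Marquardt least squares with
deterministic, data-driven starting values: `A₀ = 1.1·max(V)`,
`B₀ = min(V)`, `tmid₀` the first age at which the series exceeds half its
maximum, and `Rg₀ = 4·(max-min)/(age range · A₀)`; the Gompertz start is
moment-matched from the logistic configuration (equal asymptote and maximal
rate). Bounds are generous but exclude degenerate optima: asymptotes in
`(0, 10·max(V)]`, rate parameters in `(0, 1]` per day, `tmid` in `[0, 400]`
days. Flat series and series with fewer distinct ages than free parameters
are reported as non-converged rather than as errors, so that vertex-wise
map fitting can simply mask such vertices. The 3PL formula is implemented
literally; it only approaches 0 at `t = 0` rather than equaling it, and we
treat the "constrained to 0" reading as a description of that limit.

A fit with an exact interpolation (zero residual) is admitted — a line
through two points is the obvious case — with the BIC kept finite by
clamping the residual sum of squares at the smallest positive double.

Percent-of-adult fits express fetal volumes as `100·V/V_adult` and refit
the 3PL with `A` pinned at 100, leaving `Rg` and `tmid` free; the maximal
relative growth rate is then `25·Rg` %/day. Values above 100 are tolerated
(noise overshoot), with a warning when the latest age group averages above
110. Note that an inflection age beyond the sampled range (the cerebellum's
maximal relative growth falls after birth) is an extrapolation: it is
identifiable from the curvature of the sampled rise, but its uncertainty
grows with distance from the data.

## Two-stage inference: residuals plus a random-intercept mixed model

Because every structure grows nonlinearly, covariate effects are tested in
two stages: (1) fit the BIC-selected population curve for the region;
(2) model the residuals `r_i = V_i − V̂(age_i)` with

```
r_i = β0 + β1·age_i + β2·sex_i + β3·age_i·sex_i + b_subject + ε_i
```

a linear mixed model with a per-fetus random intercept absorbing repeated
scans. Estimation is REML; p-values use Satterthwaite denominator degrees
of freedom and α = 0.05; confidence intervals are `β ± t(df, 0.975)·se`.
Sex is coded female = 0, male = 1, so a positive `β3` means the male slope
exceeds the female slope; the source convention for published coefficient
signs is not stated, so signs may differ from other reports even when the
science agrees. Age enters uncentered, in days. Confound screens (scanner
version, reconstruction method, scan number, acquisition resolution, pulse
sequence) reuse the same formula with the confound in place of sex.

When no fetus has a repeated scan the random intercept is unidentifiable;
the fit then reduces exactly to ordinary least squares with classical
residual degrees of freedom, flagged as a boundary case. Bonferroni
correction (`min(1, m·p)`) is applied across the regions tested together:
`m = 7` for the volumetric family (whole brain, cortical plate, nascent
white matter, subcortical gray matter, brainstem, cerebellum, ventricles)
and `m = 3` for the surface metrics (area, K*, thickness). Random slopes,
crossed dam effects, and Kenward-Roger df are deliberately out of scope —
the model is intercept-only by design.

## Volumetry

Compartment volumes are voxel counts times the voxel volume (mm³/1000 =
mL). The "atlas" aggregation scheme combines the labels identifiable at
all seven fetal ages: whole brain is everything except extra-axial CSF;
intracranial volume (ICV) includes it; nascent white matter pools the
subplate, germinal matrix, and corpus callosum; subcortical gray pools the
thalamus, striatal structures (whose label codes split as parcellation
becomes possible with age — all variants map to the same compartment so
every age aggregates identically), hippocampus, amygdala, and
hypothalamus. Labels absent at a given age simply contribute zero. Two
identities hold by construction and are tested: ICV = whole brain +
extra-axial CSF, and whole brain partitions into its six reported
compartments.

## Mid-cortical surface extraction and morphometry

The mid-cortical surface is the 0.5-isosurface of an edited binary mask:
after removing the brainstem, cerebellum, and extra-axial CSF (and
restricting to a hemisphere at the volume's mid-sagittal x-midpoint), the
remaining non-cortical-plate labels form an interior mask; each cortical
plate voxel joins the mask when its Euclidean distance to the interior is
no greater than its distance to the outside of the brain (ties join the
interior, which biases the boundary toward mid-depth), and is dropped
otherwise. The edited mask is smoothed with a 5×5×5 uniform box filter
before isosurfacing.

The isosurface is extracted by marching tetrahedra: each grid cube is split
into six tetrahedra around a shared diagonal (a decomposition that is
consistent across neighboring cubes, so the result is watertight by
construction), with vertices placed by linear interpolation and triangles
oriented outward. Field values exactly at the level are nudged to the
interior side, consistent with the distance tie rule. The largest connected
component is kept, and the mesh is then regularized with 50 passes of
Taubin λ|μ smoothing — a shrink-free low-pass filter that removes
voxel-scale staircase artifacts; on a 0.5 mm sphere phantom it changes the
surface area by under 0.1% while removing most of the spurious curvature.
Extraction is deterministic and assumes isotropic voxels for the distance
comparison.

Morphometrics follow the standard conventions: per-vertex area is one
third of incident triangle areas (partitioning the total area exactly);
mean curvature comes from the cotangent-Laplacian mean-curvature normal
with Meyer mixed vertex areas, signed by the outward normal so a sphere of
radius r has `H = +1/r`; non-dimensionalized curvature is
`K* = ⟨|H|⟩_area · sqrt(SA/4π)`, dimensionless, scale invariant, 1 for a
sphere, increasing with folding; thickness is cortical plate volume over
mid-cortical surface area (`10·mL/cm²` in mm). Curvature magnitude (not
signed curvature) is aggregated because the signed mean cancels between
gyral and sulcal banks on a folded surface and would not increase with
gyrification; the absolute K* values of other tool chains may differ with
their curvature conventions even when the trajectory shape agrees. For
meshes extracted from voxel data, the curvature field is additionally
smoothed with 10 neighbor-averaging passes (`field_smoothing`), a
regularization that brings the extracted sphere phantom's K* within 2% of
1 without affecting the ordering of folded phantoms; analytically
constructed meshes do not need it and the default for raw meshes is none.

## Expansion mapping

Vertex correspondence across ages is an input (in practice the output of a
spherical registration such as aMSM; here, synthetic sequences with exact
correspondence). Per-vertex expansion between two corresponding meshes is
the arithmetic mean of the forward area ratio and the reciprocal of the
reverse contraction — identical to the exact ratio when correspondence is
exact, and a symmetrized estimate otherwise (a geometric mean is available
as an option). Expansion relative to the reference age (the youngest) is 1
at the reference by definition; display conventions that show the
reference as "0 expansion" are just that. Each vertex's expansion-vs-age
series, including the adult time point, is fit with the 3PL (asymptote
capped at 50), giving maps of asymptotic expansion `A`, maximal rate `Rg`,
and timing `tmid`; non-converged vertices are masked. The adult sample has
no natural gestational abscissa; we place it at 1770 days post-conception
(165-day term plus ~4.4 years), and since the adult point sits far on the
saturated limb of the logistic, the fitted fetal-period parameters are
insensitive to its exact placement. Stage-wise mean expansion differences
are weighted by reference-age vertex areas.

## Synthetic data: what it emulates, and what it does not

`simulate_cohort()` reproduces the atlas sampling design: 50 fetuses (28
female), 105 scans allocated to the seven target ages in the template
proportions (31, 5, 20, 6, 28, 6, 9), 1-4 scans per fetus, ±7 days of
uniform age jitter. Region values follow the published growth parameters
(sex-specific where sex differences were reported), plus a per-fetus
Gaussian intercept and independent Gaussian noise. Defaults: noise SD 2%
of the age-specific model value (heteroscedastic, as segmentation error
scales with structure size) and intercept SD 4% of the region's value at
the mid-study age G122 — large enough to make recovery nontrivial, small
enough to keep the published effect sizes detectable at this sample size.
The 4PL offset `B` for nascent white matter is not published; 1.5 mL is
assumed. The ventricular quadratic is calibrated qualitatively (minimum
near G110-G116, recrossing its G85 value late in gestation). Confound
columns are emitted independent of the measurements unless an association
is requested.

Phantoms are concentric-shell "heads" (ventricle core, subcortical shell,
subplate shell, 2 mm cortical plate shell, CSF) with analytic compartment
volumes and mid-surface area; the folded variant displaces the cortical
shell by a smooth angular ripple of known parametric area. Growing mesh
sequences displace icosphere vertices radially under a logistic-in-time,
smooth-in-space field with recorded per-vertex truth.

Passing on these data establishes internal correctness — the estimators
recover known truth under the stated noise model — not robustness to what
real fetal MRI adds: motion and reconstruction artifacts, segmentation
bias that varies with age and tissue contrast, non-Gaussian outliers,
dam-level clustering of littermates, and registration error in the vertex
correspondence. Those are properties of the upstream imaging pipeline,
which this package deliberately takes as given.

## Problem sizes and reproducibility

All generators are deterministic under a fixed seed. The validation suite
uses cohort simulations of the full design (105 scans) with 100-200
replicates for parameter recovery and calibration, 100 seeds per family
for BIC selection, 1000 null simulations for the type-I error of the
interaction test, 0.5 mm phantoms of ~90³ voxels, and icosphere meshes of
642-2562 vertices — sizes chosen so each property is measured with useful
Monte-Carlo precision while the whole suite runs in minutes on one core.
With these conditions the measured values sit comfortably inside their
tolerances (e.g. interaction type-I error ≈ 0.05, extracted-sphere K*
within 2% of 1, median `tmid` recovery error under one day).

One behavior worth knowing: with realistic noise the brainstem's shallow
Gompertz trajectory is frequently better scored by the quadratic — over a
70-day window a gentle sigmoid and a parabola are nearly
indistinguishable, and BIC rewards the distinction only as noise shrinks
(the selection-consistency property tested at decreasing noise). Model
selection on real cohorts should therefore be read per-region with the
BIC table, not as a single hard answer.
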