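---
title: "craniomorph: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{craniomorph: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniomorph)
```

This vignette is the package's own account of what it computes, which
knobs matter, and where genuinely open design choices were resolved.

## The landmark scheme

The scheme is a fixed catalogue of 36 ectodermal surface landmarks for
E10.5–E12.5 mouse embryo heads: 6 midline points (ids 1–5, 22) and 15
bilateral pairs (left id `n`, right id `n + 17`), with ids 19 and 36
unused — the gap is part of the standard numbering and is preserved
without interpretation. Ids are opaque labels, never array indices. Each
landmark carries an anatomical subset (`Nasal`, `MaxMand` for
maxillary/mandibular, `NonFacial`) and a `trouble` flag marking points
with elevated placement error. Distinct from the trouble column, the
five-landmark removal recommendation (`suggested_removals()`: 2, 7/24,
17/34, 18/35, 21/38) excludes the two trouble landmarks (10/27, 13/30)
whose definitions are considered clarifiable rather than hopeless.

## The generative model

`simulate_dataset()` draws a balanced (specimen × observer × trial)
design. Per observation and landmark, in mm:

```
coords = specimen_true + bias(observer, landmark) + N(0, sigma_trial^2 I3)
```

with `specimen_true` built from a stylized, bilaterally symmetric
36-point head template:

1. A specimen's centroid size `CS_s` is drawn around its age target
   (`growth`, default 6/7.5/9 mm) with coefficient of variation `cs_cv`
   (default 4%, a typical within-litter spread).
2. The unit shape is the base template displaced along a fixed unit
   *allometry direction* by `allometry_slope * (CS_s − mean CS)`, then
   scaled to `CS_s`. The direction encodes the qualitative ontogeny of
   this period: facial bilateral landmarks move rostrally and toward the
   midline, midline facial points rostro-ventrally, non-facial points
   caudo-dorsally. It is orthogonalized against the similarity
   transforms of the template so it is a pure shape direction.
3. Isotropic specimen-level shape noise (`sigma_specimen`, default
   0.05 mm) is added.

Observer bias is a fixed per-(observer, landmark) 3-vector drawn once
per simulation with s.d. `observer_bias_scale` (default 0.05 mm,
per-observer vector allowed) — modelling observers who hold stable but
different interpretations of a landmark definition. Trial noise is
isotropic Gaussian with per-observer s.d.: 0.02 mm for the three
experienced observers and 0.06 mm for the novice. Under the two-trial
distance law (`sigma * sqrt(2) * chi_3`) these give median
trial-to-trial errors of about 0.045 mm and 0.13 mm — below and above
the 0.1 mm working reference, matching the qualitative experienced /
novice contrast the design is meant to emulate. Trouble-flagged
landmarks have bias and trial noise inflated by `trouble_inflation`
(default 2.5).

All draws come from R's Mersenne–Twister stream (normal deviates by
inversion) seeded with `seed`, so datasets are bit-reproducible from
their parameters, and scaling `observer_bias_scale` at a fixed seed
rescales the identical bias field.

### Slope calibration

`calibrate_allometry_slope()` chooses the default `allometry_slope` in
closed form so that the expected share of Procrustes-coordinate variance
explained by centroid size is 80%. The calculation uses the design's CS
spread, the effective per-coordinate noise on per-specimen mean shapes
(specimen noise plus trial noise averaged over experienced observers and
trials, divided by mean CS to reach shape scale), `3k − 7` effective
shape coordinates (GPA removes 7 similarity degrees of freedom), and the
finite-sample overfitting term of per-coordinate least squares
(`E[SS_reg] = signal + sigma^2` per coordinate). Observer bias does
*not* enter: it is fixed across specimens, so averaging the same
observers for every specimen shifts all mean shapes identically and
contributes nothing to between-specimen variance. Empirically the
realized percentage sits a couple of points below the target because the
unit-scaling of displaced shapes and GPA are mildly nonlinear in the
displacement; the acceptance check allows ±7 points.

### What the generator does not emulate

Real embryo surfaces have spatially correlated, anisotropic placement
error (sliding along ridges), age-dependent observer disagreement,
fixation artefacts, and staging variation within an embryonic day. The
template is topologically faithful (midline/bilateral structure, facial
vs non-facial position, mm scale loosely set so head size and landmark
spacing are realistic) but anatomically stylized. Tests passing on
synthetic data therefore validate the *statistical machinery* — not any
claim about real landmarking behaviour.

## Error analysis

Intraobserver error is the Euclidean distance between the two trial
placements; left/right values of a pair are pooled under the joint label
(values kept, label merged), reflecting that the sides show similar
error behaviour. Interobserver error is the centroid size of the
observers' trial-mean placements per (specimen, landmark instance),
sides kept separate; by convention only experienced observers enter.

The placement ANOVA uses, per age, one deviation distance per
(specimen, landmark instance, observer): each observer's trials are
averaged first, the specimen mean is the average of those observer
means over **all four** observers, and the response is the distance from
an observer's mean to the specimen mean. These conventions are forced by
the degrees-of-freedom arithmetic of the reference design: 10 specimens
× 36 instances × 4 observers gives N − 1 − 9 − 35 − 3 = 1392 residual
degrees of freedom at E10.5 (1249 at E11.5 with 9 specimens), which
only holds with four observers and trial-averaged observations. Three
main effects are fitted (`distance ~ specimen + landmark + observer`);
sequential sums of squares are order-invariant under balance, which the
function enforces (unbalanced input is an error, not a silent Type-I/III
choice). Distances, not coordinates, are the response — no multivariate
Procrustes ANOVA is attempted — and p-values are reported raw, without
multiple-testing correction. A constant response returns zero sums of
squares with `NA` F and p rather than numerically meaningless ratios.

Trouble flagging combines both channels: a pooled label is flagged if
its median intraobserver distance exceeds 0.1 mm for any (age,
observer) in the supplied table, or if the median interobserver CS of
either side at any age exceeds a threshold defaulting to the 90th
percentile of the per-(instance, age) medians. The percentile default
makes the interobserver channel adaptive to the overall error level;
the absolute 0.1 mm intra threshold is the field's working reference
for this embryonic scale.

## Procrustes machinery

- Ordinary (two-shape) alignment uses the SVD construction with the
  smallest singular pair sign-flipped when needed, so the rotation is
  always proper: reflections are forbidden everywhere because embryo
  heads are chiral.
- GPA scales every configuration to unit centroid size (full GPA), keeps
  raw CS separately as the size variable, starts the consensus at the
  first shape (center/scaled), and iterates until the consensus RMS
  change is below 1e-10 (max 100 iterations; non-convergence is flagged
  in the fit, not fatal). Input order does not affect the fit beyond a
  global rotation, which the invariance tests verify via pairwise
  Procrustes distances.
- Tangent-space projection is off by default — at within-sample shape
  scales the difference is negligible — but available (`tangent = TRUE`)
  as an orthogonal projection at the consensus.
- Baseline superimposition maps three anchor landmarks to a canonical
  frame (anchor 1 at the origin, anchor 2 on +x, anchor 3 in the
  xy-plane with positive y) by a right-handed construction, so subsets
  sharing the anchors have parallel axes by construction. Collinear
  anchors are an error.

## Allometry and the subset experiment

Specimen shapes entering the regression are per-specimen means over the
experienced observers' trial means (configurable). All ages are pooled
into one GPA; the regressor is raw CS in mm (the ontogenetic trend is
modelled as linear in CS, matching the generator). For each removal
subset the percent variance explained is computed from a fresh GPA and
regression of the remaining landmarks, with the subset's own centroid
size as regressor — the quantity a Procrustes analysis of that subset
would actually use.

Two genuinely open choices were resolved as follows:

- **Anchors.** The three baseline anchors default to 1, 22, and 8: two
  midline and one left-side point, all non-facial and non-trouble, hence
  present in every default subset except the non-facial removal — which
  mirrors the fact that no three landmarks survive all five removals.
  The non-facial subset falls back to its GPA frame rotated onto the
  all-landmark fit (`route = "gpa-aligned"`), or errors under
  `require_anchors = TRUE`.
- **The angle metric.** "Does removing landmarks change the trajectory"
  has no canonical numeric form; this package measures, per common
  landmark, the 3D angle between the subset's and the reference's slope
  vectors. Two technical safeguards make the comparison fair. First,
  both fields are put in the same registration (each subset's GPA frame
  is rotated onto the all-landmark GPA frame over the common landmarks)
  and then projected onto the subset's shape space — the orthogonal
  complement of the similarity transforms of the reference mean
  restricted to those landmarks — because a subset's superimposition
  structurally absorbs any component of the trajectory that acts on it
  as a net translation, rotation, or scaling, and leaving that component
  in the reference field would report large angles that reflect frame
  algebra, not biology. Second, angles are only reported for landmarks
  whose projected reference displacement is at least 25% of the RMS
  displacement (`min_rel_mag`): the direction of a near-stationary
  landmark is unidentifiable and its angle is pure noise.

## Numerical and interface details

- Coordinates are printed with 12 significant digits in CSV/TPS output,
  so a write/read cycle moves a millimetre-scale coordinate by well
  under 1e-9 mm.
- The TPS dialect is 3D `LM3=` blocks, one configuration per block, with
  `ID=specimen|age|observer|trial`; landmark order inside a block is the
  scheme's canonical listing order (left before right).
- Ages are categorical labels (`E10.5`, `E11.5`, `E12.5`); no
  fractional-day arithmetic exists anywhere.
- Degenerate inputs error early with the offending ids or cells named:
  missing landmarks, unbalanced designs, collinear anchors, constant
  centroid size, all-coincident configurations.

## Problem sizes used by the test suite

The suite exercises the full reference design (29 specimens × 4
observers × 2 trials × 36 landmarks) for the degrees-of-freedom and
calibration checks; 20 seeds for the variance-explained recovery; 100
and 200 simulation replicates for the observer-effect power and null
calibration checks (run on a single age to keep each replicate small);
and small random configurations (4–12 landmarks) for the brute-force
Procrustes and normal-equations ANOVA oracles. These sizes were chosen
so the whole suite completes in about a minute while leaving the
statistical checks well-powered.

## Known limitations

- The placement ANOVA treats distances as approximately homoscedastic
  and independent; within a (specimen, landmark) cell the deviations of
  the observers from their own mean are weakly negatively correlated by
  construction. The null calibration test shows the observer F-test
  holds its nominal level under the generator's conditions, but no
  claim is made for heavy-tailed or spatially correlated error.
- Percent variance explained from the regression is an in-sample
  quantity and includes the usual finite-sample optimism.
- No sliding semilandmarks, missing-landmark estimation, symmetry
  decomposition, size-corrected residual shape analysis, or formal test
  of vector-angle significance — the subset comparison is descriptive.
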