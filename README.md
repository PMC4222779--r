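# craniomorph

Landmark placement error and ontogenetic allometry for embryonic mouse
craniofacial surfaces.

## The problem

Between embryonic days (E)10.5 and E12.5 the mouse face is built by the
growth and fusion of the facial prominences. Because there is no bone yet,
craniofacial form at these ages is quantified by placing discrete landmarks
on the ectodermal surface extracted from micro-CT images. Two questions
decide whether such data can be pooled across studies and observers:

1. **How reliably can each landmark be placed?** Within one observer
   (trial-to-trial), and between observers who may hold different stable
   interpretations of the same written definition.
2. **How robust are downstream ontogenetic analyses** — the regression of
   shape on size that summarizes how the face changes as the head grows —
   to dropping landmarks that turn out to be unreliable?

`craniomorph` implements this entire analysis as a reusable, tested
pipeline around a standard scheme of 36 surface landmarks (6 midline points
and 15 bilateral pairs, ids 1–38 with 19 and 36 unused), each annotated
with an anatomical subset (`Nasal`, `MaxMand`, `NonFacial`) and a
trouble flag. Since raw embryo coordinates are rarely shared, the package
also ships a fully parameterized synthetic-data generator that emulates the
balanced design such studies use — 10/9/10 specimens at E10.5/E11.5/E12.5,
four observers (three experienced, one novice), two digitizing trials —
with specimen-level shape variation, per-observer bias, trial noise, and a
linear allometric growth trend whose every component is recorded as ground
truth.

## The statistics

With landmark configurations `X` (k × 3, mm):

- **Centroid size** `CS = sqrt(Σᵢ ||xᵢ − x̄||²)` — the standard
  geometric-morphometrics size measure and the proxy for developmental age.
- **Intraobserver error**: Euclidean distance between an observer's two
  trial placements of a landmark; bilateral sides pooled under the pair
  label.
- **Interobserver error**: centroid size of the observers' mean placements
  of one landmark on one specimen (sides kept separate).
- **Placement ANOVA** (per age): the additive model
  `distance ~ specimen + landmark + observer` on the deviation of each
  observer's trial-mean placement from the specimen mean, with sequential
  sums of squares (order-invariant under the balanced design).
- **Generalized Procrustes analysis**: iterative centering, scaling to unit
  CS, and proper rotation (no reflections — embryo heads are chiral) onto a
  converging consensus.
- **Allometric regression**: least squares of each Procrustes coordinate on
  CS; percent variance explained `100 · SS_pred / SS_total`; per-specimen
  regression scores `(x − x̄)·β̂ / ||β̂||`; per-landmark ontogenetic vectors
  `mean + β̂ · ΔCS`.
- **Subset experiment**: the regression repeated after removing the trouble
  column or an anatomical subset, with per-landmark vector angles against
  the all-landmark fit measured after projecting both slope fields into the
  subset's shape space (a subset's superimposition absorbs any component of
  the trajectory that acts as a similarity transform of that subset).

## Worked example

```r
library(craniomorph)

params <- default_study_design(seed = 1)   # 10/9/10 x 4 observers x 2 trials
sim    <- simulate_dataset(params)
sim$dataset
#> Trial dataset: 29 specimens ( 10/9/10 at E10.5/E11.5/E12.5 ), 4 observers x 2 trials, 36 landmarks

intra <- intraobserver_error(sim$dataset)
round(tapply(intra$distance, intra$observer, median), 4)
#>   obs1   obs2   obs3   obs4
#> 0.0535 0.0557 0.0561 0.1661
```

The three experienced observers' median trial-to-trial error sits near
0.05 mm, well under the 0.1 mm working reference; the novice (`obs4`) is
well above it — the pattern that motivates restricting pooled analyses to
experienced landmarkers.

```r
an <- placement_anova(deviation_from_mean(sim$dataset))
subset(an, age == "E10.5")
#>     age     term   df  sum_sq f_value    p_value
#>   E10.5 Specimen    9 0.01599  0.6792  7.284e-01
#>   E10.5 Landmark   35 5.26911 57.5477 6.571e-242
#>   E10.5 Observer    3 0.15225 19.3997  2.525e-12
#>   E10.5 Residual 1392 3.64150      NA         NA
```

The balanced design fixes the degrees of freedom (9/35/3 with residual
1392 at E10.5; 8/35/3 with 1249 at E11.5). Landmark and observer identity
are strongly associated with placement deviation — some landmarks are
intrinsically harder, and observers differ in how far they sit from the
consensus.

```r
sc <- subset_experiment(sim$dataset, observers = c("obs1", "obs2", "obs3"))
sc
#> Subset-removal allometry experiment
#>   all               75.6% variance explained; max vector angle   0.0 deg (baseline)
#>   minus_trouble     75.9% variance explained; max vector angle   0.8 deg (baseline)
#>   minus_nasal       77.4% variance explained; max vector angle   0.6 deg (baseline)
#>   minus_maxmand     75.3% variance explained; max vector angle   0.5 deg (baseline)
#>   minus_nonfacial   50.3% variance explained; max vector angle   7.8 deg (gpa-aligned)
```

Centroid size explains about three quarters of shape variation, and the
direction of the allometric trajectory is essentially unchanged (vector
angles of a few degrees) whichever landmark group is dropped. Removing the
non-facial landmarks costs the most explanatory power: those points track
overall head growth and make CS a better developmental clock.

Trouble-landmark flagging (`flag_trouble`) combines both error channels:
median intraobserver distance above 0.1 mm for any experienced observer at
any age, or median interobserver CS above the 90th percentile. The
five-landmark removal recommendation is available as
`suggested_removals()`.

## Layout

- `R/` — landmark scheme and I/O (TPS/CSV), synthetic data generator,
  error analysis, Procrustes machinery, allometry, pipeline orchestration.
- `tests/testthat/` — unit, property, and acceptance tests with
  independent oracles (brute-force rotation search, normal-equations ANOVA,
  closed-form error laws).
- `vignettes/craniomorph-methods.Rmd` — the methods notes: model
  assumptions, parameter choices, numerical details, and limitations.
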