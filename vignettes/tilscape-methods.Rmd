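---
title: "Tumor-TIL maps: models, scoring rules, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-TIL maps: models, scoring rules, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilscape)
```

## The analysis in one paragraph

Two convolutional classifiers tile a breast-cancer H&E whole-slide image
into patches and emit per-patch probabilities: a tumor model on
87.5 µm patches (350 px at 40×) and a lymphocyte model on 50 µm patches
(200 px at 40×), the latter predicting whether a patch holds two or more
lymphocytes. tilscape consumes those probability grids and does
everything downstream: binarize at ≥ 50%, align the two pitches on a
common lattice, overlay them into a Tumor-TIL map, compute percent TIL
infiltration, grade five spatial features of the infiltrate with
connected-component rules, reduce the grades to binary high-risk
indicators (high-risk group at two or more), and relate infiltration and
risk group to progression-free interval (PFI) with Kaplan–Meier,
log-rank, and Cox proportional-hazards analyses. Every stage can be
exercised on synthetic slides with planted phenotypes, so the pipeline is
testable without clinical images.

## Lattice alignment

The two models tile at incommensurate pitches, and no published recipe
exists for their co-registration, so alignment is this package's own
design. We replicate each source patch onto the lattice whose pitch is
the greatest common divisor of the two patch sizes — 12.5 µm for
87.5/50, giving 7×7 and 4×4 fine cells per source patch. Replication is
nearest-source assignment with both origins pinned to the top-left
corner: exact and deterministic, with no interpolation of boolean flags.
Patch (i, j) covers the half-open square [j·s, (j+1)·s) × [i·s, (i+1)·s)
µm, row-major; when model tiling truncates the slide edge differently per
pitch, grids are cropped to the overlapping extent, and extents differing
by more than one coarse patch are rejected as misaligned rather than
silently cropped.

Percent infiltration is computed on the fine lattice, as co-positive
cells over tumor cells; for uniform cells the ratio is scale-free, so
this equals the patch-level ratio up to edge replication effects. A slide
with no tumor-positive cells has *undefined* infiltration and is flagged
(classed condition), never silently scored 0.

## Spatial feature rules

Five features are scored from the composite map. The two binary features
have published area anchors; everything else in the rules is a documented
design parameter in `morphologyConfig()`:

| parameter | default | role |
|---|---|---|
| `connectivity` | 4 | component adjacency (conservative confluence) |
| `desertAreaFracThreshold` | 0.25 | deserts score 1 at ≥ 25% of tumor area |
| `desertMinComponentFrac` | 0.01 | smallest TIL-free component counted |
| `forestAreaFracThreshold` | 0.10 | forests score 1 at ≥ 10% of tumor area |
| `forestMinComponentFrac` | 0.02 | smallest confluent TIL group counted |
| `strengthCutoffs` | 0.05, 0.15 | fraction ladder for grades 1/2/3 |
| `bandWidthCells` | 2 (25 µm) | peritumoral band depth |
| `aggregateMinCells` | 5 | smallest distal cluster counted |
| `aggregateMultifocalMin` | 2 | clusters needed for "multifocal" |

Decisions worth spelling out:

* **The desert gap.** The published criteria leave 10–25% of tumor area
  unaddressed (score 0 is defined up to ≤ 10%, score 1 from ≥ 25%). A
  binary rule must be single-valued, so we score 1 iff the qualifying
  TIL-free area reaches 25% and 0 otherwise, treating the score-1
  criterion as operative.
* **"Significant regions" and "small groups".** Deserts sum the areas of
  TIL-free components of at least 1% of tumor area (speckle excluded,
  multifocal deserts honored); forests analogously with a 2% component
  floor, which makes the tolerated "1–2 small confluent groups"
  concrete. Both floors are configurable because the source criteria are
  qualitative.
* **Strength ladders.** Grades 1–3 are qualitative
  (weak/moderate/strong) in the source criteria; we realize them as
  infiltration-fraction ladders with cutoffs 5% and 15%. Grade 0 is
  anchored: exactly zero TIL-positive patches. Only the anchored
  endpoints and monotonicity are asserted in validation — the interior
  cutoffs are inventions.
* **The peritumoral band.** No published width exists for the
  invasive-boundary region. Default: tumor mask dilated by 2 fine cells
  (25 µm) under the chebyshev metric, minus the tumor; a
  lymphocyte-patch depth (≈ 50 µm, 4 cells) is a reasonable alternative
  preset. Component connectivity (default 4) and the dilation metric are
  deliberately separate knobs: confluence is judged conservatively while
  the band is isotropic.
* **Aggregates.** "Multifocal" is realized as ≥ 2 qualifying components
  of ≥ 5 cells lying entirely beyond tumor ∪ band. A single large distal
  cluster therefore scores 0.
* **Risk mapping.** Indicators: strength 0–1, deserts 1, forests 0,
  peritumoral 0–1, and (optional) aggregates 0. The default active set
  excludes aggregates, which were screened out for low interrater
  agreement (κ = 0.37) in the source study; `screenFeatures()`
  reproduces that screening on any panel at the κ ≥ 0.5 rule. Two or
  more active indicators give the high-risk group.

A known behavior of the component rules: sparse diffuse infiltration
leaves its TIL-free complement connected, so maps with, say, 15% scatter
can legitimately score deserts = 1 even though a human would not call
them desert-like. The complement only fragments once infiltration passes
roughly half the tumor. Consequently deserts and strength-3 *can*
co-occur (a focal cold disc in a hot tumor); no validity rule forbids
it.

## Consensus and agreement

Consensus is the per-feature median across raters; with an even rater
count we take the lower middle value so consensus stays in the ordinal
domain (the source study used three raters, where the case never
arises). Fleiss' κ is computed from the slide × category count matrix;
rows must be balanced, unscored slides are dropped rather than imputed,
and the degenerate all-one-category case reports κ = 1 with a flag. The
exclusion cutoff defaults to 0.5 ("below 0.5, unacceptable") and is
exposed because the published interpretation bands (0.4–0.6 moderate)
conflict with that rule; a feature exactly at the cutoff is retained.

## Survival layer

PFI uses day-resolution times with `event = 0` right-censoring. The Cox
fit defaults to Efron tie handling (day-resolution data tie often;
Breslow is available for oracle cross-checks), Wald confidence intervals
on the coefficient scale exponentiated, and listwise deletion of missing
covariates with a logged count. Categorical references are LumA (the
largest subtype stratum) and stage I. When percent infiltration enters a
model it is divided by its cohort standard deviation, so its hazard
ratio is per SD of infiltration — scaling to unit variance and scaling
by SD being the same operation. The TIL-sensitive subset rule is
ER-negative and/or PAM50 LumB/Her2; records missing both fields are
dropped with a logged count. Significance markers reproduce the source
legend verbatim (`*** < 0.001, ** < 0.05, * < 0.01`, in that printed
order) with a conventionally ordered alternative.

The TIL-class split supports both mean and median centers — the source
describes both in different places — defaulting to the mean (the methods
text); values tied with the center go to "Low".

## What the synthetic generator emulates

`phenotypeSpec()` describes a 2100 µm square slide (24×24 tumor patches,
42×42 lymphocyte patches, 168×168 common lattice) with a connected tumor
blob from a seeded union of discs (~35% of the slide), and one of seven
planted phenotypes: cold, diffuse, forest (confluent disc, 15% of tumor
area), desert (cold disc, 30%, in a diffusely infiltrated background),
peritumoral ring, distal aggregates, or mixed. Planted fractions sit
safely past the scoring thresholds on purpose: they are study
conditions, not tuning knobs. Probabilities are beta-distributed around
0.9/0.1 for planted positives/negatives with concentration `3 / jitter`;
at the default jitter = 0.1 a threshold flip is about a 10⁻⁹-per-cell
event, so binarization recovers the planted pattern essentially always,
and larger jitter degrades it smoothly.

Ground-truth feature scores are computed by scoring the *noiseless*
planted pattern: truth for the graded strengths is thereby defined
relative to the same configured ladder the scorer uses, which is the
only coherent choice when the source grades are qualitative. End-to-end
recovery therefore measures the pipeline's robustness to probability
noise and lattice resampling, not agreement with a human.

`cohortSpec()` plants proportional hazards: exponential event times at
`baselineRate · exp(lp)`, uniform censoring on a follow-up window, and
recognized coefficients for the high-risk group and SD-scaled
infiltration. Defaults (baseline 1/2500 per day, 2000-day window,
subtype/ER/stage probabilities matching a large breast-cancer cohort)
give ≈ 40% observed events at n = 400, the regime used for parameter
recovery.

What the generator does **not** emulate: H&E texture, classifier failure
modes (folds, pen marks, necrosis), spatially correlated probability
errors, multiple slides per patient, or inter-cohort composition shifts.
Passing tests demonstrate internal correctness of the rules and
statistics under the planted data-generating process — they say nothing
about classifier accuracy on real tissue.

## Validation design and problem sizes

The package validates against independent brute-force oracles rather
than against itself: flood-fill components (vs the igraph route), the
direct Fleiss formula (to 1e-12 on 100 random matrices), a 1-D partial
likelihood grid search (Cox coefficient to ~1e-4 on an 8-record toy),
exhaustive pair enumeration (concordance), hand product-limit tables
(Kaplan–Meier), and per-cell distance transforms (peritumoral band).
Threshold flip-points are located by exhaustive 1-cell sweeps on 20×20
all-tumor grids. Statistical properties run at deliberate desk scale:
1000 random 40×40 grids for component equivalence, 100 cohort replicates
of n = 400 at ≈ 40% events for hazard-ratio recovery, 1000 two-group
null replicates of n = 100 for log-rank calibration, 200 seeds per
phenotype for end-to-end recovery, and a 300-slide mixed cohort
(diffuse fraction swept over 0.02–0.75 so infiltration spans the
weak-to-strong range) for the strength/desert correlation properties.

## Known limitations

* The desert rule's behavior on sparse scatter (above) means desert
  calls at low infiltration are rule-truthful but perceptually
  aggressive; tightening `desertMinComponentFrac` trades this against
  multifocal-desert sensitivity.
* The GCD lattice is exact only for patch-size pairs with a rational
  ratio; pathological pitches are rejected rather than approximated.
* Strength interior cutoffs, band width, and aggregate minima are
  inventions with no published anchor; conclusions that depend on them
  should be swept.
* The survival layer models PFI only, with exponential synthetic times;
  a Weibull stress test of proportional-hazards robustness is left to
  the user via custom cohort generation.
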