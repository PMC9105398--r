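# tilscape

Spatial mapping and prognostic scoring of tumor-infiltrating lymphocytes
(TILs) from patch-classifier heatmaps of breast-cancer whole-slide
images.

## The problem

Patch-level deep-learning models turn an H&E whole-slide image into two
probability grids: a tumor model on 87.5 µm patches and a lymphocyte
model on 50 µm patches. Overlaying the two yields a **Tumor-TIL map** —
each location is background, tumor, lymphocyte, or both — from which two
kinds of prognostic readout follow:

* **Percent TIL infiltration**, the fraction of tumor-positive patches
  that are also lymphocyte-positive:

  `infiltration % = 100 · |tumor ∧ lymphocyte| / |tumor|`

* **Spatial ecology features** of the infiltrate: intratumoral strength
  (0–3), immune-cold **deserts** (1 when confluent TIL-free regions
  reach ≥ 25 % of tumor area), confluent **forests** (1 when a confluent
  TIL group spans ≥ 10 % of tumor area), peritumoral strength at the
  invasive boundary (0–3), and tertiary lymphoid **aggregates** beyond
  the peritumoral band (1 when multifocal). Features map to binary
  high-risk indicators (low strengths 0–1, deserts present, forests
  absent, aggregates absent); patients with **two or more** high-risk
  features form the high-risk group.

tilscape implements the full downstream pipeline for people who already
have (or simulate) the model heatmaps: ingestion and binarization at
≥ 50 %, alignment of the two pitches on their common 12.5 µm lattice,
map composition and rendering, algorithmic feature scoring, multi-rater
median consensus with Fleiss' κ screening, and the
progression-free-interval (PFI) survival layer — Kaplan–Meier curves,
log-rank tests, and Cox proportional-hazards fits with SD-scaled
infiltration and concordance. A synthetic-data module plants spatial
phenotypes and cohort hazards so every stage is testable without
clinical images. CNN training/inference and whole-slide image decoding
are out of scope.

## Worked example

Plant a desert phenotype, run the pipeline, and stratify a synthetic
cohort:

```r
library(tilscape)

out  <- plantPhenotype(phenotypeSpec("desert", seed = 42))
pair <- resampleToCommonLattice(binarize(out$tumor), binarize(out$lymph))
map  <- composeMap(pair)
map
#> CompositeMap 'synthetic-42': 168 x 168 cells @ 12.5 um
#>   tumor 8190 | lymph 86 | co-positive 1610 | background 18338

percentInfiltration(map)
#> InfiltrationSummary 'synthetic-42': 1610 / 9800 tumor cells co-positive = 16.43%

sc <- scoreAll(map)
sc
#> FeatureScores: intratumoral 3 | deserts 1 | forests 0 | peritumoral 2 | aggregates 0
highRiskProfile(sc)
#> HighRiskProfile: high-risk (2 indicators: deserts_present, forests_absent)
```

The planted cold disc (30 % of tumor area) fires the desert indicator,
and the diffuse background infiltration — 16.4 % of tumor cells, hence
strength 3 — forms no confluent forest, so two indicators fire and the
slide lands in the high-risk group.

A cohort with a planted hazard ratio of 2 for the high-risk group is
recovered by the survival layer:

```r
d <- simulateCohort(cohortSpec(n = 400, seed = 42))
coxFit(d, "risk_group")
#> CoxFit: n = 400, events = 151, concordance = 0.583
#>                 term      coef                   hr      p_value
#>  risk_grouphigh-risk 0.7665816 2.152 [1.557, 2.976] 3.509284e-06

lr <- logrankTest(d, d$risk_group)
#> log-rank chi-square 22.5, p = 2.1e-06
```

The hazard ratio of 2.15 (95 % CI 1.56–2.98) brackets the planted value
of 2; the concordance of 0.58 is what a single binary covariate of this
effect size can explain.

A thin command-line wrapper covers the batch workflow
(`exec/tilscape`): `simulate`, `ingest`, `compose` (with `--render` for
the four-panel composite PNG), `score`, and `consensus`; survival
modeling is a two-line R call (`stratifyRisk` + `coxFit`) and is left to
the R interface.

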