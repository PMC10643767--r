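# primateClocks

Multi-species DNA methylation age clocks, EWAS-of-age meta-analysis and
methylation-based sex prediction for primate cohorts.

## The problem

DNA methylation at a modest number of CpG sites tracks chronological age so
tightly that a penalized linear model on methylation fractions — an
*epigenetic clock* — predicts age with correlations above 0.9 in many
species. Building one clock that works **across** primate species, from
small-bodied strepsirrhines (maximum lifespan ~10 years) to humans (122.5
years), raises methodological questions that this package implements as a
tested, reusable pipeline:

- **Age transformations.** Absolute age is a poor regression target across
  species whose lifespans differ tenfold. The package provides the four
  standard outcomes with exact inverses: identity, `sqrt(Age + 1)` (the
  1-year offset keeps prenatal samples, coded with negative ages, in
  domain), the piecewise log-linear transform anchored at the species' age
  at sexual maturity, and *relative age* = Age / maximum lifespan.
- **The clock itself.** Elastic-net regression (mixing parameter
  alpha = 0.5, halfway between ridge and lasso) of the transformed age on
  beta values, with the penalty chosen by internal tenfold cross-validation.
- **Honest accuracy estimates.** Leave-one-out CV and tenfold CV balanced by
  species (every fold holds the same proportion of each species), with the
  penalty re-selected inside each training fold. Accuracy is the Pearson
  correlation R between DNAm age and chronological age plus the median
  absolute error in years; *epigenetic age acceleration* is the residual of
  DNAm age regressed on age (or the raw difference), with cross-tissue
  acceleration correlations joined on shared animals.
- **EWAS of age.** Per-stratum correlation screening (signed Z,
  `Z = sign(r) * qnorm(1 - p/2)`, standard normal under the null; positive =
  gain of methylation with age), then a two-stage unweighted Stouffer
  meta-analysis (`Z_meta = sum(z)/sqrt(k)`): tissues within species, then
  across species, with strata under 10 samples excluded and small species
  poolable into one pseudo-species.
- **Sex effects.** Per-stratum OLS of methylation on age + sex, SMP counts
  (5% FDR) split by chromosome class and direction, consensus calling
  across models, a pooled EWAS of sex, and a binomial elastic-net sex
  predictor with cross-validated accuracy.
- **Gene-region enrichment.** Fisher exact tests of top CpG sets (up to 500
  per direction at p < 1e-4) against the array background, per region class
  (promoter, UTRs, exon, intron, intergenic), with a strand-aware region
  classifier for BED-like gene models.

Because consortium methylation data are not freely redistributable, the
package ships a **synthetic cohort generator** that emulates the relevant
statistical structure — multiple species with distinct lifespans and
species-divergent baselines, multiple tissues from the same animals, shared
and tissue-specific age CpGs in both directions, X-linked and autosomal sex
effects, fetal samples, per-species mappability masks, and an optional
chimeric species whose sex signal is erased — so every downstream stage is
testable end to end.

## Worked example

```r
library(primateClocks)

cfg    <- cohortConfig(seed = 17L)            # 5 species, 3 tissues, 2000 CpGs
cohort <- simulateCohort(cfg, nPerStratum = 20)
cohort
#> MethylationCohort: 2000 CpGs x 300 samples
#>   species: galago, vervet, baboon, macaque, human
#>   tissues: blood, liver, cortex
#>   age range: -0.44 to 119.06 years (9 fetal)
#>   planted truth: 155 causal CpGs recorded

tr <- ageTransform("sqrt_offset", cohort = cohort)
cv <- runCV(cohort, tr, scheme = "LOFO10", seed = 17L)
subset(cv$metrics, grouping != "tissue")
#>   grouping   level   n pearson_R   MAE
#> 1  overall     all 300     0.983 1.529
#> 2  species  galago  60     0.957 0.957
#> 3  species  vervet  60     0.972 1.029
#> 4  species  baboon  60     0.982 1.488
#> 5  species macaque  60     0.974 1.359
#> 6  species   human  60     0.981 4.356
```

Every sample is predicted once by a clock never trained on it; the overall
R of 0.98 and per-species R ≥ 0.96 show the planted age signal (logit slope
3 per unit relative age, logit noise 0.3) is recovered across lifespans
spanning 10–122.5 years. The MAE grows with lifespan, as expected for an
error measured in years.

A per-stratum EWAS of age ranks CpGs by correlation with age:

```r
ew <- correlationEwas(cohort, "baboon", "cortex")
head(ew[order(ew$p), c("cpg_id", "n", "r", "Z", "p", "q")], 3)
#>     cpg_id  n         r        Z            p            q
#> 40 cg00040 20 0.9805086 7.574918 3.593550e-14 6.867273e-11
#> 17 cg00017 20 0.9741953 7.243019 4.388042e-13 2.433542e-10
#> 29 cg00029 20 0.9741264 7.239801 4.493441e-13 2.433542e-10
```

All three top hits are planted age CpGs (`cohortTruth(cohort)`). Strata can
then be combined with `twoStageMeta()`, top lists extracted with
`selectTopCpgs()` and compared with `overlapTopLists()`, and enriched by
gene region with `regionEnrichment()`. Sex analysis runs through
`sexEwas()`, `countSmps()`, `consensusSmps()`, `pooledSexEwas()`,
`fitSexPredictor()`/`predictSex()` and `sexPredictorCV()`. Cohorts and
fitted models round-trip through `writeCohort()`/`readCohort()` and
`writeClock()`/`readClock()`.

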