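---
title: "Methods: multi-species methylation clocks, EWAS meta-analysis and sex prediction"
author: "primateClocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-species methylation clocks, EWAS meta-analysis and sex prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical methods: the
models it fits, the assumptions behind them, what the synthetic cohort
generator does and does not emulate, and the numerical choices that a
maintainer would otherwise have to reverse-engineer from the code.

## 1. The data model

A `MethylationCohort` is a `SummarizedExperiment` whose single assay holds
methylation fractions (beta values) in [0, 1], CpGs as rows and samples as
columns. Three pieces of metadata ride along and are used throughout:

- the **sample sheet** (`colData`): sample, animal and species identifiers,
  tissue, chronological age in years (negative for prenatal samples) and
  sex (`F`, `M` or `unknown`);
- the **CpG annotation** (`rowData`): chromosome (including `chrX`),
  position, nearest gene, region class and one logical
  `mappable_<species>` column per species — a CpG unmappable in a species
  is `NA` in all that species' samples;
- the **species table** (`metadata`): maximum lifespan, average age at
  sexual maturity and gestation length per species, which parameterize the
  age transforms and the simulator.

Several animals contribute one sample per tissue; this animal-matched
design is what makes cross-tissue acceleration correlations estimable.

## 2. Age transformations

Clock regression uses a transformed outcome; each transform has an exact
inverse so predictions are always reportable in years:

| kind | forward | inverse | domain |
|---|---|---|---|
| `identity` | $a$ | $y$ | all |
| `sqrt_offset` | $\sqrt{a + c}$ | $y^2 - c$ | $a \ge -c$, $y \ge 0$ |
| `loglinear` | $\log(a+1) - \log(m+1)$ if $a \le m$, else $(a-m)/(m+1)$ | piecewise | $a > -1$ |
| `relative` | $a / L$ | $yL$ | $L > 0$ |

with $c$ the offset (1 year by default, so fetal ages down to one gestation
below zero remain in domain), $m$ the species' maturity age and $L$ its
maximum lifespan. The log-linear form is the classic pan-tissue-clock
transform: logarithmic growth of the outcome during development, linear
after maturity, continuous with matching one-sided slopes $1/(m+1)$ at
$a = m$. It is parameterized per species; a single shared maturity constant
is available as a degenerate one-entry map. Relative-age predictions are
**not** clamped to [0, 1]; raw values are reported so users can see
out-of-range behaviour rather than having it masked.

Monotonicity and the exact round-trip (to 1e-9 absolute) are enforced by
property tests over random ages.

## 3. Clock fitting and prediction

`fitClock()` regresses the transformed age on beta values with an
elastic-net penalty, alpha = 0.5 (the midpoint between ridge and lasso,
deliberately not tuned), and the penalty strength chosen as the
mean-squared-error minimizer of an internal tenfold cross-validation
(`cv.glmnet`'s `lambda.min`). The maximizing-accuracy choice of
`lambda.min` over the more conservative `lambda.1se` is intentional:
multi-species clocks are judged by raw predictive correlation.

Numerical policy:

- **Missingness.** Betas missing through mappability are mean-imputed per
  CpG; the training means are stored inside the model and reused verbatim
  at prediction time (including for model CpGs entirely absent from a new
  cohort, which additionally triggers a warning). Imputation by a constant
  is deliberately simple: anything fancier would leak information across
  species in ways that are hard to audit.
- **Degenerate columns.** All-`NA` columns are dropped silently; constant
  columns are dropped with a warning that counts them.
- **Reproducibility.** The internal fold assignment is seeded explicitly;
  fitting twice with the same seed is bit-identical, and predicting on the
  training set reproduces the stored fitted values to 1e-8.
- **Inverse-domain truncation.** A sqrt-scale score below zero (possible
  for extrapolated fetal predictions) is truncated at zero before
  inversion, so the smallest reportable DNAm age is minus the offset.

Models serialize to a coefficient CSV with a commented header (transform
tag and parameters, alpha, penalty) and 17-significant-digit numbers, which
makes save/load/save byte-identical; an unknown transform tag or malformed
row is a parse error naming the line.

## 4. Cross-validation and acceleration

`makeFolds()` implements LOOCV and LOFO10. LOFO10's species balance is
realized constructively: within each species, samples are shuffled
(seeded) and dealt round-robin over a shuffled fold ordering, which makes
the per-species fold counts differ by at most one — the balance property
itself, not a rejection-sampling approximation. `runCV()` re-runs the
entire fitting procedure (including penalty selection) inside each training
fold, so no hyperparameter information leaks from held-out samples, and
every sample is predicted exactly once by a model that never saw it.

Accuracy is summarized as Pearson R between DNAm age and age plus the
median absolute error in years, overall and per species/tissue. Both
acceleration definitions are computed: `delta` (DNAmAge − Age) and
`residual` (residual of DNAmAge regressed on Age). Residual is the default:
it is invariant to calibration offsets and has zero mean and zero age
correlation by construction (asserted to 1e-8). Cross-tissue acceleration
correlations are Pearson correlations of animal-matched accelerations;
tissue pairs sharing fewer than 3 animals are `NA`.

## 5. EWAS of age and the two-stage meta-analysis

Per stratum (species x tissue), each CpG is screened by pairwise-complete
Pearson correlation with age: $t = r\sqrt{n-2}/\sqrt{1-r^2}$, a two-sided
p from the t distribution with $n-2$ df, and the signed normal score
$Z = \mathrm{sign}(r)\,\Phi^{-1}(1-p/2)$, standard normal under the null;
positive Z means gain of methylation with age. Benjamini–Hochberg q-values
are computed within the stratum over its tested CpGs only — per-species
mappability makes cross-stratum pooling ill-defined.

Degenerate inputs have explicit conventions: a zero-variance CpG is
emitted with p = 1, Z = 0 and flag `zero_variance`; when p underflows
(|r| at or near 1), the reported p is floored at 1e-320, Z is capped at
$\Phi^{-1}(1 - 10^{-320}/2) \approx 38.4$ and the row flagged `saturated`.

`twoStageMeta()` combines strata by the unweighted Stouffer method
($Z_{meta} = \sum z_i/\sqrt{k}$), tissues within species first, species
second. A single-stratum combination is the identity, so species observed
in one tissue pass through stage 1 unchanged. Strata with fewer than 10
samples are excluded; species too small to analyze individually can be
pooled into one pseudo-species — the recommended route is pooling at the
sample level (`correlationEwas()` accepts a species vector), with the
`pooledSpecies` argument available for table-level relabeling. Top lists
take CpGs of one Z sign with p below 1e-4, sorted by p with a
deterministic tie-break (larger |Z|, then lexicographic CpG id), truncated
at 500 per direction; list overlaps are scored against the hypergeometric
null.

## 6. Sex analysis

`sexEwas()` fits, per stratum (species x tissue x age category, default
split at 1 year to separate neonates), the OLS model
`beta ~ age + female`, and reports the female-minus-male coefficient in
beta units (female coded 1, so higher methylation in females is positive),
with BH q per model. The age covariate is dropped in constant-age strata;
strata lacking 3 samples of either sex are skipped with a warning. The
vectorized solver groups CpGs by missingness pattern — valid because
mappability-driven missingness is species-block, so within a stratum the
patterns are few. SMP counts split by chromosome class (autosome/X/Y) and
direction; consensus SMPs are those significant in at least a chosen
number of models. The pooled EWAS of sex uses the same regression on all
samples; its significance threshold is configurable because desk-scale
cohorts cannot reach the extreme thresholds meaningful at consortium scale
(the package default is 1e-8).

The sex predictor is a binomial elastic net on the female indicator
(alpha = 0.5, lambda.min), fit on the full CpG set by default — with real
X-inactivation-like signal, the selected CpGs concentrate on the X
chromosome by selection rather than masking, and an `xOnly` mask is
available. Prediction is the logistic probability of female with label
threshold 0.5; a probability of exactly 0.5 is labelled `unknown`.
`sexPredictorCV()` estimates accuracy by tenfold CV stratified by species
and sex.

## 7. Gene-region enrichment

`regionEnrichment()` builds, per region class, the 2x2 table of top-set
membership against class membership over the background (all analyzed
array CpGs) and reports the sample cross-product odds ratio with a
two-sided Fisher exact p. The cross-product OR (not the conditional MLE
that `fisher.test` estimates) was chosen because it matches the
"count versus background" convention of enrichment bar plots and is exactly
testable; tables with a zero cell get a flagged Haldane–Anscombe 0.5
correction for the OR only, never for the p-value.

`annotateRegionClass()` classifies positions against BED-like gene models
(0-based half-open) with fixed precedence promoter > 5'UTR > exon > 3'UTR
> intron > intergenic. The promoter window is strand-aware, 5 kb upstream
to 1 kb downstream of the TSS by default (the TSS of a minus-strand gene
is its interval end); the window is configurable since annotation
conventions differ. CpGs on contigs absent from the gene models are
intergenic with a flag.

## 8. The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the analyses assume,
on the logit scale of beta values:

$$\mathrm{logit}(\mu_{js}) = b_j + d_{j,\mathrm{sp}(s)} +
  \beta \cdot \delta_j \cdot \frac{a_s + u_{\mathrm{an}(s)}}{L_{\mathrm{sp}(s)}},
\qquad
\mathrm{beta}_{js} = \mathrm{logit}^{-1}(\mathrm{logit}(\mu_{js}) + \varepsilon_{js})$$

with per-CpG baselines $b_j$, per-(CpG, species) divergence
$d_{js} \sim N(0, \sigma_{div}^2)$, planted direction $\delta_j \in \{\pm 1\}$,
logit effect $\beta$ per unit relative age, an optional per-animal
"fast-ager" offset $u$ (years), and Gaussian logit noise. Sex CpGs receive
a beta-scale offset $\pm\Delta\beta$ in females, erased for a designated
chimeric species (emulating chimeric blood, where methylation cannot
predict sex). Betas are clamped to [0.001, 0.999]; mappability dropout is
missing-at-random per (CpG, species). The generator is fully determined by
its seed.

Default study conditions (fixed once, used by the recovery tests and the
acceptance script): five species with lifespans 10, 30.8, 37.5, 40 and
122.5 years; three tissues from the same animals; 2000 CpGs of which 100
shared age CpGs (half gain, half loss; logit slope 3), 20 tissue-specific
age CpGs per tissue, 50 X-linked and 5 autosomal sex CpGs
($\Delta\beta = 0.3$); logit noise sd 0.3; 5% fetal samples; 5%
mappability dropout; baseline divergence sd 0.5.

**Why species-divergent baselines are part of the model.** The planted age
signal lives on the relative-age scale, but an absolute-age clock must
predict $\sqrt{aL+1}$-scale outcomes across species whose lifespans span
an order of magnitude. A variance decomposition shows that with identical
baselines across species the best species-blind predictor caps the pooled
years-scale correlation near 0.66 — species identity is simply not in the
data. Real methylomes are strongly species-divergent at baseline, and
adding that divergence (a realistic feature, not a convenience) lets the
elastic net encode species offsets through divergent CpGs; the squared
inverse transform then supplies the species-by-age interaction, and pooled
recovery reaches R ≈ 0.99. Two corollaries worth knowing: (i) on a
multi-species *null* cohort, a clock can still "predict age" by predicting
each species' mean age from its baseline signature, so null-signal checks
use single-species cohorts; (ii) the logit-linear generative model is an
artifact choice flagged in the truth record — the source literature gives
no distributional description of methylation trajectories.

**What passing tests do not show.** The generator has no batch effects,
no probe chemistry or normalization artifacts, no heteroskedasticity
beyond the logit-bounded kind, no correlated CpG blocks (co-methylation),
no age-varying effect sizes, and its species divergence is unstructured
rather than phylogenetic. Recovery results on simulated cohorts therefore
demonstrate the correctness of the machinery, not expected accuracy on
real arrays.

## 9. Problem sizes and tolerances used by the test suite

The suite exercises the pipeline at sizes chosen to make sampling bands
tight while keeping a full run in minutes on one core: recovery cohorts of
300 samples x 2000 CpGs; null calibration at 2000 CpGs x 100 samples with
100 replicates for the FDR check (the 3-sigma binomial band on the
p < 0.05 fraction is [0.035, 0.065]); sex prediction at n = 200 with 40
samples per species; oracle-equivalence checks at 1000 random CpGs
(p and Z to 1e-10 against `cor.test`), Fisher p against exhaustive
hypergeometric enumeration to 1e-12, and Stouffer trees against an
explicit traversal to 1e-12. The chimeric-species control asserts accuracy
in [0.4, 0.6] on 40 samples — a deliberately wide band, since a fair coin
on 40 draws has a standard error of 0.08.

## 10. Known limitations

- Ordinary (unweighted) pooling is used when combining species in dual- or
  multi-species clocks; no sample reweighting is exposed.
- The EWAS screen is plain Pearson correlation; no robust correlation,
  mixed models or genomic-control inflation correction.
- The region classifier expects simple single-transcript gene models; it
  does not merge isoforms.
- Acceleration correlations are Pearson on possibly few shared animals;
  no shrinkage for small overlaps.
- The generator's mappability is missing-at-random; real probe dropout is
  phylogenetically structured.
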