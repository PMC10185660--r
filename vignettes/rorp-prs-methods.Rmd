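---
title: "Methods: a polygenic score for a tumor expression phenotype and its survival validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a polygenic score for a tumor expression phenotype and its survival validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rorpPRS)
```

## The problem this package addresses

Polygenic risk scores (PRSs) for overall breast cancer risk preferentially
predict indolent, ER-positive disease; among cases, a higher overall-risk
PRS is associated with *better* survival. rorpPRS implements the converse
strategy: fit a case-only PRS to a continuous tumor-aggressiveness
phenotype — the risk-of-recurrence score weighted on proliferation (ROR-P),
derived from the PAM50 expression signature — and validate the resulting
score against breast cancer-specific survival. The package provides every
stage as a tested function: ROR-P scoring from expression data, PRS
construction from candidate susceptibility SNPs, comparator
likelihood-ratio scores from case-case summary statistics, and survival
validation with meta-analysis and calibration diagnostics. A seeded
synthetic-cohort generator with recorded ground truth makes the whole
chain testable with known answers.

## ROR-P scoring

ROR-P for a sample is a fixed linear combination of its Spearman rank
correlations with the five intrinsic-subtype centroids (Basal, Her2, LumA,
LumB, Normal) and of a proliferation index:

$$\mathrm{RORP} = -0.001\,\mathrm{Basal} + 0.7\,\mathrm{Her2}
  - 0.95\,\mathrm{LumA} + 0.49\,\mathrm{LumB} + 0.34\,\mathrm{Prolif}$$

where Prolif is the mean normalized expression of an 11-gene proliferation
subset of the 50-gene panel. The Normal-like correlation participates in
the subtype call (argmax of the five correlations, ties broken in the
fixed label order Basal, Her2, LumA, LumB, Normal) but carries no weight
in the score.

Three preprocessing rules matter:

* **Probe collapse.** Genes measured by several probes are collapsed to
  the arithmetic mean across probes (`collapseProbes()`).
* **ER-balanced normalization.** Nearest-centroid subtype calling assumes
  the target series resembles the ER mix of the original training series.
  `erBalancedNormalize()` therefore subsamples all ER-negative cases plus
  an equal number of randomly chosen ER-positive cases, records per-gene
  medians, repeats this 1000 times (configurable), and subtracts the
  per-gene median-of-medians from every sample. When a series has fewer
  ER-positive than ER-negative cases the subsample is drawn with
  replacement, with a warning.
* **Scale.** The raw linear combination on correlations lives roughly in
  [-1.3, 1.6]; clinical reports use a 0–100 scale. The raw value is the
  canonical output here; `rorpModel(rescale = c(slope, intercept))`
  applies an optional affine rescale, and Low/Medium/High cutoffs are
  configuration, not defaults, because no canonical cutpoints exist on the
  raw scale.

## PRS construction

The development input is a case series with genotypes, ROR-P values, ten
genetic-ancestry principal components and a study indicator.

1. **Candidate panel.** Known susceptibility SNPs with published
   association p-values. `ldPrune()` removes linkage disequilibrium:
   candidates are visited by ascending published p-value (ties by SNP id)
   and kept only if their $r^2$ with every retained SNP is below 0.2, so
   within a correlated pair the SNP with the lower published p-value
   survives.
2. **Missing genotypes.** SNPs with more than 5% missingness are excluded;
   remaining missing entries are drawn from the Hardy-Weinberg genotype
   distribution $(q^2, 2pq, p^2)$ at the SNP's observed effect-allele
   frequency (`fillMissingGenotypes()`).
3. **Residualization.** ROR-P is regressed on PC1–PC10 plus study dummies
   (`residualizeRORP()`); all SNP association scans operate on the
   residual, which removes ancestry and between-study location effects.
4. **Scan and threshold selection.** Each SNP is tested by simple linear
   regression of the residual on dosage (`snpScan()`). The inclusion
   threshold is chosen by repeated k-fold cross-validation
   (`cvThresholdSelection()`): within every training fold the
   residualization, the scan and the per-SNP weights are all refit, the
   held-out fold is scored, and the fold $r^2$ is the squared Pearson
   correlation between held-out PRS and held-out residuals. The default
   grid runs from 0.1 to 0.6 in steps of 0.025, five folds, ten repeats;
   the selected threshold is the argmax of mean CV $r^2$, ties resolved
   toward the smaller threshold.

   Two design points were genuinely open. The CV metric could have been a
   regression $R^2$; the squared correlation is used because the PRS scale
   is arbitrary within each fold. And the per-fold refit of every stage
   (rather than reusing full-data weights) is the leakage-safe choice; a
   property test verifies that on null data the CV estimate sits below the
   in-sample $r^2$ of the same model.
5. **Final weights and scoring.** For each selected SNP the weight is the
   dosage coefficient of `rorp ~ dosage + PC1..PC10 + study` on the full
   development data (`fitFinalWeights()`); the PRS of a new sample is the
   weighted dosage sum $\sum_k \beta_k x_k$ (`scorePRS()`). SNPs missing
   from a target cohort are dropped without reweighting — coverage is
   reported instead — matching how partial panels are handled in
   practice. Scores are standardized to per-SD units among the analyzed
   cases (`standardizePRS()`).

## Comparator likelihood-ratio scores

A comparator PRS for the case-case risk of ER-negative versus ER-positive
disease is built from paired case-control summary statistics: because both
phenotypes share one control series, the per-SNP case-case log-odds is the
difference $\beta_{ER-} - \beta_{ER+}$ (`caseCaseBeta()`). Effect sizes
are converted to per-genotype likelihood ratios under a per-allele
multiplicative model with a Hardy-Weinberg genotype prior: with risk-allele
frequency $p$, $\mu = (p\,\mathrm{OR} + q)^2$ and
$\mathrm{LR}_g = \mathrm{OR}^g/\mu$, so the population-mean LR is exactly 1
(`buildLRWeights()`); the multiplicative PRS is the product of per-SNP LRs,
computed as an exponentiated log-sum (`scoreLRPRS()`). The source method is
cited in the literature without formulas; this population-calibrated
per-allele form is the standard construction and is documented here as an
interpretation. The same machinery scores an overall-risk PRS from any
published odds-ratio weight table; no weights are bundled.

## Survival validation

* **Cox models** (`coxFit()`) use the partial likelihood with Efron tie
  handling (the tie method is unstated in the source analyses; Efron is
  the better approximation) and report hazard ratios per SD with Wald
  intervals. The nested adjustment ladder (`nestedCoxModels()`) is:
  ancestry PCs; + age and BMI; + stage; + treatment flags; ancestry +
  measured ROR-P; ancestry + ER status. Joint models with two PRSs and
  ER-stratified fits use the same interface.
* **Kaplan-Meier tertiles** (`kmTertiles()`) split the analyzed cases into
  three rank-based groups differing by at most one sample and report the
  2-df log-rank statistic.
* **Meta-analysis** (`randomEffectsMeta()`) pools study-level log hazard
  ratios with a REML estimate of the between-study variance $\tau^2$,
  recovering standard errors from Wald intervals as
  $(\ln U - \ln L)/(2 \times 1.96)$. Heterogeneity is reported as
  Cochran's Q and $I^2 = \max(0, (Q - df)/Q) \cdot 100$, floored at zero.
  With one study the summary is that study.
* **Goodness of fit** (`gronnesbyBorgan()`): cases are grouped into ten
  equal strata of the fitted linear predictor and the statistic is the
  score test for adding the nine group indicators, evaluated at the fitted
  coefficients with the information matrix adjusted for their estimation
  (equivalently, a test that grouped martingale residuals vanish). The
  reference distribution is $\chi^2$ with (groups - 1) degrees of freedom;
  a 500-replicate simulation in the test suite confirms approximate
  uniformity of its p-values under a correctly specified model. Strata
  without events are merged with a warning.
* **Calibration** (`bootstrapCalibration()`): model-predicted survival at
  a 5-year horizon per risk stratum is compared with the Kaplan-Meier
  estimate, with an optimism correction: each of 200 bootstrap refits
  contributes the difference between its apparent calibration gap and its
  gap when applied to the original data, and the mean optimism is
  subtracted. The exact bias-correction variant used in the source
  analyses is not described; this apparent-minus-test scheme is the
  standard one and is flagged as an interpretation.
* **Feature associations** (`featureAssociation()`): logistic regression
  for binary tumor features (plus a companion t-test), multinomial
  logistic regression for grade and intrinsic-like subtype (plus ANOVA),
  all adjusted for ancestry PCs, with the PRS standardized to per-SD
  units.

## The synthetic cohort generator

`simulateCohort()` produces genotypes, tumor state, expression, and
outcomes with full ground truth. It emulates the statistical structure the
analysis assumes, not any particular dataset:

* **Genotypes** are i.i.d. Hardy-Weinberg draws at frequencies sampled
  uniformly from `mafRange` (default 0.05–0.5). Real LD blocks are not
  simulated; LD enters only through explicit pairwise tables consumed by
  the pruning step.
* **Tumor state.** A configurable subset of SNPs (default 10) drives a
  multinomial-logit over the five subtypes; a disjoint subset (default 10)
  adds to a proliferation value. The latent ROR-P applies the ROR-P
  coefficient pattern to true-subtype indicators plus 0.34 times
  proliferation, so the expression-based estimate is a noisy measurement
  of a well-defined latent quantity. The proliferation noise SD is
  calibrated on the realized cohort so that the variance fraction of
  latent ROR-P explained by its genetic expectation matches
  `geneticVarianceFraction` (default 0.17, the midpoint of published
  13–21% heritability estimates for ROR-P). The joint distribution
  linking SNPs, subtype and proliferation is not identified by any
  published analysis; this multinomial-logit plus additive-proliferation
  structure is one admissible choice and is flagged as such.
* **Population versus cohort randomness.** Allele frequencies, causal SNP
  identities and effect sizes derive from `architectureSeed`; sample-level
  draws derive from `seed`. Two configs sharing an architecture but
  differing in seed yield independent cohorts from the same population —
  exactly the development/validation situation a transferable PRS
  requires.
* **Receptor status and covariates.** ER, HER2 and grade are sampled
  conditionally on subtype (luminal subtypes mostly ER-positive, basal
  mostly ER-negative), with the ER conditionals shifted on the logit
  scale to meet the configured marginal ER-positive fraction (default
  0.75). Stage increases mildly in latent ROR-P and treatment flags
  depend on receptor status and stage, so the nested-model attenuation
  analyses have something to attenuate. Ancestry PCs are plain Gaussians
  with an optional confounding toggle (`pcRorpEffect`); real population
  structure is not simulated.
* **Expression** is the true subtype's centroid column plus Gaussian
  noise (SD 0.8 around centroids of roughly unit scale), proliferation
  genes shifted by the sample's proliferation value, optional per-study
  location shifts (SD 0.25, absorbed downstream by the study indicator),
  and optional probe multiplicity. Batch-correction artifacts are not
  simulated.
* **Outcomes** are exponential with hazard
  $\lambda_0 \exp(\ln(\mathrm{HR_{SD}})\, z)$ on the standardized latent
  ROR-P, censored administratively. Defaults — baseline hazard 0.02 per
  year and 10 years of follow-up, about 18% breast cancer-specific
  mortality — describe a case series enriched for higher-risk disease,
  chosen so that survival analyses of a score capped at explaining 17% of
  the latent phenotype's variance are adequately powered at the cohort
  sizes used below.

Because the generator is i.i.d. across SNPs and samples, passing tests
show that the *procedures* behave as designed under their own assumptions;
they do not show robustness to LD misspecification, cryptic relatedness,
batch effects, or non-proportional hazards, none of which are emulated.

## Numerical choices and problem sizes

All randomness flows from explicit seeds fanned out per stage, so every
generator, the 1000-rep normalization, CV folds, HWE fills and bootstraps
are bit-reproducible. Ties: subtype calls break in fixed label order; CV
threshold ties toward the smaller threshold; LD-prune ties on published p
toward the lexicographically smaller SNP id. Monomorphic SNPs are flagged
and excluded from scans and weights; constant expression vectors are
flagged and excluded from subtype calls. REML estimation is delegated to
`metafor`; $I^2$ is recomputed from Q by the formula above.

The packaged checks run on one CPU at these sizes: Hardy-Weinberg
goodness-of-fit at $10^5$ draws; heritability recovery at $10^4$ samples;
threshold-selection behavior at $n = 2000$ with 226 candidates (10
causal); Cox coverage at $n = 5000$ over 100 replicates per hazard ratio;
the full case-only chain (expression scoring through Cox validation) at
$n = 5000$ over 100 replicates with a 100-rep normalization and a
six-point threshold grid per replicate, against 100 matched null
replicates; goodness-of-fit calibration over 500 replicates at $n = 500$.
The end-to-end check builds and evaluates the PRS within one simulated
series, mirroring a case-only design in which development and follow-up
occur in the same population; cross-cohort transfer at matched
architecture is exercised separately by the pipeline and recovery tests.

## Known limitations

The generator's independence assumptions are listed above. The
likelihood-ratio parameterization is an interpretation of a method cited
without formulas. Penalized-regression PRSs, competing-risks models,
time-varying effects, imputation to reference panels, and multiple-testing
control across the association battery are out of scope.
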