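---
title: "Methods: the continuous MetS score and its candidate-SNP association workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the continuous MetS score and its candidate-SNP association workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metscore)
library(dplyr)
```

## The problem

Metabolic syndrome (MetS) is diagnosed dichotomously: at least three of five
features — abdominal obesity, low HDL cholesterol, high triglycerides,
elevated blood pressure, hyperglycemia — each defined by a hard cut-off, with
medication for a feature accepted as an alternative indicator. The yes/no
label throws away severity information and fragments genetic association
studies into heterogeneous subgroups. `metscore` implements the standard
alternative: a single continuous severity score built by principal component
analysis (PCA) over the six measured traits (waist circumference, diastolic
and systolic blood pressure, glucose, HDL, triglycerides), which is then the
quantitative outcome for candidate-SNP association testing under a dominance
model.

## Score construction

**Normalizing transforms.** Each trait is Shapiro–Wilk screened; traits
rejecting normality receive a designated transform before PCA:
`log10(log10(SBP))`, `1/log10(glucose)^10`, `ln(HDL)^2`, `log10(log10(TG))`,
with waist and DBP untransformed. The default pipeline mode (`"fixed"`)
applies exactly this assignment unconditionally, so the score definition does
not depend on which traits a particular sample happens to flag; `"screen"`
mode (screen decides, at a configurable `alpha`) is available for generality.
The doubled-log transforms need values above 1 (the inner log must be
positive) and the package enforces that as a per-record domain error. Note
the glucose transform is *decreasing*: higher raw glucose lowers the
transformed value, which is why its loading on the first component is
negative while higher glucose still raises the score.

**PCA.** Transformed traits are standardized to mean 0 / SD 1 and the
correlation matrix is eigendecomposed (correlation, not covariance, because
the traits have wildly different units). Components with eigenvalue strictly
above 1.0 are retained (Kaiser rule; the threshold is an argument). Retained
loadings are varimax-rotated with Kaiser row normalization — the convention
of mainstream statistical packages — and explained-variance proportions are
recomputed from the rotated loadings. On cohorts with the default generative
structure two components are retained: a blood-pressure/waist/glucose axis
and a lipid (TG/HDL) axis.

**Component scores and orientation.** Scores use the regression method on
standardized data. For PCA the unrotated scores `Z V Λ^{-1/2}` have exactly
unit sample variance and zero sample correlation; applying the same
orthogonal varimax rotation to the scores preserves both properties exactly,
so "summing component scores" is well defined. PCA signs are arbitrary, so a
convention is needed. We orient each component toward the *metabolically
adverse* direction — positive association with waist, blood pressure and TG,
negative with transformed glucose and HDL — so that a higher score is always
a less favorable profile and the score is monotone in every trait's adverse
direction. A content-agnostic alternative ("largest loading positive") is
exposed as an option, but it is not the default because on the lipid axis the
largest-magnitude loading is HDL's *negative* one: forcing it positive flips
the axis and makes adverse lipids lower the score, contradicting the score's
meaning.

**Weighting.** The final score is `score_i = Σ_k w_k s_ik`. Two weightings
are implemented and both tested: `"proportional"` (`w_k = v_k / Σ v_k`, each
component weighted by its share of explained variance) and `"equal"`
(`w_k = 1`). The choice matters for dispersion: with two retained components
equal weighting gives a score SD of exactly √2 ≈ 1.41 on the fitting sample
(the component scores are uncorrelated with unit variance), while
proportional weighting gives `sqrt(w1² + w2²)` ≈ 0.71. Published MetS scores
of this family report an SD of 1.41, consistent only with (near-)equal
weights even when the text says "weighted by relative contribution"; since
the intent is ambiguous we default to the literal proportional reading and
expose `"equal"` explicitly. Rotated rather than unrotated component scores
are used, matching the reported post-rotation loadings; for orthogonal
rotations the sum over both weighted scores spans the same subspace either
way.

## Dichotomous classification

`classify_mets()` implements the harmonized definition: waist ≥ 94 cm (men)
/ 80 cm (women); HDL < 40 / 50 mg/dL (strict inequality, as printed); TG ≥
150 mg/dL; BP ≥ 130/85 mmHg read as SBP ≥ 130 **or** DBP ≥ 85 (the standard
reading of the slash); glucose ≥ 100 mg/dL. A medication flag forces its
feature regardless of the measurement; lipid-lowering medication maps to
*both* lipid features by default (configurable, since the definition does not
pin the mapping). Five criterion features are counted (six traits, but SBP
and DBP share one feature), so risk counts run 0–5 and MetS is count ≥ 3.
Prevalence intervals default to the Wald normal approximation (which
reproduces the conventional printed intervals for cohorts of this size);
Wilson is available behind a flag.

## Genetics

Dosages count minor alleles (0/1/2), with pairwise deletion so per-SNP sample
sizes may differ. Hardy–Weinberg equilibrium is tested by the plain 1-df
chi-square on observed vs expected genotype counts at the observed allele
frequency, without continuity correction. Association uses the dominance
contrast (carriers of ≥ 1 minor allele vs major-allele homozygotes) and a
pooled-variance Student t-test: pooled SE is the default because it is what
published genotype-group tables (n, mean ± SD per group) imply, and
`t_test_summary()` runs the identical arithmetic directly from such printed
summaries — `t_test_raw()` is defined as that function applied to the
groups' own summaries, so the two routes agree exactly. Welch is a flag.
Bonferroni correction multiplies by the family size (default 37, the shipped
candidate panel) and caps at 1. Per-trait association dispatches to the
t-test or Mann–Whitney according to a per-group Shapiro–Wilk screen.
Per-SNP risk orientation for the genetic risk count must be explicit
(`"carrier"`/`"noncarrier"`) because a protective minor allele flips the risk
state; the count feeds a linear trend test.

The trend test is a single-df linear contrast across ordered group means with
centered group codes and the pooled within-group mean square as error. It
equals the regression slope test exactly for two groups; with more levels the
regression error term additionally absorbs lack-of-fit, so the two differ
slightly by construction.

Power analysis inverts the two-sample normal approximation,
`δ = (z_{1-α/2} + z_{power}) · σ · sqrt(1/n1 + 1/n2)`, with σ defaulting to
1.41 (the equal-weight score SD). A noncentral-t refinement, which is
slightly larger, is available behind a flag; the normal form is the default
because it is the arithmetic behind conventionally reported minimum
detectable differences.

## Covariate adjustment

"Contribution to score variation" is operationalized as the marginal
incremental R² of each covariate against an intercept-only model (for a
single regressor, its squared correlation with the score); covariates above
the 5% threshold enter `score ~ carrier + covariates` by least squares, and
the genotype term is always retained regardless of screening. A partial-η²
alternative is available. Sex is coded female = 1 (direction affects only
the coefficient sign and is documented). The adjusted difference is reported
as reference minus carrier, matching the unadjusted tables; with no
covariates the fit reduces exactly to the pooled t-test.

## The synthetic generator

No individual-level cohort ships with the package; the generator makes every
stage testable. It emulates:

- six traits generated **on the transformed scale** as linear combinations of
  two latent standard-normal factors plus independent unique noise, with the
  default loading matrix shaped like the published two-component solution
  (communality + uniqueness = 1 per trait), then mapped to realistic
  transformed-scale values and inverse-transformed to raw units;
- genotypes in HWE at the 37-SNP panel's published minor-allele frequencies;
- covariates drawn independently at survey-style prevalences (female 57.8%,
  smoker 18.0%, excessive alcohol 8.7%, inactivity 59.7%, unhealthy diet
  35.9%, antihypertensive 26.2%, lipid-lowering 12.6%, antidiabetic 7.3%)
  and age ~ N(56.4, 16.2²) truncated to 26–91;
- optional dominance effects: carriers of configured SNPs have latent factor
  1 (the axis returned as `latent_score`) shifted by β before traits are
  generated; an optional age→factor term and an age–genotype association
  switch make confounding, and hence adjustment, testable.

**Numerical choices.** Transformed-scale locations/scales come from the
delta method at the target raw means/SDs, with the scale capped at a quarter
of the location wherever the inverse transform needs a positive value. Only
glucose hits the cap: its reciprocal-tenth-power transform is so sharp that a
Gaussian transformed value matching the full raw dispersion would put ~8% of
draws outside the valid domain, and the resampling this forces truncates the
tail and biases the glucose–factor correlation. The cap keeps invalid draws
negligible (rows that still land outside any domain are redrawn, up to a
bounded retry count) at the cost of a compressed raw-glucose SD (~15 instead
of ~34 units); the raw-trait match is approximate by design. All draws come
from one seeded generator stream, so a cohort is fully reproducible from
`(config, seed)`.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: linkage disequilibrium between SNPs (draws are
independent), measurement error, survey nonresponse, trait–covariate
dependence beyond the optional age term, non-Gaussian latent structure, and
any true genetic architecture. Tests against the generator validate the
*machinery* (calibration, recovery, invariances), not epidemiological
conclusions.

A note on recovery targets: PCA eigenvalues absorb unique as well as common
variance, so the top-two explained proportion of the generative correlation
matrix (≈ 74% under the default loadings) is necessarily larger than the
generative communality (≈ 63%). Structure-recovery checks therefore compare
the fitted explained variance against the population PCA value of the
generator's own correlation matrix, which is the quantity a PCA fit can
recover.

## Problem sizes and tolerances

The test suite and the acceptance script use: n = 5000 cohorts for
dispersion/structure recovery (score SD √2 ± 0.05; explained variance ±
0.05 of the population value); 500 replicate null cohorts of n = 206 for
association type-I error (5% ± 2%) and p-value uniformity
(Kolmogorov–Smirnov at α = 0.01); 1000 simulated SNPs at n = 500 for HWE
calibration; 100 replicates of n = 1000 for recovery of an injected 0.8
dominance effect (± 0.1); exhaustive enumeration for Mann–Whitney up to group
size 8; and exact equality (1e-12) for the raw-vs-summary t-test identity.
Equality of the standardization round trip is asserted at 1e-10 and transform
inversion at 1e-8 relative error.

## Known limitations

- The score is sample-relative: loadings, weights and standardization
  constants are re-estimated per cohort, so scores are comparable within a
  fitting sample (or via a serialized model applied to new data), not across
  independently fitted cohorts.
- The Wald prevalence interval is first-order and degenerates at p̂ ∈ {0, 1};
  use Wilson near the boundary.
- The marginal 5% screening rule ignores covariate collinearity; the partial
  metric mitigates but does not remove this.
- Only the dominance genotype coding is implemented end to end; additive and
  recessive codings are deliberate non-goals here.

## A worked example

```{r example}
cohort <- generate_cohort(synthetic_config(
  n = 206, seed = 1,
  genetic_effects = tibble::tibble(snp_id = "rs4244285", beta = -0.8,
                                   model = "dominant")))
res <- run_pipeline(cohort$phenotypes, cohort$genotypes, seed = 1)
res
res$association |>
  filter(p_value < 0.05) |>
  select(snp_id, n1, n2, estimate, conf_low, conf_high, p_value, p_bonferroni)
res$power$table |> filter(snp_id == "rs4244285")
```

The injected protective effect (carriers shifted down by 0.8 latent units)
surfaces as a positive reference-minus-carrier difference, and the power
table reports the smallest mean difference the realized group sizes could
detect at 80% power.
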