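---
title: "Modelling genetic risk for late-stage AMD: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling genetic risk for late-stage AMD: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(amdgrs)
```

## The problem

Late-stage age-related macular degeneration — geographic atrophy (GA) or
neovascular disease (NV) — is strongly heritable, with a handful of loci
(above all CFH and ARMS2/HTRA1) explaining a large share of disease. A
weighted genetic risk score summarises a subject's burden across the 13
established risk variants into one number on the log-odds scale, which can
then drive a risk classification and, under assumptions about population
prevalence, absolute-risk statements. This vignette explains the models the
package implements, the defaults and why they were chosen, what the
synthetic cohort generator does and does not emulate, and the numerical
choices that matter.

## The joint model and the score

Case status is regressed on all 13 risk-allele dosages at once by
maximum-likelihood logistic regression (`fit_joint_model()`, IRLS with
convergence tolerance 1e-10 on the deviance scale, at most 100 iterations;
rank-deficient designs and suspected separation — any |beta| above 15 — are
errors, not warnings). The score of a subject is the fitted linear
predictor,

$$\mathrm{GRS} = a + \sum_{i=1}^{k} b_i x_i,$$

including the intercept. The intercept *is* the centering constant: no
further standardisation is applied, because any affine change of the score
would silently move the classification boundaries. Consequences worth
knowing:

- `exp(b_i)` is the per-allele odds ratio of variant *i* given the others,
  generally different from the single-SNP odds ratio when variants at the
  same locus are correlated.
- Refitting case status on the in-sample GRS returns slope exactly 1 (the
  logistic score equations are already satisfied), so the in-sample odds
  ratio per GRS unit is exactly `e` ≈ 2.72. This is an identity, useful as
  a self-calibration test; only the *out-of-sample* slope is informative,
  and it is attenuated below 1 by estimation noise in the weights.
- Model fit is summarised by McFadden's pseudo R²,
  `1 − lnL(model)/lnL(intercept-only)`, which is not a variance-explained
  measure.

Per-SNP association (`fit_single_snp()`, `association_table()`) uses the
same additive logistic model with one dosage at a time, Wald CIs and
p-values (`exp(b ± 1.96·SE)`); a likelihood-ratio p-value is available by
flag. Models are unadjusted by default — age and sex can be added as a
sensitivity analysis. Hardy-Weinberg equilibrium in controls is tested with
the exact conditional test (the probability mass of all heterozygote counts
no more probable than the observed one, given the allele counts). An HWE
violation is reported, never a reason to drop a variant: the strongest AMD
variant, CFH Y402H, violates HWE in controls in the reference study and is
retained there.

## Risk categories and exact odds ratios

`grs_categories()` cuts the observed GRS range into five equal-width
intervals; assignment is right-closed (`]a, b]`), so a score exactly on a
cut point falls in the lower category. Equal width (rather than quantiles)
follows the published scheme: the extreme categories are deliberately small
and extreme.

Category odds ratios versus the middle category are estimated by
conditional maximum likelihood with exact conditional CIs (noncentral
hypergeometric inference, via `fisher.test()`). The reason is the sparse
top cell: the reference composition has a single control in category 5, and
Wald/Woolf intervals are meaningless there, while exact conditional
inference remains honest without continuity-correction hacks.

Published tables often print only within-group percentages.
`reconstruct_category_counts()` recovers integer counts as
`round(pct/100 × margin)`; the rounded counts need not sum exactly to the
margins (the reference reconstruction yields 985 of 986 cases), so the
table carries the true margins as an attribute and the prevalence weight is
always computed from those. Both integer and fractional-count conventions
are exposed because derived published values are not all reproducible under
a single convention.

## Population projection

A case-control sample fixes the case fraction by design. To model a
general population with prevalence π, each case is weighted by

$$w = \frac{\pi}{1-\pi}\cdot\frac{N_{\mathrm{controls}}}{N_{\mathrm{cases}}},$$

the unique weight making the weighted case fraction equal π exactly. The
absolute risk in category *g* is then `w·cases_g/(w·cases_g + controls_g)`,
and the modelled population fraction `(w·cases_g + controls_g)` over the
weighted total. The default prevalence schedule maps published late-stage
AMD prevalences to age bands: 1% (65–69), 2.5% (70–74), 5% (75–79),
10% (80–84), 15% (>85). These projections inherit all assumptions of the
weighting: representative controls, correct prevalence, and no age-by-GRS
interaction within a band.

## Validation

`roc_auc()` is the midrank Mann-Whitney AUC (ties credited 0.5), identical
to the trapezoidal area under the empirical ROC and invariant under
strictly increasing transforms of the score. `cross_validate()` repeats a
random 2/3–1/3 split, refits the joint model on the training part and
scores the held-out part; splits are simple random subsamples by default
(stratified splitting by flag), and the CI of the mean is the normal
approximation over repeats (percentile CI by flag). An unfittable split is
skipped; more than 5% skipped repeats aborts the run. No category
boundaries are re-derived inside CV — only weights are refit and the test
AUC computed.

`parsimonious_search()` ranks locus groups by single-locus in-sample AUC
and removes the weakest first, refitting at each step down to a single
locus; it flags the smallest model within 0.001 AUC of the full model and
also returns an exhaustive leave-one-locus-out table at the full model,
since strict greedy order is a choice, not a law.

## The synthetic cohort generator

No individual-level data are distributable, so the generator
(`simulate_cohort()`) emulates the study conditions:

- **Genotypes** under Hardy-Weinberg equilibrium at the published control
  risk-allele frequencies of the 13 variants (used as population
  frequencies — adequate for a disease with prevalence ≤ 15%).
- **Disease** through the logistic model with the published single-SNP
  per-allele odds ratios as true effects and an intercept calibrated so
  the population prevalence hits the target (default 15%).
- **Retrospective sampling** by rejection: population subjects are drawn
  and kept until exactly 986 cases and 796 controls are collected. One
  code path, exact under any LD structure.
- **LD (optional)**: within a locus group, each non-anchor variant can be
  coupled to the locus' first variant at the published r², with positive
  risk-allele phase (the published correlations do not state phase;
  positive coupling is assumed, not asserted) and conditional independence
  given the anchor. Loci are independent of each other — and independent
  is the default, because the parameter-recovery properties of the joint
  model are only exact when the simulating effects are the joint effects.

The intercept calibration is exact, not Monte Carlo: the distribution of
the genetic linear predictor is enumerated by convolving per-locus
genotype atoms (≤ 3¹³ support points for 13 independent SNPs, ~1.6M
atoms, well under a second of arithmetic), and the intercept is found by
monotone root finding to 1e-10 on the prevalence scale. Every stochastic
function takes an explicit integer seed and restores the caller's RNG
state; nothing consumes global randomness.

**What the generator does not emulate:** environmental risk factors
(smoking, diet), age structure and age-dependent effects, genotyping
error, cross-locus LD, and the spouse-control recruitment of the original
study. Passing tests on synthetic cohorts therefore demonstrate the
correctness and calibration of the *machinery* under the stated model —
not that real AMD data satisfy that model. Simulated in-sample AUCs
(~0.78–0.81) sit near but not exactly at the published 0.820, as expected
when within-locus LD is ignored and marginal effects are used as joint
effects.

## Numerical choices and degenerate inputs

- Logistic fits: `stats::glm` (binomial), epsilon 1e-10, 100 iterations;
  zero-variance dosages, rank deficiency, non-convergence and separation
  are errors naming the offending SNP/column.
- The Welch (unequal-variance) t-test is the default for comparing group
  mean GRS, with the pooled test by flag; for the three planned subgroup
  contrasts the Bonferroni level 0.05/3 is the default significance flag.
- HWE exact test: computed in log-space (`lgamma`), so counts in the
  hundreds of thousands are safe; equality of probabilities uses a 1e-12
  relative guard.
- Equal-width categories require a non-constant score; the interior widths
  agree to 1e-9 of the range by construction.
- A category empty of both classes yields `NA` odds ratio and absolute
  risk rather than an error; an empty reference category is an error.
- The dosage file format rejects any value outside {0, 1, 2} with its row
  and column; nothing is imputed or coerced (the reference study had no
  missing genotypes, and the package treats missingness as a data error
  upstream of analysis).

## Problem sizes used by the test suite

The suite simulates at the study's sample sizes where the property under
test demands it (parameter-recovery coverage across 500 replicate cohorts
of 986/796; null calibration of Wald p-values at n = 2000 across 500
fits), and at smaller sizes elsewhere; cross-validation properties use
100–200 repeats. These sizes were chosen as the smallest that leave the
statistical bands (e.g. 92–98% CI coverage) well-powered.

## Known limitations

- Absolute risks and predictive values are only as good as the assumed
  prevalence and the representativeness of the controls.
- The equal-width classification depends on the observed score range, so
  boundaries from one cohort must be exported (`write_model_export()`)
  and reused to classify another cohort on the same scale.
- Exact conditional CIs for sparse 2×2 tables are conservative and can be
  extremely wide (the top-category CI spans two orders of magnitude);
  that is the honest statement the data support.
- The parsimonious search is greedy in-sample model selection and is not
  protected against over-fitting; it describes this data set, not a law
  about which loci matter.
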