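---
title: "An anti-inflammatory diet score and its case-control analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An anti-inflammatory diet score and its case-control analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aidiet)
```

## The scientific setting

Chronic inflammation contributes to carcinogenesis, and dietary patterns
modulate systemic inflammation. `aidiet` implements the analysis toolkit
for a hospital-based case-control study of cutaneous melanoma that asks
two questions: does adherence to an anti-inflammatory diet lower melanoma
risk, and is any such effect modified by the COX-2 promoter polymorphism
−765G>C, whose C allele reduces promoter activity?

The study design the package assumes is a frequency-matched case-control
series: incident, histologically confirmed melanoma cases and hospital
controls without skin disease or cancer, matched 1:1 on sex and 5-year
age strata, with a dermatological examination (nevi, lentigines,
photo-type, pigmentary traits), a structured interview (education,
smoking, BMI, sun exposure, NSAID use, chronic disease) and a validated
food-frequency questionnaire (FFQ) on a seven-point frequency scale. A
subset of subjects donates blood for genotyping.

## The anti-inflammatory diet score

The score counts, over eleven food items with recognised
anti-inflammatory properties, how many a subject consumes at a high
level. Each item contributes a 0/1 indicator and the score is their sum,
so it ranges 0–11; all other foods contribute 0 by construction. The
item thresholds, expressed on the seven-point scale (0 = never, 1 = less
than monthly, 2 = less than weekly, 3 = 1–2 times weekly, 4 = 3–4 times
weekly, 5 = 5–7 times weekly, 6 = daily), are:

| item | high consumption | qualifying levels |
|---|---|---|
| green leafy vegetables, salad | ≥ 3 times/week | 4–6 |
| vegetables in general, citrus fruits | ≥ 5 times/week | 5–6 |
| fruits in general, coffee | daily or more | 6 |
| nuts, fish rich in n-3 fatty acids | weekly and more | 3–6 |
| exclusive olive oil; fresh rosemary; fresh salvia | yes | yes |

This threshold-to-scale mapping is the only consistent alignment of the
stated cut-offs with the seven-point scale: "≥ 3 times/week" admits the
3–4-weekly level and above, "≥ 5 times/week" the 5–7-weekly level and
above, "daily or more" only the daily level, and "weekly and more" the
1–2-weekly level and above.

Scores are categorised into terciles of the controls' distribution; the
published categories are low ≤ 5, medium 6–7, high ≥ 8, and these are
the package default. `control_tercile_cutpoints()` can re-derive
cut-points from any control series (empirical 1/3 and 2/3 quantiles,
floored to integers) but is deliberately opt-in: on synthetic or external
data the empirical terciles can differ from the published categories,
and the published cut-points are what the effect estimates refer to.

**Missing items.** The source tables report varying totals due to
missing values, yet all subjects are scored; the package therefore
defaults to counting a missing item as low consumption (contribution 0)
while recording `n_missing_items` per subject, with a `strict` policy
available that refuses to score incomplete records.

```{r score}
rec <- list(green_leafy = 4L, salad = 2L, veg_general = 5L, citrus = 3L,
            fruits = 6L, nuts = 3L, coffee = 6L, fish_n3 = 2L,
            olive_oil = 1L, rosemary = 0L, salvia = 0L)
compute_score(rec)
```

## RFLP genotype calling

The −765G>C assay amplifies a 228-bp promoter fragment; a restriction
enzyme cuts it into 161 + 67 bp only when the G allele is present. The
caller inverts this band pattern — {161, 67} → GG, {228} → CC,
{228, 161, 67} → GC — enforcing that cut fragments conserve the amplicon
length (161 + 67 = 228). Anything else, including the partial-digestion
patterns {228, 161} and {228, 67}, is an explicit no-call: with clean,
sequencing-confirmed RFLP as the reference standard there is no
justification for imputing ambiguous lanes. An optional ±bp tolerance
accommodates gel-estimated sizes; it never overrides the band count.
Because CC homozygotes are rare, analyses pool GC and CC as C-carriers.

## Statistical machinery

Descriptive contrasts use the Pearson chi-square test (no continuity
correction) for categorical variables and the Mann–Whitney U test
(midrank ties, tie-corrected normal approximation at n ≥ 8 per group,
exact enumeration below) for age. Crude odds ratios use the 2×2
cross-product with Woolf (log-scale Wald) 95% intervals; a
Haldane–Anscombe 0.5 correction is applied to zero cells only on
request.

Adjusted effects come from unconditional maximum-likelihood logistic
regression (IRLS, convergence tolerance 10⁻¹⁰, ≤ 100 iterations),
complete-case per model with the realised n reported alongside every
estimate. Non-convergence and separation (any |β| > 15 on the log-odds
scale) are errors, not warnings. The frequency-matched design is
analysed unconditionally with the matching factors (sex, age) in the
model; age enters as continuous years. Model presets A–H mirror the
published specification: A adjusts for sex, age, education (< 8 / 8–13 /
> 13 years), common nevi (0–59 / ≥ 60), skin photo-type (I–II vs
III–IV), solar lentigines and childhood sunburn; B–H each add one
robustness covariate (BMI class, COX-2 inhibitor use, aspirin, pooled
genotype, smoking, chronic disease excluding/including cardiovascular
disease). The stated variable-retention rule (keep covariates with
likelihood-ratio p < 0.05) is implemented via
`likelihood_ratio_test()` but is off by default — the presets use fixed
covariate lists so results are comparable across models. No
multiple-testing correction is applied.

Dose-response is tested by re-fitting with the tercile as an ordinal
0/1/2 code and reading the Wald z of that single coefficient.
Gene-diet interaction is a likelihood-ratio test of the adjusted model
with tercile × pooled-genotype product terms against the one without
(2 df); stratified estimates re-fit the adjusted model within each
genotype stratum, flagging (rather than dropping) strata too small to
support the fit.

## The synthetic-study generator

No subject-level data are distributed with the source study, so the
package ships a generator that emulates the study's statistical
structure and makes every pipeline stage testable end-to-end. The causal
order is exposure-first: covariates and diet are drawn for a source
population, disease is assigned from a logit-linear model, and the
case-control study is sampled from the result — so configured log-odds
are recoverable truths, not descriptive targets.

* **Covariates** are drawn independently at the control-series
  marginals of the study tables (the joint distribution is not
  reported; independence is the stated simplification). Age is
  truncated-normal on 18–90 years with mean 51.9, SD 15.6.
* **Genotypes** default to the printed frequencies
  (GG/GC/CC = 60.7/33.7/5.6%), which deviate from exact Hardy–Weinberg
  proportions at the implied allele-C frequency 0.2244 by at most 1.1
  points — a departure far below detection at study scale (the
  noise-free chi-square is 0.32). Supplying `allele_c_freq` switches to
  exact HWE sampling (p², 2pq, q²).
* **FFQ items** are Bernoulli indicators with marginals `item_p`,
  coupled through a single latent healthy-eating factor u ~ N(0, 1):
  item i is high with probability plogis(aᵢ + b·u), aᵢ solved by
  Gauss–Hermite quadrature so the marginal is exact. The loading
  b (default 0.76) induces the positive inter-item correlation real
  dietary patterns show and sets the score SD. Observed scale levels
  are then drawn within the qualifying/non-qualifying ranges with
  triangular weights peaked at the threshold; only the indicator enters
  any analysis.
* **Disease** follows logit P = intercept + β_T2·T2 + β_T3·T3 +
  covariate terms (+ optional C-carrier tercile offsets γ for
  gene-diet interaction). Default truths are the published adjusted
  tercile effects (OR 0.83 and 0.29) and the printed covariate odds
  ratios (nevi 5.41, photo-type 2.80, lentigines 3.60, childhood
  sunburn 2.50, education 1.43/2.87). The intercept (−4.35) sets
  population prevalence near 10%, keeping controls close to the source
  population so calibration statements about controls are clean.
* **Sampling** takes the requested cases at random from the diseased
  and apportions controls over sex × 5-year age strata to the cases'
  distribution (largest remainder; exact per-cell equality at 1:1).
  The population size is auto-scaled from a pilot prevalence estimate
  with a 30% margin; an unfillable matching cell is an error naming
  the cell. Per-field missingness is applied afterwards; by default
  only the genotype is masked, at 44.1%, mirroring the 303/542
  genotyped subjects.

### Calibration

The packaged defaults (`calibration_default()`) were fixed once against
the study's headline descriptives: at 50,000 synthetic controls and
cases the mean score is ≈ 6.20 in controls and ≈ 5.51 in cases (targets
6.2 and 5.5), with SDs ≈ 2.19 and 1.97 (printed 2.1 and 1.9). One
deviation is structural: the printed control tercile split
(39.8/29.0/31.2%) cannot coexist with mean 6.2 and SD 2.1 for any
unimodal score distribution (the split implies SD ≈ 2.7), so the
calibration privileges the means and SDs and realises a split of about
37/33/30%. The generator emulates marginal structure and the configured
effect sizes; it does not model recall bias, interviewer effects,
covariate dependence beyond the latent diet factor, or the hospital
control selection — so passing recovery tests demonstrates correctness
of the estimators under the assumed model, not robustness to those
real-data features.

## Worked example

```{r pipeline}
study <- simulate_study(generator_config(n_cases = 273, n_controls = 269),
                        seed = 20240523)
report <- analyze_study(study)
report$models[, c("model", "or_t2", "or_t3", "p_trend", "n")]
report$gene_environment$interaction
```

At the study's own size (273/269) the tercile estimates are noisy — the
Wald intervals are wide — which is exactly what the source design
implies; the parameter-recovery checks therefore run at 5,000–10,000
cases where Monte-Carlo error is small.

## Numerical and design choices

* Logistic CIs are Wald on the log scale throughout (matching the
  symmetric printed intervals); profile-likelihood intervals are not
  offered.
* The LRT statistic is clipped at 0 (it is non-negative in exact
  arithmetic; floating-point can dip infinitesimally below) and refuses
  to compare fits on differing rows or non-nested terms.
* Tercile cut-point derivation uses left-continuous (type-1) quantiles
  floored to integers; a degenerate control distribution (coincident
  terciles) is flagged, not silently accepted.
* Problem sizes in the test suite: property loops use 1,000 random
  records; null-uniformity checks use 500 replicates at n = 400;
  recovery checks 200 replicates at n = 5,000 (direct designs) plus
  single full-pipeline runs at 5,000–10,000 cases. These sizes keep
  Monte-Carlo error well inside the asserted tolerances.
* Default RNG seed when none is supplied: 20240523. The command-line
  `simulate`/`reproduce` subcommands require an explicit seed.

## Limitations

The package analyses the design it implements: unconditional logistic
regression for frequency-matched data, item-count diet scoring (no
nutrient-level inflammatory weighting, portion sizes or energy
adjustment beyond BMI as an indirect indicator), and a single candidate
polymorphism. The generator's independence assumptions mean synthetic
confounding structure is limited to what the disease model induces.
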