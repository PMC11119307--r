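# aidiet

Anti-inflammatory diet scoring and case-control association analysis for
cutaneous melanoma, with COX-2 −765G>C PCR-RFLP genotype calling and a
calibrated synthetic-study generator.

## The problem

Chronic inflammation promotes carcinogenesis, and diet is one of its few
modifiable drivers. For a hospital-based case-control study of melanoma
(incident cases and matched hospital controls), the analysis needs

1. an **anti-inflammatory diet score**: over eleven food items with
   recognised anti-inflammatory properties — green leafy vegetables,
   salad, vegetables in general, citrus fruits, fruits in general, nuts,
   coffee, n-3-rich fish, exclusive olive-oil use, fresh rosemary, fresh
   salvia — count the items consumed at a high level. Each item is a 0/1
   indicator against an item-specific threshold on a seven-point
   frequency scale (e.g. green leafy vegetables ≥ 3 times/week, coffee
   daily), so the score S ∈ {0, …, 11}; it is analysed in terciles
   (low ≤ 5, medium 6–7, high ≥ 8);
2. **genotype calls** for the COX-2 promoter polymorphism −765G>C from
   restriction-fragment patterns of a 228-bp amplicon ({161, 67} → GG,
   {228} → CC, {228, 161, 67} → GC), with GC/CC pooled as C-carriers;
3. the **association machinery**: k×2 contingency tables, crude odds
   ratios OR = ad/bc with Woolf intervals
   exp(ln OR ± 1.96·√(1/a + 1/b + 1/c + 1/d)), chi-square and
   Mann–Whitney descriptive tests, adjusted unconditional logistic
   models logit P(case) = β₀ + β_T2·T2 + β_T3·T3 + γᵀx for preset
   covariate sets A–H, Wald trend tests on the ordinal tercile,
   likelihood-ratio tests for covariate retention and for
   tercile × genotype interaction, and genotype-stratified estimates.

Because the source study's subject-level data are not deposited, the
package also ships a **synthetic-study generator**
(`simulate_study()`) whose defaults are calibrated to the study's
marginals (control mean score 6.2, case 5.5; genotype frequencies
60.7/33.7/5.6%; frequency matching on sex × 5-year age strata) with the
published adjusted effects as configured truths — so the entire
pipeline, including parameter recovery, runs at desk scale with no
external data. See the methods vignette
(`vignettes/anti-inflammatory-diet-analysis.Rmd`) for the model and its
assumptions.

## Worked example

```r
library(aidiet)

study  <- simulate_study(generator_config(n_cases = 273, n_controls = 269),
                         seed = 20240523)
report <- analyze_study(study)
report
```

```
case-control analysis: 273 cases / 269 controls

anti-inflammatory diet score terciles:
     variable  level n_case n_control pct_case pct_control    or ci_low ci_high
 diet_tercile    low    139        94     50.9        34.9    NA     NA      NA
 diet_tercile medium     93       101     34.1        37.5 0.623  0.424   0.915
 diet_tercile   high     41        74     15.0        27.5 0.375  0.236   0.595

multivariate models (tercile ORs vs low):
 model or_t2 ci_low_t2 ci_high_t2 or_t3 ci_low_t3 ci_high_t3  p_trend   n
     A 0.586     0.367      0.938 0.238    0.1338      0.422 1.15e-06 542
     ...
     E 0.577     0.318      1.048 0.177    0.0803      0.388 2.05e-05 311

gene-diet interaction LRT: p = 0.633 (n genotyped = 311)
stratified adjusted estimates:
   stratum  level    or ci_low ci_high  p_value   n available note
        GG   high 0.110 0.0350   0.347 0.000164 186      TRUE   NA
 C_carrier   high 0.275 0.0784   0.968 0.044281 125      TRUE   NA
```

Reading it: the crude high-vs-low tercile OR is 0.375; after model-A
adjustment (sex, age, education, nevi, photo-type, lentigines, childhood
sunburn) the high tercile carries OR 0.238 (configured generator truth
0.29 — a study of this size has wide intervals) with a strongly
significant dose-response trend; adding robustness covariates (models
B–H) barely moves the estimate; the gene-diet interaction is
non-significant and the protective diet effect is present in both
genotype strata. `n` is always the complete-case count the model
actually used — model E restricts to the 311 genotyped subjects.

Lower-level entry points: `compute_score()` / `score_subjects()`,
`call_genotype()` / `genotype_frequencies()` / `hwe_chi_square()`,
`crude_or()`, `fit_logistic()`, `wald_trend_test()`,
`likelihood_ratio_test()`, `interaction_test()`,
`stratified_estimates()`. A thin command-line front end with
`simulate`, `score`, `genotype`, `analyze` and `reproduce` subcommands
is at `system.file("cli", "aidiet.R", package = "aidiet")`.

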