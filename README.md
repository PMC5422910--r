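# phenoval

Administrative-data phenotyping algorithms with full diagnostic-accuracy
validation, built around one worked phenotype: identifying hospital
surgical encounters in which **endoscopic sinus surgery (ESS) was performed
for chronic rhinosinusitis (CRS)** from ICD-10 diagnostic and CCI
procedural codes.

Administrative databases represent diseases and procedures as codes, and a
code-based case definition is only usable for research once its agreement
with a ground-truth reference standard has been measured. `phenoval` is for
epidemiologists and health-services researchers who define such computable
phenotypes and need to validate them: it ships the CRS/ESS code lists and
the three model variants built on them, a hierarchical prefix/wildcard
code matcher, the complete 2×2-table accuracy machinery, and a seeded
synthetic cohort generator that can reproduce a published confusion
structure exactly — so every validation statistic can be recomputed from
scratch without access to the original patient data.

## The phenotype and its statistics

The final model labels an encounter a **case** when it carries at least
one CRS ICD-10 code (`J32.x` chronic sinusitis or `J33.x` nasal polyp
families) **and** at least one ESS CCI code (sinus drainage/excision
families such as `1.EU.52.^^`, where `^^` is a wildcard qualifier group);
two single-clause variants (diagnosis-only, procedure-only) are provided
for comparison. Against a chart-review reference standard on a 2×2 table
the package reports

- sensitivity `Se = tp/(tp+fn)`, specificity `Sp = tn/(tn+fp)`, positive
  and negative predictive value, prevalence — each with exact
  Clopper–Pearson (default), Wilson, or Wald confidence intervals;
- likelihood ratios `LR+ = Se/(1−Sp)`, `LR− = (1−Se)/Sp` with log-method
  (Simel-type) intervals;
- `ppv_at_prevalence()` to project PPV onto a different case mix via
  Bayes' theorem.

## Worked example

Rebuild the derivation cohort from the published confusion structure and
validate the final model against it:

```r
library(phenoval)

fixture <- derivation_fixture()     # joint code-presence counts, solved
cohort  <- realize_cohort(fixture, seed = 1)   # 185,354 encounters
nrow(cohort)
#> [1] 185354

ct <- confusion_from_cohort(cohort, model_catalog()$model3)
accuracy_report(ct)
#> <accuracy_report> 95% CIs (clopper_pearson; log method for LRs)
#>   sensitivity  96.0% (93.3-97.8)
#>   specificity  100% (100-100)
#>   ppv          95.4% (92.7-97.4)
#>   npv          100% (100-100)
#>   prevalence   0.19% (0.17-0.21)
#>   lr_positive  11,096 (6,795-18,121)
#>   lr_negative  0.04 (0.02-0.07)
```

Reading the output: of the 347 reference cases in the 185,354-encounter
cohort, the model finds 96.0% (333), and 95.4% of its 349 predicted cases
are true cases; at a case prevalence of 0.19%, a positive model label
raises the odds of true ESS-CRS status about 11,000-fold. The internal
validation design — review all predicted cases plus 200 randomly sampled
predicted controls from a later year — is one call:

```r
review <- sample_validation_cohort(
  realize_cohort(validation_year_fixture(), seed = 5),
  model_catalog()$model3, n_controls = 200, seed = 6)
accuracy_report(confusion_from_cohort(review, model_catalog()$model3))
#> <accuracy_report> 95% CIs (clopper_pearson; log method for LRs)
#>   sensitivity  98.9% (96.2-99.9)
#>   specificity  97.1% (93.7-98.9)
#>   ppv          96.9% (93.3-98.8)
#>   ...
```

A command-line surface wraps the same functions:

```sh
exec/phenoval simulate --fixture derivation --seed 1 --out cohort.csv
exec/phenoval report   --input cohort.csv --out results/
```

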