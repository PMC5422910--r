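---
title: "Validating a code-based ESS-CRS phenotype: models, statistics and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a code-based ESS-CRS phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoval)
```

## The problem

Administrative health databases record diseases and procedures as codes
(ICD-10 diagnoses, CCI interventions in Canadian data). Before a coded rule
— a *computable phenotype* — can be used to assemble a research cohort, its
agreement with a ground-truth reference standard must be measured, because
encounters carrying a code frequently do not have the condition the code
represents. `phenoval` implements one such phenotype end to end: identifying
hospital surgical encounters in which endoscopic sinus surgery (ESS) was
performed for chronic rhinosinusitis (CRS), validated against
chart-review-confirmed case status, together with the general machinery any
such validation needs.

## The phenotype models

Three model variants over an encounter's code sets, available from
`model_catalog()`:

* **model1** — the encounter lists any CRS ICD-10 diagnostic code
  (the chronic sinusitis family `J32`, `J32.0`–`J32.4`, `J32.8`, `J32.9`
  and the nasal polyp family `J33`, `J33.0`, `J33.1`, `J33.8`, `J33.9`);
* **model2** — the encounter lists any ESS CCI procedural code (drainage,
  destruction, repair, partial or radical excision families on the
  ethmoidal, sphenoidal, maxillary, frontal and paranasal sinuses, e.g.
  `1.EU.52.^^`);
* **model3** (the final model) — both: at least one CRS diagnostic code
  AND at least one ESS procedural code.

An analogous ICD-9 list (`473.x`, `471.x`) is carried for users defining
variants on legacy data, but no shipped model uses it.

### Matching semantics

Codes are normalized (uppercased, dots and whitespace stripped) and matched
by hierarchical prefix: pattern `J32` matches `J320`, `J324`, and so on.
CCI wildcard groups (`^^`) denote whole qualifier families; we treat a
wildcard as "any completion" — the pattern matches any code extending the
text before the first wildcard group — rather than "exactly two
characters", because qualifier-field lengths vary across data dialects and
every enumerated child code is matched either way. Under this rule the one
pattern printed with a single wildcard group (`1.EX.^^`) reduces to the
plain prefix `1EX`, consistent with its siblings. The published code table
prints two of its CCI rows twice; a `code_list` stores set-deduplicated
patterns since duplicates cannot change an any-match. All diagnosis fields
on an encounter are eligible — the published rule says "at least one" code
with no position qualifier, so no primary-diagnosis restriction is applied.

Clauses are restricted to `ALL`/`ANY` combinations of code lists: the
validated models need nothing more, and negation is easy to misuse
silently. Algorithms are data (JSON), not code, so users can author
variants cheaply. The minimum-age rule (18 years) was an eligibility
criterion of the chart review, not part of the coded model, so
`filter_adults()` keeps encounters with missing age and warns instead of
dropping them.

## Accuracy statistics

`build_confusion()` cross-tabulates predicted against reference labels
into a 2×2 table; `accuracy_report()` computes, on unrounded proportions:

* sensitivity $Se = tp/(tp+fn)$, specificity $Sp = tn/(tn+fp)$,
  $PPV = tp/(tp+fp)$, $NPV = tn/(tn+fn)$, prevalence $(tp+fn)/N$;
* likelihood ratios $LR^+ = Se/(1-Sp)$ and $LR^- = (1-Se)/Sp$, with
  $LR^+ = \infty$ reported as an explicit sentinel when $fp = 0$ and any
  zero-denominator statistic reported as *undefined*, never as 0 — no
  silent 0.5 continuity corrections.

Rounding happens only at display time (`format_report()`): percentages to
one decimal, except values that round to 100.0 are shown as `100` and
percentages below 1 keep two decimals (so a 0.19% case prevalence is not
flattened to 0.2); ratios use magnitude-dependent precision (≥ 100 nearest
integer, [1, 100) one decimal, < 1 two decimals), with half-way values
rounded away from zero, the display convention of the validation tables.
Carrying unrounded proportions matters: the derivation-period $LR^+$ of
11,096 is only reproducible from the exact $Se$ and $Sp$, not from their
printed one-decimal forms.

### Confidence intervals

Binomial proportions use Clopper–Pearson (exact beta-quantile) intervals
by default, with Wilson score and Wald available by flag. The validation
study named no method; exact intervals are consistent with its printed
bounds within rounding and were the common statistical-software default of
its era. Likelihood-ratio intervals use the standard log-transform
(Simel-type) form,

$$\exp\!\Big(\ln LR^{+} \pm z_{1-\alpha/2}
  \sqrt{\tfrac{1}{tp} - \tfrac{1}{tp+fn} + \tfrac{1}{fp} - \tfrac{1}{fp+tn}}\Big),$$

(analogously for $LR^-$ with $fn$ and $tn$ in the leading terms), which
reproduces the published derivation bounds (6,794–18,120) and validation
bounds (15.3–74.0) to within rounding; no alternative interval we examined
comes closer. A zero cell makes the interval undefined and is flagged
rather than corrected. Note one caveat: the published internal-validation
sensitivity and PPV intervals are not exactly Clopper–Pearson (and the PPV
upper bound is printed inconsistently in two places in the source report),
so proportion CI bounds are treated as approximate reproductions, not
exact targets, throughout the tests.

`ppv_at_prevalence()` projects a validated $(Se, Sp)$ pair onto another
centre's case mix via Bayes' theorem — relevant because predictive values
are prevalence-dependent and the phenotype was validated at ~0.19% case
prevalence.

## Synthetic cohorts

No encounter-level data can be shipped, so the package generates it.

**Fixture mode.** A `joint_count_fixture` fixes, per reference stratum,
how many encounters carry *both* codes, a *diagnostic code only*, a
*procedural code only*, or *neither*. These eight integers fully determine
the confusion tables of all three models, so realized cohorts reproduce
them exactly for every seed — randomness affects only which concrete
codes, ids, ages, dates and ordering appear. `solve_joint_counts()`
reconstructs the derivation-period fixture from published material alone:
the final model's complete 2×2 table (333/16/14/184,991) plus each
single-clause model's sensitivity and PPV printed to one decimal. It
searches exhaustively over admissible integer (TP, FP) pairs — bounded
below by the conjunctive model's cells, since the final model's cases are
a subset of each single-clause model's — keeping pairs whose percentages
match under round-half-up to one decimal, and errors unless the solution
is unique. For the derivation cohort it is: cases split 333/2/3/9 and
controls 16/8/8/184,975 across both/dx-only/proc-only/neither.

For the internal-validation year only the final model's table is
published (186/6/2/198 over 392 reviewed encounters), so
`validation_year_fixture()` is a constructed stand-in: the 2 false-negative
cases are realized as diagnostic-code-only encounters (any pattern short
of "both" keeps them predicted controls, as they must be to appear among
the 200 sampled controls) and the 198 true controls as neither-code
encounters. Single-clause-model results on this fixture are therefore not
meaningful.

**Realization choices.** "dx present" draws one leaf code uniformly from
the CRS ICD-10 list; "proc present" one concrete qualifier completion
(`AA`-style) of the ESS CCI families — under prefix semantics any
completion matches, and a property test asserts the choice cannot affect
labels. Absent fields receive filler codes from unrelated ICD-10 chapters
and CCI families (verified non-matching by test) so the matcher's negative
space is exercised. Ages are uniform 18–90 and dates uniform over the
fixture's period; both are cosmetic.

**Parametric mode.** `parametric_generate()` draws code presence per
stratum from free probabilities, independently by default; a `dependence`
parameter in [0, 1] mixes in a comonotone coupling for positive
within-encounter correlation between diagnostic and procedural coding.
This mode supports power-style exploration and the parameter-recovery
property tests (empirical model1 sensitivity within 3 binomial SDs of the
generating probability at 10⁴ cases).

`sample_validation_cohort()` implements the internal-validation design —
all model-predicted cases plus a seeded random sample of predicted
controls — and `apply_attrition()` emulates record-linkage loss (the
source cohort lost 10 cases and 3 controls in linkage, 357 → 347 cases).

**What the generator does not emulate.** Chart-review adjudication
(surgical indication, recurrent-sinusitis re-review), longitudinal
structure (repeat encounters per patient), realistic co-occurrence of
specific codes on real encounters, and coding-quality drift. Passing
fixture-mode tests therefore demonstrates that the *software* reproduces
the published confusion structure, not that the phenotype would achieve
these statistics at another centre — external transportability is exactly
what `ppv_at_prevalence()` is meant to probe.

All stochastic operations take a mandatory integer seed and set the RNG
state, making every fixture bit-reproducible.

## Numerical and interface choices

* Counts and percentage matching in the solver use round-half-up to one
  decimal, the display convention of the published tables; base R's
  round-half-to-even would mis-rank half-way percentages.
* Statistic computation is in double precision on exact count ratios; no
  intermediate rounding.
* Degenerate inputs: empty cohorts flow through classification and CSV
  round trips; an all-case prediction makes control sampling an error, as
  does attrition exceeding a stratum.
* The CLI (`exec/phenoval`, subcommands `simulate` / `classify` /
  `validate` / `report`) is a thin layer over the exported `cmd_*`
  functions with YAML/JSON config files mirroring the flags; stage counts
  are logged to stderr for attrition auditability, and input errors
  (exit 1) are distinguished from configuration errors (exit 2).

## Problem sizes used in the test suite

The derivation-scale checks realize the full 185,354-encounter synthetic
cohort (about half a second to generate and under a second per model to
classify); property tests use cohorts of 10⁴–10⁵ encounters for parameter
recovery and tens of encounters for oracle-equivalence checks, sizes at
which the naive double-loop oracle remains fast.

## Limitations

* The ESS-CRS phenotype is single-encounter; no temporal logic (code X
  within N days of code Y) is provided.
* No ROC/AUC machinery: the phenotype is a binary rule with no threshold
  to sweep.
* The ICD-10↔ICD-9 lists are parallel, not a general cross-walk.
* The validation-year fixture's within-stratum split beyond the final
  model's cells is a modelling choice, as described above.
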