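---
title: "The triple p16-CD8-Ki67 score: method, evaluation and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The triple p16-CD8-Ki67 score: method, evaluation and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplescore)
```

## The procedure

Homozygous deletion of *CDKN2A* in multiple-primary and familial
melanoma is normally established by dual-color FISH. The triple score is
a semi-quantitative surrogate built from three routine
immunohistochemical readouts, each mapped to an ordinal class and
summed:

- **p16** (percentage of tumor cells with intense staining), digressive
  four-class scale: >50% → 0, 11–50% → 1, 1–10% → 2, complete absence
  (0%) → 3. Loss of p16 expression is the direct phenotypic correlate of
  *CDKN2A* deletion.
- **CD8** (percentage of CD8-positive peritumoral TILs), digressive
  four-class scale: >60% → 0, 20–60% → 1, <20% → 2, absence (0%) → 3.
  The class limits follow the weak/moderate/intense convention
  established for CD8 TIL grading in melanoma pathology.
- **Ki67** (proliferation index in the hot spot), progressive five-class
  scale: <2% → 0, 2–5% → 1, 6–10% → 2, 11–20% → 3, >20% → 4.

The total ranges over 0–10 and a tumor is predicted to carry a
homozygous *CDKN2A* deletion when **total ≥ 9**. The model's assumption
is monotone risk: p16 loss, TIL depletion and high proliferation each
move the tumor toward the homozygous-deletion phenotype, and the maximum
total of 10 is attained exactly for complete p16 loss, absent
peritumoral TILs and Ki67 above 20%.

Heterozygous deletions are *not* a target: in the reference cohort all
three heterozygous-deletion patients score below 9, and the score is
interpreted strictly as a predictor of homozygous loss. Monosomy and
disomy are treated as CDKN2A-wild type throughout.

## Boundary semantics and the integer grid

The published class limits leave two boundary questions open ("<20%"
against an explicit "0%" class; "2–5" next to "6–10"). The package
resolves them by operating on the integer percent grid:

- all marker percentages are rounded **half-up** to integers at cohort
  validation (marker percentages are reported as integers in practice,
  typically on a multiple-of-5 grid);
- each scale is a total, non-overlapping partition of 0..100:
  p16 51–100/11–50/1–10/0; CD8 61–100/20–60/1–19/0; Ki67
  0–1/2–5/6–10/11–20/21–100.

Two boundary placements are forced by the reference cohort's published
per-patient totals: p16 = 50 must score 1 (the top class is strictly
>50), and CD8 = 20 must score 1 (the moderate class includes its lower
bound). Under these semantics the recomputed totals agree with the
published per-patient totals for 22 of the 23 reference patients. The
sole exception, CV005 (p16 50, CD8 20, Ki67 60), computes to
1 + 1 + 4 = 6 against a published 5; no consistent rubric reproduces
both CV005 and the two patients that force the boundary placements, so
the published 5 is treated as a typesetting error and excluded from
exact-match regression. The classification at the ≥ 9 cut-off is
unaffected either way.

The cut-off comparison is `>=` ("at least 9"), so the one false-positive
monosomy case (VS019, total 10) is positive under either a `>=` or `>`
reading.

## Evaluation definitions

`confusion_matrix()` tallies predictions against the FISH truth label.
The default positive class is `homozygous_deletion`; `any_mutation`
pools homo- and heterozygous deletions and is provided because the
group-level marker statistics use that dichotomy. Sensitivity is
tp/(tp+fn) and specificity tn/(tn+fp), each defined only when its
denominator is positive. On the bundled cohort at threshold 9 this gives
sensitivity 7/7 = 100% and specificity 15/16 = 93.75% over the 16
non-homozygous patients; reports carry the defining formulas in their
`notes` so the denominator is never ambiguous. Evaluation pools the
test and validation splits by default; `split = "test"` or
`"validation"` restricts it.

`threshold_sweep()` evaluates all eleven integer cut-offs. Because
positivity is `total >= threshold`, sensitivity is non-increasing and
specificity non-decreasing in the threshold; the Youden index
(sensitivity + specificity − 1) ranks candidate cut-offs, and on the
reference cohort 9 is the unique threshold attaining full sensitivity
with maximal specificity.

Group comparisons use **Welch's unequal-variance two-tailed
*t*-test** with Satterthwaite degrees of freedom. This choice was made
because it reproduces the reference group *p*-values for p16
(0.009045612) and Ki67 (0.430718946) to their full printed precision,
where pooled-variance and one-tailed variants do not — consistent with
the spreadsheet convention of an unequal-variance two-tailed test. The
reference CD8 *p*-value (0.1185) is reproduced by neither the Welch
(0.1076) nor the pooled (≈0.14) test on the bundled marker values; the
package computes and reports the Welch value and does not attempt to
reverse-engineer the published one.

`bootstrap_ci()` gives percentile (2.5/97.5) intervals for sensitivity
or specificity by case resampling. A replicate that happens to contain
no positives (or no negatives) leaves the metric undefined and is
redrawn; if more than half of all draws are undefined the cohort is too
small for a stable interval and an error says so. Intervals are
deterministic given the seed.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `threshold` | 9 | score points | positivity cut-off; 0–10 allowed for sensitivity analysis |
| `positive_definition` | `homozygous_deletion` | — | or `any_mutation` |
| `n_boot` | 2000 | replicates | ≥ 100 enforced |
| `fraction_test` | 0.5 | proportion | stratified split fraction |

The bin limits themselves are fixed constants of the method and are not
exposed as tuning parameters; `threshold_sweep()` is the supported
sensitivity analysis.

## The synthetic cohort generator

`empirical_config()` estimates, per CDKN2A status and marker, a
categorical distribution on the integer percent grid with the observed
relative frequencies; `generate_cohort()` draws patients from those
categoricals. This emulates the salient structure of real cohorts —
genotype-conditional discrete marker values (in the reference cohort
p16 only takes the values 0 and 50, and all markers sit on a
multiple-of-5 grid) — and makes every downstream stage testable at
arbitrary size without external data.

What it deliberately does **not** model: within-genotype correlation
between markers (real p16 loss and Ki67 elevation are correlated;
markers are drawn independently here), lesion-level heterogeneity,
multiple tumors per patient, and anatomic-site or sex covariates.
Passing tests on synthetic cohorts therefore demonstrate the
correctness of the scoring and tallying machinery, not the clinical
performance of the rubric on new patients.

`split_cohort()` reproduces the design's stratified randomization:
within each of the CDKN2A-wt and CDKN2A-mut strata a round-half-up
share of records goes to the test split, so at fraction 0.5 stratum
sizes differ by at most one; a stratum with fewer than two records
cannot be split and goes to the test set with a warning.

Seeding contract: every random operation takes one root seed, seeds R's
default Mersenne-Twister stream locally, and restores the caller's RNG
state afterwards, so identical seeds give identical cohorts, splits and
bootstrap intervals regardless of call order.

## Numerical choices and degenerate inputs

- Percentages are validated to [0, 100]; out-of-range values raise a
  domain error naming the offending record and field — never silent
  coercion.
- Display rounding is half-up to 2 decimals and kept separate from the
  full-precision values (JSON reports carry both, so downstream
  regression checks need no tolerance).
- Empty cohorts: scoring returns an empty table; confusion matrices and
  sweeps refuse to evaluate (no silent division by zero).
- `welch_t_test()` requires two complete samples of size ≥ 2 and errors
  on two zero-variance samples; a sample tested against itself gives
  t = 0, p = 1.
- Probabilities in synthetic configurations must sum to 1 within 1e-12.

## Problem sizes used by the test suite

The property suites run the bin functions exhaustively over all 101
integer inputs against independently written lookup tables, check
confusion-matrix tallies against a naive per-record loop on synthetic
cohorts up to ~10,000 records, and verify parameter recovery
(total-variation distance between generating and re-estimated
categoricals below 0.05) at 10,000 patients per status under a fixed
seed. These sizes give comfortable statistical resolution for the
checks while keeping the default test run fast.

## Known limitations

- The reference cohort is small (23 patients from a single region); the
  bundled sensitivity/specificity are in-sample numbers, not external
  validation.
- The rubric does not detect heterozygous *CDKN2A* deletion, and p16
  staining-intensity grades are not part of the score.
- The published specificity figure for the reference analysis (94.11%)
  corresponds to no standard denominator over these 23 patients; the
  package reports the standard tn/(tn+fp) = 93.75% and documents the
  definition in the report notes rather than matching the published
  number.
- Synthetic cohorts inherit the independence simplification above; any
  claim about marker correlation structure is outside their scope.
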