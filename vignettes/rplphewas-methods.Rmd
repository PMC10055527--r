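---
title: "Methods: EHR phenotyping and phenome-wide association for recurrent pregnancy loss"
author: "rplphewas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EHR phenotyping and phenome-wide association for recurrent pregnancy loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical design it
implements: the cohort definitions, the models, the synthetic data that
stand in for protected records, and the numerical and design choices made
where more than one defensible option existed. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## Study design

The package implements a retrospective case-control phenome-wide
association study. Cases are patients with recurrent pregnancy loss (RPL,
two or more losses); controls are patients with an uncomplicated live
birth. For every candidate phenotype — a Phecode-aggregated diagnosis
occurring in at least one cohort member's study window — the analysis asks
whether carrying that phenotype is associated with being in the RPL group,
adjusting for confounders. Everything operates on three flat OMOP-shaped
tables (persons, dated vocabulary-tagged events, visits), a concept-set
file defining the pregnancy-outcome and gender concept groups, and an
ICD→Phecode crosswalk.

## Cohort phenotyping

**RPL qualifying rules.** A record qualifies through any of: (a) an RPL
diagnosis code; (b) a pregnancy-loss record strictly after a recorded
history-of-pregnancy-loss; (c) two loss records at least 90 days apart.
The 90-day separation exists to avoid counting multiple records of the
same loss as two losses; "at least" is read inclusively, so a 90-day gap
qualifies and an 89-day gap does not, and the test suite pins this
boundary. The index date is the earliest date at which any rule is first
satisfied; where rules tie on the same day the fixed order (a), (b), (c)
breaks the tie deterministically. For rule (c) the earliest qualifying
second loss is found against the record's earliest loss, which minimizes
the index date; the suite checks index-date minimality against exhaustive
pairwise evaluation. "After" in rule (b) is strict: a same-day history and
loss record does not qualify.

**Controls** need at least one live-birth record and a whole-record
absence — no time restriction — of loss, RPL-diagnosis, history-of-loss
and exclusion-outcome records (preterm birth/labor, molar, extrauterine
pregnancy and similar). The index date is the first live birth. Because
any loss record excludes a patient from the control group, the RPL and
Control groups are disjoint by construction.

**Gender-inclusive demographics.** Patients are included when their
recorded gender code is female *or* they have any incident-pregnancy
record; gender-diverse concept records set a `tgd` label. This keeps
transgender, non-binary and gender-diverse patients who have been pregnant
in the study instead of dropping them on the gender field.

**Quality filters.** Site selection flows typically apply demographic,
data-quality and data-sufficiency screens whose exact criteria are
site-specific. The package uses four declared, configurable stand-ins
(`cohort_config()`): non-missing birth date, age at index within [10, 60]
years, index date inside the person's recorded event span, and at least
one visit. Attrition is reported per step and group, and counts are
asserted non-increasing. Whether a minimum record-length threshold should
also apply is left to the analyst (`cohort_config` is the hook); none is
imposed by default. Similarly, rule (b) imposes no time limit between the
history record and the subsequent loss, because none is part of the
definition.

## Study window and phenome construction

The study window is everything before the index date plus 365 days after
it ("a year" is fixed at 365 days for day-granularity determinism;
configurable). The post-index year is included because diagnostic workups
that follow a loss or birth are informative about the pregnancy outcome.
Events on the index date count as in-window. ICD9/ICD10 codes are mapped
through the crosswalk — exact string matching after whitespace trimming;
an optional `strip_dots` flag is the only normalization, since silent
fuzzy matching hides data errors — and unmapped codes are excluded from
the phenome rather than given pseudo-phenotypes. Presence is one-hot: five
records of the same Phecode count once. A phenotype is a candidate column
when at least one cohort member carries it in-window; for age-stratified
runs candidates are re-derived within each stratum.

## Association models

**Crude.** The crude odds ratio is the 2×2 cross-product ratio `ad/bc`
(identical to the single-binary-predictor logistic MLE), with a Wald
p-value on the log scale. Any zero cell triggers the 0.5 continuity
correction on all four cells, flagged in the output, so estimates stay
finite.

**Adjusted.** The adjusted model is a binomial GAM,
`logit P(RPL) = beta_x x + s(age) + race + ethnicity`, with a penalized
thin-plate spline on age (basis dimension k = 10, smoothness selected by
penalized likelihood) because pregnancy-loss risk is strongly non-linear
in maternal age. Race and ethnicity enter as unordered factors with the
largest observed category as reference and missing values as an explicit
`"unknown"` level — deterministic regardless of input ordering. The
engine is mgcv: `gam(..., method = "REML")` below 2,000 observations and
`bam(..., discrete = TRUE, nthreads = 1)` at or above it; both select
smoothness by penalized likelihood, and the discrete method keeps
phenome-scale scans (thousands of fits) tractable on one core. When the
age smooth cannot be supported (fewer unique ages than basis functions)
the age term degrades to linear; with no covariates at all the fit reduces
to plain logistic regression and reproduces the crude estimate to
numerical precision (tested at 1e-6).

**Degenerate fits.** A phenotype constant in the sample is skipped (no
estimate enters the multiple-testing family). Quasi-separation or
non-convergence — detected by non-convergence flags, |log OR| ≥ 15 or a
Wald standard error ≥ 10 — falls back to a ridge-penalized logistic model
(penalty 0.5 on all non-intercept coefficients, intercept unpenalized)
with a fixed-knot natural cubic age spline on 5 interior quantile knots.
Its Wald p-value uses the penalized information matrix and is approximate;
the row is flagged `separation_fallback`.

**Multiple testing.** Benjamini–Hochberg adjustment is applied across
exactly the phenotypes tested in one analysis run — main, each age
stratum, and the utilization sensitivity run are separate families.
Significance is adjusted p < 0.05. The BH step (`bh_adjust()`) wraps
`stats::p.adjust`; the suite verifies it against a hand-rolled step-up
implementation on randomized vectors.

**Utilization sensitivity.** The sensitivity run appends the study-window
visit count as a linear covariate. Visit count is a direct measure of
contact with the health system, and is deliberately kept *out* of the main
model: utilization can confound (more contact, more recorded diagnoses
and more recognized losses) but also collide (diagnoses increase
utilization), so the main/sensitivity contrast is reported rather than a
single "correct" model. The comparison statistic is the median percent
change `100 (OR_main − OR_sens) / OR_main` over the union of phenotypes
significant in either run; positive values mean attenuation.

**Redaction.** Rows where the positive count is below 10 in *both* groups
are masked (counts, ORs, p-values withheld; the row and its flag remain).
The threshold-10 convention matches the plotting filter, which keeps
points with ≥10 patients in *either* group; the write path emits the
literal token `REDACTED` and the test suite scans all artifacts for
violations.

## Cross-site validation

Two sites' results are intersected on shared candidate phenotypes.
Concordance classes (validated positive, validated negative, discordant,
single-site-only, neither) partition the shared set; an odds ratio of
exactly 1 counts as the negative direction, a deterministic tie-break that
never fires in continuous data. Overlap enrichment uses the hypergeometric
upper tail P(X ≥ x) with population = shared candidate count, successes =
site A's significant count, draws = site B's — a symmetric,
conventional parameterization (the margins could be chosen otherwise; the
bound-level conclusion is insensitive to the choice). Odds-ratio agreement
uses Spearman rank correlation, invariant to the log scale of ORs. The
age-strata comparison counts phenotypes whose under-35 OR strictly exceeds
the 35-plus OR over the union of significant-in-either-stratum phenotypes;
ties count as not-higher.

## The synthetic EHR generator

The generator exists so that every downstream stage can be validated
against known truth. Its defaults encode the study conditions the package
is designed around:

* **Age:** truncated-normal age at index, means 36.6 (cases) vs 33.4
  (controls) years, sd 6, range [18, 55] — cases older than controls.
* **Utilization:** per-person visit counts are 1 + negative-binomial
  (dispersion 1.5), with the mean tuned so the count median hits the
  configured target. The UCSF-like profile uses medians 42 vs 41
  (near-balanced); the Stanford-like profile uses 31 vs 14 plus a
  utilization→diagnosis slope of 0.03 log-odds per visit, creating genuine
  utilization confounding. Overdispersed counts are the norm in EHR
  utilization data.
* **Ethnicity contrasts** per profile (11.7% vs 16.6% and 16.4% vs 29.3%
  Hispanic/Latino among cases vs controls); race is generated
  independently of phenotypes by default so tests can isolate age and
  utilization effects.
* **Outcomes:** each synthetic case satisfies exactly one qualifying rule,
  chosen uniformly, so all three phenotyping branches are exercised
  evenly; controls get one live birth and no loss/exclusion records.
* **Phenotypes:** each candidate phenotype fires per person with
  probability `plogis(qlogis(baseline) + logOR·I[case] +
  slope·(visits − median))`, where the centering median is the empirical
  median of the site's generated visit counts. Planted log ORs are
  user-specified; null phenotypes get log OR 0 with baselines spaced
  log-uniformly over [0.01, 0.20]. Event dates are uniform over the three
  years before through 365 days after index — no within-window timing
  structure is modeled, because none is part of the design being tested.
  Each phenotype is reachable through one ICD10CM and one ICD9CM code, so
  the dual-vocabulary aggregation path is always exercised.
* **Contaminated controls** (`generate_contaminated_controls`) emulate the
  key limitation of loss-based control selection: a configurable fraction
  of controls are truth-only loss carriers whose candidate diagnoses
  follow the case model while their recorded data still qualify them as
  controls. Planted odds ratios attenuate toward 1 as the rate grows,
  which the suite checks directionally with paired seed sets.

What the generator does **not** emulate: diagnosis co-occurrence
structure, within-person temporal correlation, seasonality, ICD9→ICD10
coding-era drift, or informative missingness. Passing tests therefore
demonstrate that the pipeline's logic and estimators are correct under
known data-generating mechanisms — not that real-data associations are
unbiased with respect to the many EHR artifacts the generator leaves out.

## Validation suites and problem sizes

The property suites in `tests/testthat/test-acceptance.R` run at sizes
chosen to make their statistical tolerances meaningful on a single CPU:

* phenotyping vs an exhaustive pairwise rule oracle on 500 randomized
  records concentrated around the 90-day boundary;
* generator→phenotyping closed loop at 2,000 per arm over 5 seeds;
* estimator calibration: planted log ORs {−0.7, 0, 0.7, 1.6} at 5,000 per
  arm, mean absolute bias < 0.1 over 10 seeds;
* FDR control: 20 all-null sites with 200 phenotypes at 2,000 per arm,
  mean significant count ≤ 10 (= 0.05 × 200);
* utilization confounding: with a planted visits→case and visits→diagnosis
  link and zero direct effects, the visit-adjusted OR moves toward 1 for
  ≥80% of phenotypes, while a balanced site moves < 5% (median);
* primitive oracles (BH, cross-product OR, Mann–Whitney, Spearman,
  hypergeometric tail) against brute-force definitions;
* a post-hoc scan of every emitted artifact for redaction and plot-filter
  violations.

## Known limitations

The adjusted model tests one phenotype at a time; no interaction or
effect-modification terms are fitted, no meta-analytic pooling across
sites is attempted (sites are intersected, not pooled), and no
pregnancy-episode inference (gestational age, episode linking) is
performed. Wald p-values from penalized fits are approximate near
separation. The redaction rule masks by count only; it is a
de-identification convention, not a variance guarantee.
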