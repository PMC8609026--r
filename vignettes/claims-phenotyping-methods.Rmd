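---
title: "Claims-based phenotyping of genetic-disease indicators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Claims-based phenotyping of genetic-disease indicators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoclaims)
library(dplyr)
```

## The problem

Many genetic diseases present with nonspecific clinical features, and most
patients who would plausibly benefit from genetic testing never receive it.
Administrative healthcare claims — diagnosis codes (ICD-9/10), procedure
codes (CPT/HCPCS), facility revenue codes, enrollment spans and allowed
amounts — are the one population-scale record of these patients' care.
`phenoclaims` implements a computational-phenotyping pipeline over such
claims: it identifies pediatric and critically-ill-newborn patients whose
coded presentations suggest an undiagnosed genetic disease, pairs them with
matched controls, and quantifies genetic-test utilization, intensive-care
use, diagnostic-category transitions, and cost trajectories.

Real claims extracts are proprietary, so the package also ships a synthetic
claims generator with *planted* ground truth. The generator is first-class,
tested code: every downstream algorithm is validated by recovering what the
generator planted.

All dates are **derived dates** — integer days since birth (day 0 = date of
birth) — the de-identified representation used by commercial claims
databases.

## The code catalog

Everything downstream is driven by a curated code catalog
(`load_catalog()`), an external delimited file with three kinds of entries:

* **Diagnosis codes**, each assigned a tier encoding the likelihood that
  the coded presentation has a genetic etiology: `possible` (roughly
  10–30%), `probable` (above 30%), or `definite` (the code names a genetic
  disease). Entries carry an `easy_to_diagnose` flag (conditions with
  established targeted diagnostics, which are excluded from cohort entry),
  congenital-anomaly and multiple-anomaly flags, intellectual-disability /
  developmental-delay / epilepsy flags, an organ-system label, and an
  age-of-presentation window in days. The window encodes that a feature can
  be suggestive in a newborn but multifactorial in an adolescent; a code
  outside its window simply does not classify.
* **Procedure codes** split into `genetic_test` versus `other_workup`.
* **Revenue codes** identifying NICU or PICU room and board.

Codes match exactly after normalization (uppercase, periods stripped).
Range expansion, if needed, belongs in the catalog-building step, not the
matcher — exact matching keeps every classification auditable. The package
bundles a ~40-code synthetic demonstration catalog
(`demo_catalog_path()`) spanning every tier, flag and category; it is not
any study's curated list, whose content (thousands of codes) is data, not
schema.

Organ-system labels are free vocabulary supplied by the catalog. The
multiple-anomaly rule needs only *distinctness* of systems, so any
partition the curator prefers (ICD chapters are a reasonable default)
works.

## Cohort definitions and the index algorithm

Three nested cohorts are built per patient (`assign_cohorts()`):

* **Broad** — any possible/probable/definite diagnosis code (excluding
  easy-to-diagnose codes) *or* any curated CPT/HCPCS code.
* **MCA/ID/DD/E** — diagnosis codes for multiple congenital anomalies
  (either a multiple-anomaly-specific code or single-anomaly codes in two
  or more distinct organ systems), moderate/severe intellectual
  disability, developmental delay, or epilepsy/seizures.
* **Conservative** — a possible- or probable-tier diagnosis as the index
  code plus at least one genetic-test procedure code at any time; a
  definite-tier index code excludes the patient (their disease is already
  named).

Each cohort has its **own index event**: the service day of the first
qualifying code for that definition (diagnosis-only for Conservative and
MCA/ID/DD/E; diagnosis or procedure for Broad). Within a day, the index
category follows the hierarchy definite > probable > possible; diagnosis
codes take precedence over procedure codes, and residual ties break on the
lexicographically smallest code — the tie-breaks beyond the tier hierarchy
are this package's own determinism choices.

Eligibility requires **continuous enrollment** for the 180 days before the
index date, reduced to the child's age when younger than 180 days:
`L = min(180, index_day)`, and one enrollment span must cover
`[index_day - L, index_day]`. "Continuous" is read strictly — zero gap
days — with a configurable `enrollment_bridge` (default 0) for analysts
who want to bridge administrative hiccups.

Because each cohort indexes on its own date, a patient could in principle
pass the (later, longer-lookback) subcohort enrollment check while failing
the Broad one. The two subcohorts are documented as subsets of the Broad
cohort, so membership in MCA/ID/DD/E or Conservative additionally requires
Broad membership; this keeps the subset invariant exact on every dataset.

Cases are split into populations on the Broad index date: **critically-ill
newborns** are at most 28 days old at index with at least one NICU
revenue-coded claim at any time during the observation period (the union
of enrollment spans — events outside enrollment are unobservable in
claims); other cases at most 18 years old (`index_day <= 6570`) are
**pediatric**; older patients are excluded. **Controls** have no catalog
diagnosis or procedure code ever — evaluated at any age, the strictest
reading — and index at the start of their first enrollment span, with no
lookback requirement (it is definitionally satisfied there). Patients with
catalog codes that never yield an eligible index are `excluded` with a
reason code, and the attrition report accounts for every patient:
cases + controls + excluded = input n.

## Matching

Controls are paired to each cohort by **coarsened exact matching with
k-to-k pruning**. Covariates (race/ethnicity, sex, census division, birth
year, household children, and — for the pediatric population — age at
index coarsened into 0–1, 1–5, 5–12 and 12–19 year bins) are collapsed to
a joint signature; within each signature stratum,
`min(n_cases, n_controls)` one-to-one pairs are drawn by seeded uniform
selection without replacement, and unmatched cases are pruned. Because
strata are exact on the coarsened covariates, any within-stratum pairing
is balance-equivalent; random selection avoids input-order artifacts. The
age bins and the random within-stratum rule are package choices — the
binning is configurable through `coarsening_scheme()`.

Balance is measured by the **L1 multivariate imbalance**: half the summed
absolute difference of case and control relative frequencies over the
joint signature bins, 0 meaning perfectly matched and 1 completely
unmatched. Post-match L1 over retained units is exactly 0 by construction
of exact within-stratum pairing.

## Outcomes

* **Genetic-test utilization** — a test is a claim on/after index bearing
  a genetic-test code, counted as distinct (day, code) pairs; count and
  days-to-first summaries are computed among tested patients.
* **ICU utilization** — a NICU/PICU stay is at least one revenue-coded
  claim during enrollment. NICU length of stay counts billed days, with
  runs split when more than one un-billed day intervenes (room-and-board
  codes are daily; the gap threshold is configurable); LOS statistics use
  each patient's total billed days among those with any stay.
* **Diagnostic transitions** — a patient transitions X→Y when their index
  category is X and a later claim's *first-listed* diagnosis code
  classifies (at that day's age) into a strictly more specific category Y
  (possible < probable < definite; procedure-code indexes transition only
  to definite). "Primary diagnosis = first-listed" is the standard claims
  convention; the denominators are full cohorts, so the combined
  possible-or-probable→definite fraction is identically the sum of its two
  component rows.
* **30-day cost accrual** — bin *k* covers days
  `[index + 30k, index + 30(k+1))`; a patient enters a bin's denominator
  only when enrolled for the entire bin (full-bin requirement avoids
  partial-exposure bias; proration is available as an option). Total,
  inpatient and outpatient series are reported, pharmacy entering the
  total only.
* **Demographic comparisons** — Welch's unequal-variance two-sided t-test
  per variable, with proportions compared as 0/1 indicators.

Percentages in reports are rendered to one decimal, half rounded away from
zero, matching the convention of printed claims tables.

## The synthetic generator

`generate_population()` plants per-patient labels — `none`, `broad_only`,
`mca_id_dd_e`, `conservative` — and emits claims sufficient (and only
sufficient) for the corresponding cohort criteria. Unlabeled patients
receive only codes absent from the catalog, so exact label recovery is a
meaningful end-to-end test. Ground truth is written as a separate table
the pipeline never reads: the acceptance surface is recovery, not leakage.

Default parameters are chosen to emulate the published population
structure of a large US pediatric claims cohort: label prevalences of
8.4% / 0.8% / 0.2% (Broad total ≈ 9.4%), a small critically-ill-newborn
slice (2.5% of labeled patients, indexed at 0–28 days with NICU
room-and-board claims whose geometric stay lengths average ~24 days),
log-normal claim costs by setting, and an early post-index cost elevation
for labeled patients (multiplier 6, decaying as `exp(-bin/3)` over 12
months) that reproduces the elevated-then-steady-state cost-curve shape.
Genetic tests are planted only for conservative-labeled patients: adding a
test to a patient with a possible/probable index would make them
Conservative and silently falsify the planted label. Enrollment gaps are
planted in a configurable fraction of labeled patients, placed inside the
pre-index lookback window, so the continuous-enrollment filter has a
non-trivial, fully attributable kill set.

What the generator does **not** emulate: claims adjudication (denials,
coordination of benefits), pharmacy NDC detail, coding errors and
miscoding, ICD-9→10 transition dynamics, informative disenrollment, or any
distributional estimate of a real database. Passing tests therefore
demonstrate algorithmic correctness on well-formed claims, not robustness
to real-world coding noise.

## Numerical and degenerate-input choices

* Coarsening bins are half-open `[a, b)`; values outside the outermost
  edges clamp to the boundary bin with a warning.
* Same-day index ties break deterministically (hierarchy, then kind, then
  code order); matching randomness is seeded per stage from one root seed,
  so whole-pipeline reruns are byte-identical.
* Zero-variance t-tests are reported `NA` (not-applicable) when both
  groups are constant, and groups of size one are an error.
* Empty cohorts, empty claim tables and empty datasets round-trip and
  summarise without error; unknown codes never raise.
* ICD-9 and ICD-10 forms of one concept are independent catalog entries;
  no cross-walking or per-patient deduplication across the coding
  transition is attempted.

## Problem sizes used in validation

The shipped validation suite exercises: exact planted-label recovery at
n = 10,000 patients; brute-force oracle equivalence on 1,000 randomized
small fixtures (≤ 12 patients each — 300 cohort-assignment, 400
matching/imbalance, 300 outcome fixtures); and cost-signal detection at
n = 4,000 with ~500 matched pairs. These sizes give exact set comparisons
and ≥3-standard-error separation for the planted cost signal while keeping
the whole suite fast to run routinely.

## Worked example

```{r example, eval = FALSE}
catalog <- load_catalog(demo_catalog_path())
dataset <- generate_population(
  generator_config(n_patients = 5000, seed = 1, gap_probability = 0),
  catalog)

assignments <- assign_cohorts(dataset, catalog)
attrition(assignments)

members <- cohort_members(assignments, "broad", "pediatric")
genetic_test_utilization(members, dataset, catalog)
diagnostic_transitions(members, dataset, catalog)

res <- run_pipeline(list(catalog = catalog, data = dataset, seed = 1))
glance(res$matches[["pediatric.broad"]])
autoplot(res$results[["pediatric.broad"]]$costs_cases)
```

## Known limitations

* Exact code matching means catalog completeness is the analyst's burden;
  there is no prefix/range grammar.
* The control definition is global (no qualifying code ever); the package
  does not support serving as control for one population while being a
  case in the other.
* Severity qualifiers ("moderate or severe" intellectual disability) are
  encoded in the catalog's flags, not computed from claims.
* Comorbidity odds-ratio reporting would require a comorbidity code list;
  the frame supports one but none is bundled.
* Survival analysis, propensity-score matching variants and
  cost-effectiveness modeling are out of scope.
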