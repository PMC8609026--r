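# phenoclaims

Claims-based computational phenotyping of pediatric and critically-ill
newborn patients with clinical indicators of genetic disease.

Most genetic diseases present through nonspecific clinical features, and
administrative healthcare claims — ICD-9/10 diagnosis codes, CPT/HCPCS
procedure codes, NICU/PICU revenue codes, enrollment spans, allowed
amounts — are the only population-scale record of how such patients are
worked up. `phenoclaims` turns a claims extract plus a curated code
catalog into analysis-ready cohorts and outcome tables:

* **Code catalog** — tiered diagnosis codes (`possible` ≈ 10–30% genetic
  etiology, `probable` > 30%, `definite` = a named genetic disease) with
  easy-to-diagnose flags and age-of-presentation windows; procedure codes
  categorized `genetic_test` vs `other_workup`; NICU/PICU revenue codes.
* **Cohorts** — per-patient index events (first qualifying code, with the
  within-day hierarchy definite > probable > possible), continuous
  enrollment with lookback `L = min(180, index_day)` days, and three
  nested definitions: *Broad* (any qualifying diagnosis or procedure
  code), *MCA/ID/DD/E* (multiple congenital anomalies — one
  multiple-anomaly code or single anomalies in ≥ 2 organ systems —
  intellectual disability, developmental delay, epilepsy/seizures), and
  *Conservative* (possible/probable index diagnosis plus ≥ 1 genetic
  test). Cases split into critically-ill newborns (index ≤ 28 days + NICU
  stay) and pediatric patients (≤ 18 years).
* **Matching** — coarsened exact matching with k-to-k (1:1) pruning on
  race/ethnicity, sex, census division, birth year, household children
  and (pediatric) age-at-index bins, with balance measured by the L1
  multivariate imbalance

  L1 = ½ · Σ_b | f_cases(b) − f_controls(b) |

  over joint coarsened-covariate bins b (0 = perfectly matched,
  1 = disjoint).
* **Outcomes** — genetic-test utilization (distinct day × code counts,
  days to first test), NICU/PICU utilization and length of stay, diagnostic
  transitions from less- to more-specific index categories via first-listed
  post-index diagnosis codes, 30-day cost accrual from the index date,
  and Welch-t demographic comparisons.
* **Synthetic claims generator** — plants ground-truth cohort labels,
  enrollment gaps, NICU confinements and an early post-index cost
  elevation, so the entire pipeline is testable without proprietary data.

Dates everywhere are *derived dates*: integer days since birth (day 0 =
birth), the de-identified representation used by commercial claims
databases.

## Worked example

```r
library(phenoclaims)

catalog <- load_catalog(demo_catalog_path())
dataset <- generate_population(
  generator_config(n_patients = 5000, seed = 1, gap_probability = 0),
  catalog)

assignments <- assign_cohorts(dataset, catalog)
attrition(assignments)
#> # A tibble: 20 × 3
#>   cohort      filter                 n_remaining
#> 1 broad       all_patients                  5000
#> 2 broad       qualifying_index               471
#> 3 broad       continuous_enrollment          471
#> 4 broad       cohort_members                 471
#> 5 broad       critically_ill_newborn          11
#> 6 broad       pediatric                      460
#> ...
```

471 of 5,000 synthetic patients carry a qualifying code; with complete
enrollment none are lost to the lookback filter, and the Broad cases split
into 11 critically-ill newborns and 460 pediatric patients.

```r
members <- cohort_members(assignments, "broad", "pediatric")
genetic_test_utilization(members, dataset, catalog)
#> # A tibble: 1 × 9
#>       n n_tested pct_tested mean_days_to_first_test tests_mean ...
#> 1   460        8        1.7                    115.       1.25
```

1.7% of the pediatric Broad cohort ever receives a genetic test — the
under-testing pattern the pipeline is designed to quantify.

```r
res <- run_pipeline(list(catalog = catalog, data = dataset, seed = 1))
res$matches[["pediatric.broad"]]
#> <match_result: coarsened exact matching, k-to-k>
#>   cases: 460  controls: 4529  pairs: 188  pruned cases: 272
#>   L1 imbalance: 0.9338 (pre) -> 0.0000 (post)

dplyr::filter(res$results[["pediatric.broad"]]$costs_cases,
              setting_group == "total") |> head(4)
#>     bin setting_group     n total_cost mean_cost
#> 1     0 total           188   1175176.     6251.
#> 2     1 total           188   1125943.     5989.
#> 3     2 total           188    883948.     4702.
#> 4     3 total           188    766674.     4078.
```

Exact within-stratum pairing drives the post-match L1 to 0; the matched
cases' mean 30-day costs start elevated (about $6,300 in the first bin
against a few hundred dollars for matched controls) and decline toward
steady state — the planted diagnostic-odyssey cost shape.
`autoplot(res$results[["pediatric.broad"]]$costs_cases)` draws the curve;
`tidy()` / `glance()` extract match pairs and summaries.

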