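test_that("index hierarchy: definite beats possible on the same day", {
  cat_ <- demo_cat()
  ds <- mk_ds(claims = clm("P1", 50, dx = c("Q24.9", "E70.9")))
  ie <- find_index_event(ds$claims, cat_, "broad")
  expect_equal(ie$index_day, 50)
  expect_equal(ie$index_category, "definite")
  expect_equal(ie$index_code, "E709")
})

test_that("broad cohort can index on a genetic-test procedure date", {
  cat_ <- demo_cat()
  ds <- mk_ds(claims = clm("P1", 90, px = "81415"))
  ie <- find_index_event(ds$claims, cat_, "broad")
  expect_equal(ie$index_day, 90)
  expect_equal(ie$index_category, "genetic_test")
  expect_equal(ie$index_code_kind, "genetic_test")
  # but conservative and MCA/ID/DD/E index only on diagnosis codes
  expect_equal(nrow(find_index_event(ds$claims, cat_, "conservative")), 0)
  expect_equal(nrow(find_index_event(ds$claims, cat_, "mca_id_dd_e")), 0)
})

test_that("easy-to-diagnose codes never qualify as index", {
  cat_ <- demo_cat()
  # E84.0 is definite but easy to diagnose
  ds <- mk_ds(claims = clm("P1", 30, dx = "E84.0"))
  expect_equal(nrow(find_index_event(ds$claims, cat_, "broad")), 0)
})

test_that("diagnosis beats procedure on the same day; ties break on smallest code", {
  cat_ <- demo_cat()
  ds <- mk_ds(claims = list(clm("P1", 10, dx = "Q24.9", px = "81415"),
                            clm("P2", 10, dx = c("Q64.9", "Q04.9"))))
  ie1 <- find_index_event(ds$claims[ds$claims$patient_id == "P1", ],
                          cat_, "broad")
  expect_equal(ie1$index_category, "possible")  # diagnosis preferred
  ie2 <- find_index_event(ds$claims[ds$claims$patient_id == "P2", ],
                          cat_, "broad")
  expect_equal(ie2$index_code, "Q049")  # lexicographically smallest
})

test_that("age windows are evaluated at the claim's service day", {
  cat_ <- demo_cat()
  # M41.9 qualifies only in the first 28 days of life
  ds_young <- mk_ds(claims = clm("P1", 10, dx = "M41.9"))
  ds_old <- mk_ds(claims = clm("P1", 3650, dx = "M41.9"))
  expect_equal(find_index_event(ds_young$claims, cat_, "broad")$index_day, 10)
  expect_equal(nrow(find_index_event(ds_old$claims, cat_, "broad")), 0)
})

test_that("continuous enrollment uses a lookback of min(180, index age)", {
  s <- span("P1", 0, 400)
  expect_true(check_continuous_enrollment(s, 200))   # L = 180, covered
  expect_true(check_continuous_enrollment(s, 100))   # reduced L = 100
  expect_false(check_continuous_enrollment(span("P1", 300, 900), 400))
  # exact boundary: enrollment begins exactly at index - L
  expect_true(check_continuous_enrollment(span("P1", 220, 900), 400))
  expect_false(check_continuous_enrollment(span("P1", 221, 900), 400))
  # a gap inside the window kills it unless bridged
  gappy <- dplyr::bind_rows(span("P1", 0, 250), span("P1", 260, 900))
  expect_false(check_continuous_enrollment(gappy, 400))
  expect_true(check_continuous_enrollment(gappy, 400, bridge = 10))
  expect_error(check_continuous_enrollment(s, -5))
})

test_that("the MCA rule needs two organ systems or one multiple-anomaly code", {
  cat_ <- demo_cat()
  # cardiac + CNS anomalies: two systems
  two <- mk_ds(claims = clm("P1", 10, dx = c("Q24.9", "Q04.9")))
  expect_true(has_mca(two$claims, cat_))
  # two cardiac anomaly codes: one system
  one <- mk_ds(claims = clm("P1", 10, dx = c("Q24.9", "746.9")))
  one$claims$dx_system <- "ICD10"  # only Q24.9 resolves; 746.9 is ICD9
  expect_false(has_mca(one$claims, cat_))
  # a single multiple-anomaly-specific code suffices
  mca1 <- mk_ds(claims = clm("P1", 10, dx = "Q89.7"))
  expect_true(has_mca(mca1$claims, cat_))
  expect_false(has_mca(mk_ds(claims = clm("P1", 1, dx = "NC1"))$claims, cat_))
})

test_that("conservative membership needs a possible/probable index plus a genetic test", {
  cat_ <- demo_cat()
  # possible index + later genetic test -> conservative (and broad)
  ds1 <- mk_ds(claims = list(clm("P1", 100, dx = "G93.9"),
                             clm("P1", 400, px = "81228")))
  a1 <- assign_cohorts(ds1, cat_)
  expect_true(a1$in_broad); expect_true(a1$in_conservative)
  # definite index excludes from conservative even with a genetic test
  ds2 <- mk_ds(claims = list(clm("P2", 100, dx = "E70.9"),
                             clm("P2", 400, px = "81228")))
  a2 <- assign_cohorts(ds2, cat_)
  expect_true(a2$in_broad); expect_false(a2$in_conservative)
  # possible index without any genetic test is broad only
  ds3 <- mk_ds(claims = clm("P3", 100, dx = "G93.9"))
  a3 <- assign_cohorts(ds3, cat_)
  expect_true(a3$in_broad); expect_false(a3$in_conservative)
})

test_that("patients with no catalog codes are controls indexed at first enrollment", {
  cat_ <- demo_cat()
  ds <- mk_ds(claims = clm("P1", 10, dx = c("NC1", "JUNKY")),
              spans = span("P1", 5, 600))
  a <- assign_cohorts(ds, cat_)
  expect_equal(a$population, "control")
  expect_false(any(a$in_broad, a$in_mca_id_dd_e, a$in_conservative))
  expect_equal(a$index_day, 5)
})

test_that("population split: NICU stay at any observed time makes a newborn critically ill", {
  cat_ <- demo_cat()
  # index at day 10, NICU claim much later at day 400
  ds1 <- mk_ds(claims = list(clm("P1", 10, dx = "Q24.9"),
                             clm("P1", 400, rv = "0173",
                                 setting = "inpatient")))
  expect_equal(assign_cohorts(ds1, cat_)$population, "critically_ill_newborn")
  # same index, no NICU claim ever -> pediatric
  ds2 <- mk_ds(claims = clm("P1", 10, dx = "Q24.9"))
  expect_equal(assign_cohorts(ds2, cat_)$population, "pediatric")
  # index at ~8 years -> pediatric regardless of NICU
  ds3 <- mk_ds(claims = clm("P1", 3000, dx = "Q24.9"))
  expect_equal(assign_cohorts(ds3, cat_)$population, "pediatric")
  # NICU claim outside any enrollment span is not observed
  ds4 <- mk_ds(claims = list(clm("P1", 10, dx = "Q24.9"),
                             clm("P1", 900, rv = "0173")),
              spans = span("P1", 0, 500))
  expect_equal(assign_cohorts(ds4, cat_)$population, "pediatric")
  # index after the 18th birthday -> excluded
  ds5 <- mk_ds(claims = clm("P1", 7000, dx = "Q24.9"))
  a5 <- assign_cohorts(ds5, cat_)
  expect_equal(a5$population, "excluded")
  expect_equal(a5$exclusion_reason, "age_over_18")
  expect_false(a5$in_broad)
})

test_that("every patient lands in exactly one population and subsets hold", {
  cfg <- generator_config(n_patients = 600, seed = 23, gap_probability = 0.3,
                          prevalence = c(broad_only = 0.2, mca_id_dd_e = 0.1,
                                         conservative = 0.05))
  ds <- generate_population(cfg, demo_cat())
  a <- assign_cohorts(ds, demo_cat())
  expect_true(all(a$population %in% c("critically_ill_newborn", "pediatric",
                                      "control", "excluded")))
  expect_equal(nrow(a), nrow(ds$patients))
  # subset property
  expect_true(all(a$in_broad[a$in_mca_id_dd_e]))
  expect_true(all(a$in_broad[a$in_conservative]))
  # controls carry no flags
  ctrl <- a$population == "control"
  expect_false(any(a$in_broad[ctrl] | a$in_mca_id_dd_e[ctrl] |
                     a$in_conservative[ctrl]))
  # attrition counts are non-increasing along each chain
  att <- attrition(a)
  for (ch in c("broad", "mca_id_dd_e", "conservative")) {
    chain <- att$n_remaining[att$cohort == ch][1:4]
    expect_true(all(diff(chain) <= 0))
  }
  # exclusions sum: excluded + cases + controls = n
  n_cases <- sum(a$population %in% c("critically_ill_newborn", "pediatric"))
  expect_equal(n_cases + sum(ctrl) + sum(a$population == "excluded"),
               nrow(a))
})

test_that("planted enrollment gaps are the only source of exclusions", {
  cfg <- generator_config(n_patients = 1500, seed = 77,
                          gap_probability = 0.4)
  ds <- generate_population(cfg, demo_cat())
  a <- assign_cohorts(ds, demo_cat())
  gt <- ds$ground_truth
  lost <- gt$label != "none" & !a$in_broad
  expect_true(all(gt$planted_gap[lost]))
  expect_true(all(a$exclusion_reason[lost] == "continuous_enrollment"))
  # and with a large enough bridge the gap patients come back
  a2 <- assign_cohorts(ds, demo_cat(), enrollment_bridge = 10000)
  expect_equal(a2$in_broad, gt$label != "none")
})

test_that("split_populations is re-runnable on assignment output", {
  cfg <- generator_config(n_patients = 300, seed = 55, gap_probability = 0.2)
  ds <- generate_population(cfg, demo_cat())
  a <- assign_cohorts(ds, demo_cat())
  again <- split_populations(a, ds, demo_cat())
  expect_equal(again$population, a$population)
  expect_equal(again$exclusion_reason, a$exclusion_reason)
  expect_equal(again$index_day, a$index_day)
})

test_that("cohort assignment agrees with the brute-force oracle on random fixtures", {
  cat_ <- demo_cat()
  for (seed in 1:40) {
    ds <- random_fixture(seed)
    got <- assign_cohorts(ds, cat_)
    want <- oracle_assign(ds, cat_)
    want <- want[match(got$patient_id, want$patient_id), ]
    expect_equal(got$in_broad, want$in_broad, info = paste("seed", seed))
    expect_equal(got$in_mca_id_dd_e, want$in_mca_id_dd_e,
                 info = paste("seed", seed))
    expect_equal(got$in_conservative, want$in_conservative,
                 info = paste("seed", seed))
    expect_equal(got$population, want$population, info = paste("seed", seed))
    cases <- got$in_broad
    expect_equal(got$broad_index_day[cases], want$broad_index_day[cases],
                 info = paste("seed", seed))
    expect_equal(got$broad_index_category[cases],
                 want$broad_index_category[cases],
                 info = paste("seed", seed))
  }
})
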