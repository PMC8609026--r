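cohort_row <- function(id, index_day, index_category = "possible") {
  tibble::tibble(patient_id = id, index_day = index_day,
                 index_category = index_category)
}

test_that("genetic tests are counted as distinct day-code pairs after index", {
  cat_ <- demo_cat()
  ds <- mk_ds(claims = list(
    clm("P1", 200, px = "81415"),
    clm("P1", 250, px = "81228"),
    clm("P1", 250, px = "81228"),   # duplicate same day+code: one test
    clm("P1", 50, px = "81415"),    # pre-index: ignored
    clm("P2", 10, dx = "NC1")))
  u <- genetic_test_utilization(cohort_row(c("P1", "P2"), 100), ds, cat_)
  expect_equal(u$n, 2)
  expect_equal(u$n_tested, 1)
  expect_equal(u$pct_tested, 50)
  expect_equal(u$tests_mean, 2)     # (250, 81228) and (200, 81415)
  expect_equal(u$mean_days_to_first_test, 100)
  expect_equal(u$tests_min, 2); expect_equal(u$tests_max, 2)
})

test_that("fraction tested follows plain cohort arithmetic", {
  cat_ <- demo_cat()
  claims <- c(lapply(sprintf("T%02d", 1:3),
                     function(id) clm(id, 120, px = "81415")),
              lapply(sprintf("U%02d", 1:17),
                     function(id) clm(id, 120, dx = "NC1")))
  ds <- mk_ds(claims = claims)
  u <- genetic_test_utilization(
    cohort_row(c(sprintf("T%02d", 1:3), sprintf("U%02d", 1:17)), 100),
    ds, cat_)
  expect_equal(u$pct_tested, 15)   # 3 / 20
})

test_that("NICU stays split on gaps of more than one day; LOS counts billed days", {
  cat_ <- demo_cat()
  # contiguous 0..12 -> one stay, 13 days
  ds1 <- mk_ds(claims = lapply(0:12, function(d)
    clm("P1", d, rv = "0173", setting = "inpatient")))
  st1 <- nicu_stays(ds1, cat_)
  expect_equal(nrow(st1), 1)
  expect_equal(st1$days, 13)
  # {0..5} and {40..42} -> two stays, 9 total days
  ds2 <- mk_ds(claims = lapply(c(0:5, 40:42), function(d)
    clm("P1", d, rv = "0173", setting = "inpatient")))
  st2 <- nicu_stays(ds2, cat_)
  expect_equal(nrow(st2), 2)
  expect_equal(sum(st2$days), 9)
  u <- icu_utilization(cohort_row("P1", 0), ds2, cat_)
  expect_equal(u$pct_nicu, 100)
  expect_equal(u$nicu_days_mean, 9)
  # a skipped billing day within a stay does not split it
  ds3 <- mk_ds(claims = lapply(c(0, 2, 4), function(d)
    clm("P1", d, rv = "0174", setting = "inpatient")))
  expect_equal(nrow(nicu_stays(ds3, cat_)), 1)
  expect_equal(nicu_stays(ds3, cat_)$days, 3)
})

test_that("patients without revenue-coded claims stay out of the LOS stats", {
  cat_ <- demo_cat()
  ds <- mk_ds(claims = list(clm("P1", 3, rv = "0173"),
                            clm("P2", 5, dx = "NC1"),
                            clm("P3", 9, rv = "0202")))
  u <- icu_utilization(cohort_row(c("P1", "P2", "P3"), 0), ds, cat_)
  expect_equal(u$pct_nicu, pct(1, 3))
  expect_equal(u$pct_picu, pct(1, 3))
  expect_equal(u$nicu_days_mean, 1)  # only P1 contributes
})

test_that("diagnostic transitions follow the first-listed-code counting rule", {
  cat_ <- demo_cat()
  # index possible at day 0; probable primary at 30; definite primary at 60
  ds <- mk_ds(claims = list(
    clm("P1", 0, dx = "G93.9"),
    clm("P1", 30, dx = c("E88.9", "NC1")),   # probable first-listed
    clm("P1", 60, dx = c("E70.9", "NC1"))))  # definite first-listed
  tr <- diagnostic_transitions(cohort_row("P1", 0, "possible"), ds, cat_)
  get <- function(t) tr$n_transitioned[tr$transition == t]
  expect_equal(get("possible_to_probable"), 1)
  expect_equal(get("possible_to_definite"), 1)
  expect_equal(get("probable_to_definite"), 0)
  expect_equal(get("possible_or_probable_to_definite"), 1)
  # a definite code in second position is not a primary diagnosis
  ds2 <- mk_ds(claims = list(clm("P2", 0, dx = "G93.9"),
                             clm("P2", 40, dx = c("NC1", "E70.9"))))
  tr2 <- diagnostic_transitions(cohort_row("P2", 0, "possible"), ds2, cat_)
  expect_equal(sum(tr2$n_transitioned), 0)
  # a definite-indexed patient feeds no transition numerator
  ds3 <- mk_ds(claims = list(clm("P3", 0, dx = "E70.9"),
                             clm("P3", 40, dx = "E75.23")))
  tr3 <- diagnostic_transitions(cohort_row("P3", 0, "definite"), ds3, cat_)
  expect_equal(sum(tr3$n_transitioned), 0)
})

test_that("the combined transition fraction equals the sum of its components", {
  cat_ <- demo_cat()
  for (seed in c(3, 9, 27)) {
    ds <- generate_population(
      generator_config(n_patients = 400, seed = seed, gap_probability = 0,
                       transition_probability = 0.5), demo_cat())
    a <- assign_cohorts(ds, cat_)
    m <- cohort_members(a, "broad")
    tr <- diagnostic_transitions(m, ds, cat_)
    frac <- function(t) tr$fraction_pct[tr$transition == t]
    expect_equal(frac("possible_or_probable_to_definite"),
                 transition_combined(frac("possible_to_definite"),
                                     frac("probable_to_definite")))
  }
})

test_that("cost bins start at the index date and need full-bin enrollment", {
  # single claim of 100 at index+35 with full enrollment
  ds <- mk_ds(claims = list(clm("P1", 135, dx = "NC1", amount = 100)),
              spans = span("P1", 0, 2000))
  cs <- cost_accrual_30d(cohort_row("P1", 100), ds, n_bins = 3)
  tot <- dplyr::filter(cs, setting_group == "total")
  expect_equal(tot$mean_cost, c(0, 100, 0))
  expect_equal(tot$n, c(1, 1, 1))
  # disenrollment at index+45 removes bins 1+ from the denominator
  ds2 <- mk_ds(claims = list(clm("P1", 110, dx = "NC1", amount = 50)),
               spans = span("P1", 0, 145))
  cs2 <- cost_accrual_30d(cohort_row("P1", 100), ds2, n_bins = 3)
  tot2 <- dplyr::filter(cs2, setting_group == "total")
  expect_equal(tot2$n, c(1, 0, 0))
  expect_equal(tot2$mean_cost[1], 50)
  expect_true(is.na(tot2$mean_cost[2]))
  # no claims at all: means are 0 with full denominators
  ds3 <- mk_ds(claims = clm("P9", 1, dx = "NC1"), spans = span("P3", 0, 2000),
               ids = c("P3", "P9"))
  cs3 <- cost_accrual_30d(cohort_row("P3", 100), ds3, n_bins = 2)
  tot3 <- dplyr::filter(cs3, setting_group == "total")
  expect_equal(tot3$mean_cost, c(0, 0))
  expect_equal(tot3$n, c(1, 1))
})

test_that("pharmacy claims enter the total series only", {
  ds <- mk_ds(claims = list(
    clm("P1", 105, dx = "NC1", amount = 10, setting = "inpatient"),
    clm("P1", 106, dx = "NC1", amount = 20, setting = "outpatient"),
    clm("P1", 107, dx = "NC1", amount = 40, setting = "pharmacy")),
    spans = span("P1", 0, 2000))
  cs <- cost_accrual_30d(cohort_row("P1", 100), ds, n_bins = 1)
  expect_equal(cs$mean_cost[cs$setting_group == "total"], 70)
  expect_equal(cs$mean_cost[cs$setting_group == "inpatient"], 10)
  expect_equal(cs$mean_cost[cs$setting_group == "outpatient"], 20)
})

test_that("proration replaces the full-bin rule with fractional person-time", {
  ds <- mk_ds(claims = list(clm("P1", 110, dx = "NC1", amount = 60)),
              spans = span("P1", 0, 114))  # enrolled 15/30 days of bin 0
  cs <- cost_accrual_30d(cohort_row("P1", 100), ds, n_bins = 1,
                         prorate = TRUE)
  tot <- dplyr::filter(cs, setting_group == "total")
  expect_equal(tot$n, 0.5)
  expect_equal(tot$mean_cost, 120)  # 60 / 0.5 person-bins
})

test_that("Welch t-test matches the closed form and flags degenerate input", {
  x <- tibble::tibble(v = c(1, 2, 3))
  y <- tibble::tibble(v = c(11, 12, 13))
  res <- compare_demographics(x, y, "v")
  # closed form: diff -10, se = sqrt(1/3 + 1/3)
  expect_equal(res$t, -10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_lt(res$p_value, 0.01)
  # identical groups: t = 0
  res0 <- compare_demographics(x, x, "v")
  expect_equal(res0$t, 0)
  # logical variables are compared as 0/1 indicators
  resb <- compare_demographics(tibble::tibble(b = c(TRUE, TRUE, FALSE)),
                               tibble::tibble(b = c(FALSE, FALSE, TRUE)),
                               "b")
  expect_equal(resb$mean_cases, 2 / 3)
  # n = 1 errors; double zero variance is reported not-applicable
  expect_error(compare_demographics(tibble::tibble(v = 1), y, "v"), "n >= 2")
  resz <- compare_demographics(tibble::tibble(v = c(1, 1)),
                               tibble::tibble(v = c(1, 1)), "v")
  expect_true(is.na(resz$p_value))
})

test_that("outcome operations agree with brute force on random fixtures", {
  cat_ <- demo_cat()
  for (seed in 101:130) {
    ds <- random_fixture(seed)
    a <- assign_cohorts(ds, cat_)
    m <- cohort_members(a, "broad")
    if (nrow(m) == 0) {
      m <- cohort_row(ds$patients$patient_id,
                      rep(0, nrow(ds$patients)))
    }
    # genetic testing
    u <- genetic_test_utilization(m, ds, cat_)
    o <- oracle_genetic_tests(m, ds, cat_)
    expect_equal(u$n_tested, sum(o$n_tests > 0), info = paste("seed", seed))
    if (u$n_tested > 0) {
      expect_equal(u$tests_mean, mean(o$n_tests[o$n_tests > 0]),
                   info = paste("seed", seed))
      expect_equal(u$mean_days_to_first_test,
                   mean(o$days_to_first, na.rm = TRUE),
                   info = paste("seed", seed))
    }
    # ICU utilization
    iu <- icu_utilization(m, ds, cat_)
    on <- oracle_nicu_days(m, ds, cat_)
    expect_equal(iu$pct_nicu, pct(sum(on$nicu_days > 0), nrow(m)),
                 info = paste("seed", seed))
    expect_equal(iu$pct_picu, pct(sum(on$picu), nrow(m)),
                 info = paste("seed", seed))
    if (any(on$nicu_days > 0)) {
      expect_equal(iu$nicu_days_mean, mean(on$nicu_days[on$nicu_days > 0]),
                   info = paste("seed", seed))
    }
    # transitions
    if (all(!is.na(m$index_category))) {
      tr <- diagnostic_transitions(m, ds, cat_)
      ot <- oracle_transitions(m, ds, cat_)
      for (t in names(ot)) {
        expect_equal(tr$n_transitioned[tr$transition == t], unname(ot[t]),
                     info = paste("seed", seed, t))
      }
    }
    # cost bins
    cs <- cost_accrual_30d(m, ds, n_bins = 4)
    oc <- oracle_cost_bins(m, ds, 4)
    for (grp in c("total", "inpatient", "outpatient")) {
      g <- dplyr::filter(cs, setting_group == grp) |> dplyr::arrange(bin)
      expect_equal(g$n, oc$n, info = paste("seed", seed, grp))
      expect_equal(g$total_cost, oc[[grp]], info = paste("seed", seed, grp))
    }
  }
})

test_that("the conservative cohort is 100% genetically tested by construction", {
  cat_ <- demo_cat()
  for (seed in c(2, 14)) {
    ds <- generate_population(
      generator_config(n_patients = 1500, seed = seed, gap_probability = 0.2,
                       prevalence = c(broad_only = 0.1, mca_id_dd_e = 0.03,
                                      conservative = 0.05)), cat_)
    a <- assign_cohorts(ds, cat_)
    m <- cohort_members(a, "conservative")
    expect_gt(nrow(m), 0)
    expect_equal(genetic_test_utilization(m, ds, cat_)$pct_tested, 100,
                 info = paste("seed", seed))
  }
})
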