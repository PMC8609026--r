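five_num <- function(x, prefix) {
  out <- if (length(x) == 0) {
    tibble(mean = NA_real_, sd = NA_real_, median = NA_real_,
           min = NA_real_, max = NA_real_)
  } else {
    tibble(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
           min = min(x), max = max(x))
  }
  setNames(out, paste0(prefix, "_", names(out)))
}

#' Genetic-test utilization for a cohort
#'
#' A genetic test is a claim on or after the patient's index date carrying a
#' genetic-test CPT/HCPCS code; tests are counted as distinct
#' (service day, code) pairs per patient. Days to first test is first test
#' day minus index day. Count and timing summaries are computed among
#' tested patients only.
#'
#' @param cohort Tibble with `patient_id` and `index_day` (e.g. from
#'   [cohort_members()]).
#' @param dataset A `claims_dataset`.
#' @param catalog A `code_catalog`.
#' @return One-row tibble: `n`, `n_tested`, `pct_tested`,
#'   `mean_days_to_first_test`, and mean/sd/median/min/max of the number of
#'   tests among tested patients.
#' @export
genetic_test_utilization <- function(cohort, dataset, catalog) {
  cohort <- as_tibble(cohort)
  tests <- px_matches(dataset$claims, catalog) |>
    filter(.data$category == "genetic_test") |>
    inner_join(cohort |> select("patient_id", "index_day"),
               by = "patient_id") |>
    filter(.data$service_day >= .data$index_day) |>
    distinct(.data$patient_id, .data$service_day, .data$code,
             .data$index_day)
  per_pt <- if (nrow(tests) == 0) {
    tibble(patient_id = character(), n_tests = integer(),
           days_to_first = numeric())
  } else {
    tests |>
      group_by(.data$patient_id) |>
      summarise(n_tests = n(),
                days_to_first = min(.data$service_day) -
                  first(.data$index_day),
                .groups = "drop")
  }
  n <- nrow(cohort)
  dplyr::bind_cols(
    tibble(n = n, n_tested = nrow(per_pt),
           pct_tested = pct(nrow(per_pt), n),
           mean_days_to_first_test = if (nrow(per_pt) > 0)
             mean(per_pt$days_to_first) else NA_real_),
    five_num(per_pt$n_tests, "tests")
  )
}

#' NICU stay runs for every patient in a dataset
#'
#' A stay is a maximal run of NICU revenue-coded service days (observed
#' during enrollment) in which consecutive billed days are at most
#' `gap + 1` days apart; room-and-board codes are daily, so the default
#' `gap = 1` splits runs separated by more than one un-billed day.
#'
#' @param dataset A `claims_dataset`.
#' @param catalog A `code_catalog`.
#' @param gap Maximum un-billed gap (days) bridged within one stay.
#' @return Tibble: `patient_id`, `stay`, `start_day`, `end_day`, `days`
#'   (distinct billed days in the run).
#' @export
nicu_stays <- function(dataset, catalog, gap = 1) {
  d <- icu_days(dataset, catalog) |>
    filter(.data$unit == "NICU")
  if (nrow(d) == 0) {
    return(tibble(patient_id = character(), stay = integer(),
                  start_day = numeric(), end_day = numeric(),
                  days = integer()))
  }
  d |>
    group_by(.data$patient_id) |>
    arrange(.data$service_day, .by_group = TRUE) |>
    mutate(stay = cumsum(c(1, diff(.data$service_day) > gap + 1))) |>
    group_by(.data$patient_id, .data$stay) |>
    summarise(start_day = min(.data$service_day),
              end_day = max(.data$service_day),
              days = dplyr::n_distinct(.data$service_day),
              .groups = "drop")
}

#' Intensive-care utilization for a cohort
#'
#' NICU and PICU stays are identified through room-and-board revenue codes
#' on claims during enrollment. NICU length of stay is each patient's total
#' billed NICU days (see [nicu_stays()] for stay splitting), summarised
#' among patients with at least one stay.
#'
#' @inheritParams genetic_test_utilization
#' @param gap Stay-splitting gap passed to [nicu_stays()].
#' @return One-row tibble: `n`, `pct_nicu`, `pct_picu`, and
#'   mean/sd/median/min/max NICU days among those with a stay.
#' @export
icu_utilization <- function(cohort, dataset, catalog, gap = 1) {
  cohort <- as_tibble(cohort)
  d <- icu_days(dataset, catalog) |>
    semi_join(cohort, by = "patient_id")
  nicu_pts <- unique(d$patient_id[d$unit == "NICU"])
  picu_pts <- unique(d$patient_id[d$unit == "PICU"])
  los <- d |>
    filter(.data$unit == "NICU") |>
    group_by(.data$patient_id) |>
    summarise(days = dplyr::n_distinct(.data$service_day), .groups = "drop")
  n <- nrow(cohort)
  dplyr::bind_cols(
    tibble(n = n,
           pct_nicu = pct(length(nicu_pts), n),
           pct_picu = pct(length(picu_pts), n)),
    five_num(los$days, "nicu_days")
  )
}

transition_levels <- c("possible_to_probable", "possible_to_definite",
                       "probable_to_definite", "genetic_test_to_definite",
                       "other_cpt_hcpcs_to_definite",
                       "possible_or_probable_to_definite")

#' Diagnostic-category transitions for a cohort
#'
#' A patient counts toward transition X→Y when their index category is X
#' and some post-index claim's first-listed (primary) diagnosis code
#' classifies — at that day's age — into a strictly more specific category
#' Y (ordering possible < probable < definite; procedure-code index
#' categories transition only to definite). Denominators are the full
#' cohort, and a patient can count toward several rows (e.g. both
#' possible→probable and possible→definite). The combined
#' possible-or-probable→definite fraction is the sum of its two component
#' fractions; see [transition_combined()].
#'
#' @param cohort Tibble with `patient_id`, `index_day` and `index_category`.
#' @param dataset A `claims_dataset`.
#' @param catalog A `code_catalog`.
#' @return Tibble with `transition`, `n_transitioned`, `fraction_pct`
#'   (unrounded percent of the full cohort).
#' @export
diagnostic_transitions <- function(cohort, dataset, catalog) {
  cohort <- as_tibble(cohort)
  n <- nrow(cohort)
  primary <- dx_events(dataset$claims, catalog) |>
    filter(.data$position == 1) |>
    inner_join(cohort |> select("patient_id", "index_day", "index_category"),
               by = "patient_id") |>
    filter(.data$service_day > .data$index_day)
  reached <- primary |>
    distinct(.data$patient_id, .data$index_category, .data$tier)
  count_tr <- function(from, to) {
    sum(reached$index_category == from & reached$tier == to)
  }
  counts <- c(
    possible_to_probable = count_tr("possible", "probable"),
    possible_to_definite = count_tr("possible", "definite"),
    probable_to_definite = count_tr("probable", "definite"),
    genetic_test_to_definite = count_tr("genetic_test", "definite"),
    other_cpt_hcpcs_to_definite = count_tr("other_cpt_hcpcs", "definite")
  )
  fr <- if (n > 0) 100 * counts / n else rep(NA_real_, length(counts))
  tibble(
    transition = transition_levels,
    n_transitioned = c(unname(counts),
                       unname(counts["possible_to_definite"] +
                                counts["probable_to_definite"])),
    fraction_pct = c(unname(fr),
                     unname(fr["possible_to_definite"] +
                              fr["probable_to_definite"]))
  )
}

#' Combine component transition fractions
#'
#' The combined possible-or-probable→definite fraction equals the sum of
#' the possible→definite and probable→definite fractions whenever both are
#' reported against the full cohort denominator (the two numerator sets are
#' disjoint because each patient has a single index category).
#'
#' @param possible_to_definite,probable_to_definite Percent fractions.
#' @return Their sum.
#' @export
transition_combined <- function(possible_to_definite, probable_to_definite) {
  possible_to_definite + probable_to_definite
}

#' 30-day cost accrual from the index date
#'
#' Costs are accrued in 30-day bins starting at each patient's index date:
#' bin *k* covers derived days `[index + 30k, index + 30(k+1))`. A patient
#' contributes to a bin's denominator only while enrolled for the entire
#' bin (with `prorate = TRUE`, partially enrolled patients instead
#' contribute with weight equal to their enrolled fraction of the bin, and
#' all their claims in the bin are counted). Series are reported for total costs
#' (medical and pharmacy), inpatient costs and outpatient costs; pharmacy
#' claims enter the total series only.
#'
#' @param cohort Tibble with `patient_id` and `index_day`.
#' @param dataset A `claims_dataset`.
#' @param n_bins Number of 30-day bins from index.
#' @param prorate Use fractional person-time denominators instead of the
#'   full-bin enrollment requirement.
#' @return A `cost_bin_series` tibble: `bin`, `setting_group`, `n`
#'   (contributing patients, fractional under proration), `total_cost`,
#'   `mean_cost`.
#' @export
cost_accrual_30d <- function(cohort, dataset, n_bins = 24, prorate = FALSE) {
  cohort <- as_tibble(cohort)
  spans <- merge_spans(dataset$enrollment |>
                         semi_join(cohort, by = "patient_id"), 0)
  grid <- tidyr::crossing(cohort |> select("patient_id", "index_day"),
                          bin = seq_len(n_bins) - 1L) |>
    mutate(bin_start = .data$index_day + 30 * .data$bin,
           bin_end = .data$bin_start + 29)
  cover <- grid |>
    left_join(spans, by = "patient_id", relationship = "many-to-many") |>
    mutate(olap = pmax(0, pmin(.data$end_day, .data$bin_end) -
                         pmax(.data$start_day, .data$bin_start) + 1),
           olap = ifelse(is.na(.data$olap), 0, .data$olap)) |>
    group_by(.data$patient_id, .data$bin, .data$bin_start, .data$bin_end) |>
    summarise(enrolled_days = sum(.data$olap), .groups = "drop") |>
    mutate(weight = if (prorate) .data$enrolled_days / 30
           else as.numeric(.data$enrolled_days == 30)) |>
    filter(.data$weight > 0)

  claims <- dataset$claims |>
    inner_join(cohort |> select("patient_id", "index_day"),
               by = "patient_id") |>
    filter(.data$service_day >= .data$index_day,
           .data$service_day < .data$index_day + 30 * n_bins) |>
    mutate(bin = floor((.data$service_day - .data$index_day) / 30))

  series <- function(keep, label) {
    amt <- claims |>
      filter(keep(.data$setting)) |>
      group_by(.data$patient_id, .data$bin) |>
      summarise(amount = sum(.data$allowed_amount), .groups = "drop")
    cover |>
      left_join(amt, by = c("patient_id", "bin")) |>
      mutate(amount = dplyr::coalesce(.data$amount, 0)) |>
      group_by(bin = .data$bin) |>
      summarise(n = sum(.data$weight),
                total_cost = sum(.data$amount),
                .groups = "drop") |>
      mutate(mean_cost = ifelse(.data$n > 0, .data$total_cost / .data$n,
                                NA_real_),
             setting_group = label)
  }
  out <- bind_rows(
    series(function(s) rep(TRUE, length(s)), "total"),
    series(function(s) s == "inpatient", "inpatient"),
    series(function(s) s == "outpatient", "outpatient")
  ) |>
    tidyr::complete(bin = seq_len(n_bins) - 1L,
                    setting_group = c("total", "inpatient", "outpatient"),
                    fill = list(n = 0, total_cost = 0, mean_cost = NA_real_)) |>
    select("bin", "setting_group", "n", "total_cost", "mean_cost") |>
    arrange(match(.data$setting_group, c("total", "inpatient", "outpatient")),
            .data$bin)
  class(out) <- c("cost_bin_series", class(out))
  out
}

#' Compare demographic variables between cases and matched controls
#'
#' Welch's unequal-variance two-sided t test per variable; proportions
#' (logical columns) are compared with the same t test on their 0/1
#' indicators, the convention used when flagging "% male"-style rows in
#' demographic tables.
#'
#' @param cases,controls Tibbles holding the variables.
#' @param variables Character vector of column names (numeric or logical)
#'   present in both groups.
#' @return Tibble: `variable`, group means and SDs, `t`, `df`, `p_value`.
#'   When both groups have zero variance the test is undefined and `t`/`p`
#'   are `NA`.
#' @export
compare_demographics <- function(cases, controls,
                                 variables = intersect(names(cases),
                                                       names(controls))) {
  cases <- as_tibble(cases); controls <- as_tibble(controls)
  variables <- variables[vapply(variables, function(v) {
    is.numeric(cases[[v]]) || is.logical(cases[[v]])
  }, logical(1))]
  if (length(variables) == 0) abort("No numeric or logical variables to compare.")
  purrr::map_dfr(variables, function(v) {
    x <- as.numeric(cases[[v]]); y <- as.numeric(controls[[v]])
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      abort(paste0("Variable `", v,
                   "`: both groups need n >= 2 for a variance."))
    }
    base <- tibble(variable = v, n_cases = length(x), n_controls = length(y),
                   mean_cases = mean(x), sd_cases = stats::sd(x),
                   mean_controls = mean(y), sd_controls = stats::sd(y))
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(base |> mutate(t = NA_real_, df = NA_real_,
                            p_value = NA_real_))
    }
    tt <- t.test(x, y, var.equal = FALSE)
    base |> mutate(t = unname(tt$statistic), df = unname(tt$parameter),
                   p_value = tt$p.value)
  })
}
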