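# Internal event extraction ---------------------------------------------

# All diagnosis-code occurrences matched against the catalog by
# (code, coding system), *before* the age-window / easy-to-diagnose filters.
# The unfiltered view drives control identification (a patient with any
# catalog diagnosis code, at any age, is never a control).
dx_matches <- function(claims, catalog) {
  dx_long(claims) |>
    mutate(code = normalize_code(.data$code)) |>
    inner_join(catalog$diagnosis,
               by = c("code" = "code", "dx_system" = "code_system"))
}

# Qualifying diagnosis events: catalog hit, service day inside the code's
# age-of-presentation window, easy-to-diagnose codes removed.
dx_events <- function(claims, catalog) {
  dx_matches(claims, catalog) |>
    filter(.data$service_day >= .data$age_min_days,
           .data$service_day <= .data$age_max_days,
           !.data$easy_to_diagnose)
}

# Procedure lookups are by code alone (claims do not carry a CPT/HCPCS
# qualifier); if a code exists under both systems, genetic_test wins.
px_lookup <- function(catalog) {
  catalog$procedure |>
    group_by(.data$code) |>
    summarise(category = if (any(.data$category == "genetic_test"))
      "genetic_test" else "other_workup", .groups = "drop")
}

px_matches <- function(claims, catalog) {
  px_long(claims) |>
    mutate(code = normalize_code(.data$code)) |>
    inner_join(px_lookup(catalog), by = "code")
}

rv_matches <- function(claims, catalog) {
  rv_long(claims) |>
    mutate(code = normalize_code(.data$code)) |>
    inner_join(catalog$revenue, by = "code")
}

# Index-category precedence: within one service day, diagnosis codes beat
# procedure codes and definite > probable > possible; remaining ties break
# on the lexicographically smallest code for determinism.
category_priority <- function(category) {
  match(category, c("definite", "probable", "possible",
                    "genetic_test", "other_cpt_hcpcs"))
}

pick_index <- function(events) {
  if (nrow(events) == 0) return(events)
  events |>
    mutate(.prio = category_priority(.data$index_category)) |>
    arrange(.data$patient_id, .data$service_day, .data$.prio, .data$code) |>
    distinct(.data$patient_id, .keep_all = TRUE) |>
    select(-".prio")
}

# Per-patient index events for one cohort definition, vectorised over the
# whole claims table. Returns patient_id, index_day, index_code,
# index_code_kind, index_category.
index_events <- function(claims, catalog, cohort_def) {
  dxe <- dx_events(claims, catalog) |>
    mutate(index_category = .data$tier, index_code_kind = "diagnosis")
  cand <- switch(
    cohort_def,
    broad = {
      pxe <- px_matches(claims, catalog) |>
        mutate(index_category = if_else(.data$category == "genetic_test",
                                        "genetic_test", "other_cpt_hcpcs"),
               index_code_kind = .data$category)
      bind_rows(
        dxe |> select("patient_id", "service_day", "code",
                      "index_code_kind", "index_category"),
        pxe |> select("patient_id", "service_day", "code",
                      "index_code_kind", "index_category"))
    },
    conservative = dxe |>
      select("patient_id", "service_day", "code", "index_code_kind",
             "index_category"),
    mca_id_dd_e = {
      two_sys <- dxe |>
        filter(.data$anomaly_flag) |>
        distinct(.data$patient_id, .data$organ_system) |>
        count(.data$patient_id) |>
        filter(.data$n >= 2) |>
        pull(.data$patient_id)
      dxe |>
        filter(.data$mca_specific_flag | .data$id_flag | .data$dd_flag |
                 .data$e_flag |
                 (.data$anomaly_flag & .data$patient_id %in% two_sys)) |>
        select("patient_id", "service_day", "code", "index_code_kind",
               "index_category")
    },
    abort(paste0("Unknown cohort definition: ", cohort_def))
  )
  pick_index(cand) |>
    rename(index_day = "service_day", index_code = "code")
}

#' Find a patient's index event for a cohort definition
#'
#' The index date is the service day of the first appearing qualifying code:
#' for the Broad cohort any non-easy-to-diagnose catalog diagnosis code *or*
#' curated CPT/HCPCS procedure code qualifies; for the Conservative and
#' MCA/ID/DD/E cohorts only diagnosis codes qualify (for MCA/ID/DD/E, only
#' codes in that cohort's defining set). Age-of-presentation windows are
#' evaluated at each claim's service day. When several codes share the
#' earliest day the index category follows the hierarchy definite >
#' probable > possible, with diagnosis codes taking precedence over
#' procedure codes and residual ties broken by smallest code.
#'
#' @param claims Claims tibble for a single patient (or several; one index
#'   row is returned per patient present).
#' @param catalog A `code_catalog`.
#' @param cohort_def `"broad"`, `"conservative"` or `"mca_id_dd_e"`.
#' @return A tibble with columns `patient_id`, `index_day`, `index_code`,
#'   `index_code_kind`, `index_category`; zero rows when no code qualifies.
#' @export
find_index_event <- function(claims, catalog,
                             cohort_def = c("broad", "conservative",
                                            "mca_id_dd_e")) {
  cohort_def <- match.arg(cohort_def)
  index_events(as_tibble(claims), catalog, cohort_def)
}

#' Does a patient meet the multiple-congenital-anomaly rule?
#'
#' True when the claims carry either a code specific for multiple anomalies
#' or single-anomaly codes in two or more distinct organ systems
#' (age-of-presentation windows respected at each claim's service day).
#'
#' @param claims Claims tibble for a single patient.
#' @param catalog A `code_catalog`.
#' @return `TRUE` or `FALSE`.
#' @export
has_mca <- function(claims, catalog) {
  e <- dx_events(as_tibble(claims), catalog)
  if (nrow(e) == 0) return(FALSE)
  any(e$mca_specific_flag) ||
    length(unique(e$organ_system[e$anomaly_flag])) >= 2
}

# Merge spans whose gaps are <= bridge days, per patient.
merge_spans <- function(enrollment, bridge = 0) {
  if (nrow(enrollment) == 0) return(enrollment)
  enrollment |>
    group_by(.data$patient_id) |>
    arrange(.data$start_day, .by_group = TRUE) |>
    mutate(gap_prev = .data$start_day -
             dplyr::lag(.data$end_day, default = dplyr::first(.data$start_day)) - 1,
           grp = cumsum(pmax(.data$gap_prev, 0) > bridge)) |>
    group_by(.data$patient_id, .data$grp) |>
    summarise(start_day = min(.data$start_day),
              end_day = max(.data$end_day), .groups = "drop") |>
    select("patient_id", "start_day", "end_day")
}

#' Continuous-enrollment check at an index date
#'
#' Patients must be continuously enrolled for the 180 days before the index
#' date; a child younger than 180 days at index has a reduced requirement
#' equal to their age, i.e. the lookback is `L = min(180, index_day)` and
#' the window `[index_day - L, index_day]` must be covered by a single
#' enrollment span with no gap (gaps of at most `bridge` days may be
#' bridged; the default, 0, is the strict reading).
#'
#' @param spans Enrollment spans for one patient: tibble with `start_day`,
#'   `end_day` (a `patient_id` column is ignored).
#' @param index_day Index date in days since birth (>= 0).
#' @param bridge Maximum ignorable gap, in days.
#' @return `TRUE` or `FALSE`.
#' @export
check_continuous_enrollment <- function(spans, index_day, bridge = 0) {
  if (is.na(index_day) || index_day < 0) abort("`index_day` must be >= 0.")
  spans <- as_tibble(spans)
  if (nrow(spans) == 0) return(FALSE)
  if (!"patient_id" %in% names(spans)) spans$patient_id <- "x"
  m <- merge_spans(spans, bridge)
  lookback <- min(180, index_day)
  any(m$start_day <= index_day - lookback & m$end_day >= index_day)
}

# Vectorised enrollment check: idx is a tibble (patient_id, index_day) with
# one row per patient; returns a logical in idx row order.
enrollment_ok <- function(enrollment, idx, bridge = 0) {
  if (nrow(idx) == 0) return(logical(0))
  stopifnot(!anyDuplicated(idx$patient_id))
  m <- merge_spans(enrollment, bridge)
  ok_tbl <- idx |>
    left_join(m, by = "patient_id", relationship = "many-to-many") |>
    group_by(.data$patient_id) |>
    summarise(ok = any(!is.na(.data$start_day) &
                         .data$start_day <= .data$index_day -
                           pmin(180, .data$index_day) &
                         .data$end_day >= .data$index_day),
              .groups = "drop")
  (idx |> left_join(ok_tbl, by = "patient_id"))$ok
}

# Revenue-coded ICU days observed during enrollment.
icu_days <- function(dataset, catalog) {
  r <- rv_matches(dataset$claims, catalog)
  if (nrow(r) == 0) {
    return(tibble(patient_id = character(), service_day = numeric(),
                  unit = character()))
  }
  spans <- dataset$enrollment
  r |>
    distinct(.data$patient_id, .data$service_day, .data$unit) |>
    inner_join(spans, by = "patient_id", relationship = "many-to-many") |>
    filter(.data$service_day >= .data$start_day,
           .data$service_day <= .data$end_day) |>
    distinct(.data$patient_id, .data$service_day, .data$unit)
}

#' Assign cohorts, populations and attrition for a claims dataset
#'
#' Runs the full eligibility algorithm: each cohort definition (Broad,
#' MCA/ID/DD/E, Conservative) gets its own index event per patient, with
#' continuous enrollment checked against that cohort's own index date.
#' Membership rules:
#'
#' * **Broad** — any qualifying diagnosis (possible/probable/definite,
#'   excluding easy-to-diagnose codes) or curated CPT/HCPCS code.
#' * **MCA/ID/DD/E** — diagnosis codes for multiple congenital anomalies
#'   (a multiple-anomaly-specific code or single-anomaly codes in two or
#'   more organ systems), moderate/severe intellectual disability,
#'   developmental delay, or epilepsy/seizures.
#' * **Conservative** — a possible- or probable-tier diagnosis as the index
#'   code (patients whose index diagnosis is definite are excluded) plus at
#'   least one genetic-test CPT/HCPCS code at any time.
#'
#' The two subcohorts are subsets of Broad by construction. Cases are split
#' into populations on the Broad index date: critically-ill newborns are
#' at most 28 days old at index with a NICU revenue-coded stay at any time
#' during the observation (enrollment) period; other cases up to 18 years
#' at index are pediatric; older patients are excluded. Controls are
#' patients with no catalog diagnosis or procedure code ever (at any age);
#' their index is the start of their first enrollment span.
#'
#' @param dataset A `claims_dataset`.
#' @param catalog A `code_catalog`.
#' @param enrollment_bridge Maximum ignorable enrollment gap in days
#'   (default 0, the strict reading of "continuously enrolled").
#' @return A tibble of class `cohort_assignments`, one row per patient,
#'   with membership flags, `population`
#'   (`critically_ill_newborn`/`pediatric`/`control`/`excluded`),
#'   per-cohort index fields and `exclusion_reason`; the attrition report
#'   is attached and retrievable with [attrition()].
#' @export
assign_cohorts <- function(dataset, catalog, enrollment_bridge = 0) {
  stopifnot(inherits(dataset, "claims_dataset"),
            inherits(catalog, "code_catalog"))
  cl <- dataset$claims
  pts <- dataset$patients$patient_id

  idx_broad <- index_events(cl, catalog, "broad")
  idx_cons <- index_events(cl, catalog, "conservative")
  idx_mca <- index_events(cl, catalog, "mca_id_dd_e")

  add_enrolled <- function(idx) {
    idx$enrolled <- enrollment_ok(
      dataset$enrollment, idx |> select("patient_id", "index_day"),
      enrollment_bridge)
    idx
  }
  ok_broad <- add_enrolled(idx_broad)
  ok_cons <- add_enrolled(idx_cons)
  ok_mca <- add_enrolled(idx_mca)

  has_genetic_test <- px_matches(cl, catalog) |>
    filter(.data$category == "genetic_test") |>
    distinct(.data$patient_id) |>
    pull(.data$patient_id)

  nicu_ever <- icu_days(dataset, catalog) |>
    filter(.data$unit == "NICU") |>
    distinct(.data$patient_id) |>
    pull(.data$patient_id)

  # Any catalog code at all (age windows and easy flag ignored) removes a
  # patient from control eligibility.
  any_dx <- unique(dx_matches(cl, catalog)$patient_id)
  any_px <- unique(px_matches(cl, catalog)$patient_id)
  has_any_code <- union(any_dx, any_px)

  first_span <- dataset$enrollment |>
    group_by(.data$patient_id) |>
    summarise(first_start = min(.data$start_day), .groups = "drop")

  a <- tibble(patient_id = pts) |>
    left_join(ok_broad |>
                rename(broad_index_day = "index_day",
                       broad_index_code = "index_code",
                       broad_index_kind = "index_code_kind",
                       broad_index_category = "index_category",
                       broad_enrolled = "enrolled"),
              by = "patient_id") |>
    left_join(ok_cons |>
                select("patient_id", cons_index_day = "index_day",
                       cons_index_code = "index_code",
                       cons_index_category = "index_category",
                       cons_enrolled = "enrolled"),
              by = "patient_id") |>
    left_join(ok_mca |>
                select("patient_id", mca_index_day = "index_day",
                       mca_index_code = "index_code",
                       mca_index_category = "index_category",
                       mca_enrolled = "enrolled"),
              by = "patient_id") |>
    left_join(first_span, by = "patient_id") |>
    mutate(
      in_broad = !is.na(.data$broad_index_day) &
        .data$broad_enrolled %in% TRUE,
      in_mca_id_dd_e = .data$in_broad & !is.na(.data$mca_index_day) &
        .data$mca_enrolled %in% TRUE,
      in_conservative = .data$in_broad & !is.na(.data$cons_index_day) &
        .data$cons_enrolled %in% TRUE &
        .data$cons_index_category %in% c("possible", "probable") &
        .data$patient_id %in% has_genetic_test,
      over_18 = .data$in_broad & .data$broad_index_day > 18 * 365
    )

  a <- split_populations(a, dataset, catalog)

  attrition <- build_attrition(length(pts), idx_broad, ok_broad, idx_mca,
                               ok_mca, idx_cons, ok_cons, a)
  structure(a, attrition = attrition,
            class = c("cohort_assignments", class(a)))
}

#' Split cohort assignments into analysis populations
#'
#' Applies the population rule to per-cohort membership flags:
#' critically-ill newborns are cases at most 28 days old on the (Broad)
#' index date with at least one NICU revenue-coded claim during the
#' observation period; other cases up to 18 years at index are pediatric;
#' cases older than 18 years are excluded (with their cohort flags
#' cleared); patients with no catalog code of any kind are controls,
#' indexed at the start of their first enrollment span; everyone else is
#' excluded with a reason code. Called by [assign_cohorts()], and
#' re-runnable on its output.
#'
#' @param assignments Tibble carrying `patient_id`, the three membership
#'   flags, `broad_index_day`/`broad_index_code`/`broad_index_category`
#'   and `broad_enrolled` (as produced by [assign_cohorts()]).
#' @param dataset The `claims_dataset` the assignments came from.
#' @param catalog The `code_catalog` used to build them.
#' @return `assignments` with `population`, `exclusion_reason` and the
#'   generic `index_day`/`index_code`/`index_category` columns set.
#' @export
split_populations <- function(assignments, dataset, catalog) {
  a <- as_tibble(assignments)
  nicu_ever <- icu_days(dataset, catalog) |>
    filter(.data$unit == "NICU") |>
    distinct(.data$patient_id) |>
    pull(.data$patient_id)
  has_any_code <- union(
    unique(dx_matches(dataset$claims, catalog)$patient_id),
    unique(px_matches(dataset$claims, catalog)$patient_id))
  first_span <- dataset$enrollment |>
    group_by(.data$patient_id) |>
    summarise(first_start = min(.data$start_day), .groups = "drop")
  if ("first_start" %in% names(a)) a <- a |> select(-"first_start")

  a |>
    left_join(first_span, by = "patient_id") |>
    mutate(
      over_18 = !is.na(.data$broad_index_day) &
        .data$broad_index_day > 18 * 365 & .data$broad_enrolled %in% TRUE,
      in_broad = .data$in_broad & !.data$over_18,
      in_mca_id_dd_e = .data$in_mca_id_dd_e & !.data$over_18,
      in_conservative = .data$in_conservative & !.data$over_18,
      population = dplyr::case_when(
        in_broad & broad_index_day <= 28 &
          patient_id %in% nicu_ever ~ "critically_ill_newborn",
        in_broad ~ "pediatric",
        !patient_id %in% has_any_code ~ "control",
        TRUE ~ "excluded"
      ),
      exclusion_reason = dplyr::case_when(
        population != "excluded" ~ NA_character_,
        over_18 ~ "age_over_18",
        is.na(broad_index_day) ~ "no_qualifying_index",
        !(broad_enrolled %in% TRUE) ~ "continuous_enrollment",
        TRUE ~ "other"
      ),
      index_day = if_else(.data$population == "control",
                          .data$first_start, .data$broad_index_day),
      index_code = if_else(.data$population == "control",
                           NA_character_, .data$broad_index_code),
      index_category = if_else(.data$population == "control",
                               NA_character_, .data$broad_index_category)
    ) |>
    select("patient_id", "in_broad", "in_mca_id_dd_e", "in_conservative",
           "population", "exclusion_reason", "index_day", "index_code",
           "index_category",
           "broad_index_day", "broad_index_code", "broad_index_category",
           "broad_enrolled",
           "mca_index_day", "mca_index_code", "mca_index_category",
           "cons_index_day", "cons_index_code", "cons_index_category")
}

build_attrition <- function(n_total, idx_broad, ok_broad, idx_mca, ok_mca,
                            idx_cons, ok_cons, a) {
  per_cohort <- function(cohort, idx, ok, member_flag) {
    tibble(
      cohort = cohort,
      filter = c("all_patients", "qualifying_index",
                 "continuous_enrollment", "cohort_members",
                 "critically_ill_newborn", "pediatric"),
      n_remaining = c(
        n_total,
        nrow(idx),
        sum(ok$enrolled),
        sum(a[[member_flag]]),
        sum(a[[member_flag]] & a$population == "critically_ill_newborn"),
        sum(a[[member_flag]] & a$population == "pediatric"))
    )
  }
  bind_rows(
    per_cohort("broad", idx_broad, ok_broad, "in_broad"),
    per_cohort("mca_id_dd_e", idx_mca, ok_mca, "in_mca_id_dd_e"),
    per_cohort("conservative", idx_cons, ok_cons, "in_conservative"),
    tibble(cohort = "none",
           filter = c("control", "excluded"),
           n_remaining = c(sum(a$population == "control"),
                           sum(a$population == "excluded")))
  )
}

#' Retrieve the attrition report attached to a cohort assignment
#'
#' @param x A `cohort_assignments` tibble from [assign_cohorts()].
#' @return A tibble with columns `cohort`, `filter`, `n_remaining`; counts
#'   are non-increasing along each cohort's filter chain.
#' @export
attrition <- function(x) {
  stopifnot(inherits(x, "cohort_assignments"))
  attr(x, "attrition")
}

#' Extract the members of one cohort with that cohort's index fields
#'
#' @param assignments A `cohort_assignments` tibble.
#' @param cohort `"broad"`, `"mca_id_dd_e"`, `"conservative"`, or
#'   `"control"`.
#' @param population Optional filter: `"critically_ill_newborn"` or
#'   `"pediatric"` (ignored for controls).
#' @return Tibble with `patient_id`, `index_day`, `index_code`,
#'   `index_category`, `population`.
#' @export
cohort_members <- function(assignments, cohort = c("broad", "mca_id_dd_e",
                                                   "conservative", "control"),
                           population = NULL) {
  cohort <- match.arg(cohort)
  a <- as_tibble(assignments)
  out <- switch(
    cohort,
    broad = a |> filter(.data$in_broad) |>
      select("patient_id", index_day = "broad_index_day",
             index_code = "broad_index_code",
             index_category = "broad_index_category", "population"),
    mca_id_dd_e = a |> filter(.data$in_mca_id_dd_e) |>
      select("patient_id", index_day = "mca_index_day",
             index_code = "mca_index_code",
             index_category = "mca_index_category", "population"),
    conservative = a |> filter(.data$in_conservative) |>
      select("patient_id", index_day = "cons_index_day",
             index_code = "cons_index_code",
             index_category = "cons_index_category", "population"),
    control = a |> filter(.data$population == "control") |>
      select("patient_id", "index_day", "index_code", "index_category",
             "population")
  )
  if (!is.null(population) && cohort != "control") {
    out <- out |> filter(.data$population == !!population)
  }
  out
}
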