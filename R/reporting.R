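#' Prevalence report from per-group counts
#'
#' Computes, for each population-by-cohort row, the eligible denominator
#' (cases + controls + any excluded patients that belong in the
#' denominator) and the prevalence as a percent of eligible patients,
#' rendered to one decimal (half away from zero). Ratios with a zero
#' denominator are reported as `NA`.
#'
#' @param counts Tibble with columns `population`, `cohort`, `case_n`,
#'   `control_n` and optionally `excluded_n` (default 0). All counts must
#'   be nonnegative.
#' @return The input with `eligible_n`, `prevalence_pct` (rounded, percent)
#'   and `prevalence_raw` (unrounded fraction) columns added.
#' @export
prevalence_report <- function(counts) {
  counts <- as_tibble(counts)
  if (!"excluded_n" %in% names(counts)) counts$excluded_n <- 0
  counts$excluded_n[is.na(counts$excluded_n)] <- 0
  if (any(counts$case_n < 0 | counts$control_n < 0 | counts$excluded_n < 0)) {
    abort("Counts must be nonnegative.")
  }
  counts |>
    mutate(eligible_n = .data$case_n + .data$control_n + .data$excluded_n,
           prevalence_raw = ifelse(.data$eligible_n > 0,
                                   .data$case_n / .data$eligible_n, NA_real_),
           prevalence_pct = pct(.data$case_n, .data$eligible_n))
}

#' Published cohort counts and transition fractions
#'
#' Printed summary counts (sample sizes per population and cohort, the
#' eligible-population and NICU-universe denominators) and diagnostic
#' transition fractions from a published large-claims analysis of
#' pediatric genetic-disease indicators, shipped as plain-text inputs for
#' exercising the reporting identities. `published_counts()` rows with
#' cohort `*_nicu_share` use the NICU-stay universe as the denominator.
#'
#' @return A tibble.
#' @export
published_counts <- function() {
  readr::read_csv(system.file("extdata", "published_counts.csv",
                              package = "phenoclaims", mustWork = TRUE),
                  col_types = "ccddd", progress = FALSE)
}

#' @rdname published_counts
#' @export
published_transitions <- function() {
  readr::read_csv(system.file("extdata", "published_transitions.csv",
                              package = "phenoclaims", mustWork = TRUE),
                  col_types = "ccddddddd", progress = FALSE)
}

# Per-patient demographic frame for comparisons and matching covariates.
demographic_frame <- function(dataset, members) {
  enrol <- dataset$enrollment |>
    group_by(.data$patient_id) |>
    summarise(length_of_enrollment = sum(.data$end_day - .data$start_day + 1),
              age_at_enrollment = min(.data$start_day), .groups = "drop")
  as_tibble(members) |>
    left_join(dataset$patients, by = "patient_id") |>
    left_join(enrol, by = "patient_id") |>
    mutate(age_years = .data$index_day / 365,
           male = .data$sex == "M",
           white = .data$race_ethnicity == "white")
}

#' Run the full phenotyping pipeline on one dataset
#'
#' Orchestrates generate (optional) → cohort assignment → coarsened exact
#' matching → outcomes → report tables, writing every table as CSV plus a
#' JSON run manifest. All randomness derives from `seed` through one
#' per-stage seed rule, so a rerun with the same configuration is
#' byte-identical.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `catalog` (path to a catalog file, or a `code_catalog`), `data` (path
#'   to a dataset directory, a `claims_dataset`, or `NULL` to generate),
#'   `generator` (list of [generator_config()] overrides, used when
#'   generating), `seed` (integer), `out_dir` (output directory, or `NULL`
#'   to skip writing), `cohorts` (default all three), `n_bins` (30-day cost
#'   bins, default 12), `enrollment_bridge`, `nicu_gap`, `prorate_costs`.
#' @return Invisibly, a named list with the assignments, attrition,
#'   prevalence, match results and per-cohort outcome tables.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  catalog <- config$catalog %||%
    abort("`config$catalog` is required (path or code_catalog).")
  if (!inherits(catalog, "code_catalog")) catalog <- load_catalog(catalog)
  seed <- as.integer(config$seed %||% 1L)
  cohorts <- config$cohorts %||% c("broad", "mca_id_dd_e", "conservative")
  n_bins <- config$n_bins %||% 12L

  dataset <- config$data
  if (is.null(dataset)) {
    gen_args <- config$generator %||% list()
    gen_args$seed <- gen_args$seed %||% derive_seed(seed, "generator")
    dataset <- generate_population(do.call(generator_config, gen_args),
                                   catalog)
  } else if (is.character(dataset)) {
    dataset <- read_dataset(dataset)
  }
  stopifnot(inherits(dataset, "claims_dataset"))

  assignments <- assign_cohorts(dataset, catalog,
                                enrollment_bridge =
                                  config$enrollment_bridge %||% 0)
  att <- attrition(assignments)
  controls <- cohort_members(assignments, "control")

  prevalence <- purrr::map_dfr(
    c("critically_ill_newborn", "pediatric"), function(popn) {
      tibble(population = popn,
             cohort = cohorts,
             case_n = vapply(cohorts, function(ch)
               nrow(cohort_members(assignments, ch, popn)), numeric(1)),
             control_n = nrow(controls))
    }) |> prevalence_report()

  results <- list()
  matches <- list()
  for (popn in c("critically_ill_newborn", "pediatric")) {
    for (ch in cohorts) {
      members <- cohort_members(assignments, ch, popn)
      key <- paste(popn, ch, sep = ".")
      if (nrow(members) == 0 || nrow(controls) == 0) next
      scheme <- default_scheme(pediatric = popn == "pediatric")
      cases_u <- demographic_frame(dataset, members)
      ctrl_u <- demographic_frame(dataset, controls)
      mr <- cem_match_k2k(cases_u, ctrl_u, scheme,
                          seed = derive_seed(seed, key))
      matches[[key]] <- mr
      matched_cases <- members |>
        filter(.data$patient_id %in% mr$pairs$case_id)
      matched_controls <- controls |>
        filter(.data$patient_id %in% mr$pairs$control_id)
      results[[key]] <- list(
        utilization = dplyr::bind_cols(
          genetic_test_utilization(members, dataset, catalog),
          icu_utilization(members, dataset, catalog,
                          gap = config$nicu_gap %||% 1) |> select(-"n")),
        transitions = diagnostic_transitions(members, dataset, catalog),
        costs_cases = cost_accrual_30d(matched_cases, dataset,
                                       n_bins = n_bins,
                                       prorate = config$prorate_costs %||%
                                         FALSE),
        costs_controls = cost_accrual_30d(matched_controls, dataset,
                                          n_bins = n_bins,
                                          prorate = config$prorate_costs %||%
                                            FALSE),
        demographics = if (nrow(matched_cases) >= 2 &&
                           nrow(matched_controls) >= 2) {
          compare_demographics(
            demographic_frame(dataset, matched_cases),
            demographic_frame(dataset, matched_controls),
            c("age_years", "male", "white", "household_children",
              "length_of_enrollment"))
        }
      )
    }
  }

  out <- list(assignments = assignments, attrition = att,
              prevalence = prevalence, matches = matches, results = results,
              seed = seed)

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(as_tibble(assignments),
                     file.path(out_dir, "cohorts.csv"), progress = FALSE)
    readr::write_csv(att, file.path(out_dir, "attrition.csv"),
                     progress = FALSE)
    readr::write_csv(prevalence, file.path(out_dir, "prevalence.csv"),
                     progress = FALSE)
    for (key in names(results)) {
      r <- results[[key]]
      readr::write_csv(r$utilization,
                       file.path(out_dir, paste0("utilization_", key, ".csv")),
                       progress = FALSE)
      readr::write_csv(r$transitions,
                       file.path(out_dir, paste0("transitions_", key, ".csv")),
                       progress = FALSE)
      readr::write_csv(r$costs_cases,
                       file.path(out_dir, paste0("costs_cases_", key, ".csv")),
                       progress = FALSE)
      readr::write_csv(r$costs_controls,
                       file.path(out_dir,
                                 paste0("costs_controls_", key, ".csv")),
                       progress = FALSE)
      readr::write_csv(tidy(matches[[key]]),
                       file.path(out_dir, paste0("matches_", key, ".csv")),
                       progress = FALSE)
      if (!is.null(r$demographics)) {
        readr::write_csv(r$demographics,
                         file.path(out_dir,
                                   paste0("demographics_", key, ".csv")),
                         progress = FALSE)
      }
    }
    manifest <- list(
      seed = seed,
      config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
      n_patients = nrow(dataset$patients),
      n_claims = nrow(dataset$claims),
      cohorts = as.list(setNames(
        lapply(cohorts, function(ch)
          sum(as_tibble(assignments)[[paste0("in_", ch)]])), cohorts)),
      n_controls = nrow(controls),
      tables = sort(list.files(out_dir, pattern = "\\.csv$"))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}
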