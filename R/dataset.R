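#' Construct a claims dataset
#'
#' Bundles the three core tables of an administrative-claims extract —
#' patients, enrollment spans and claims — plus an optional ground-truth
#' table (present only for synthetic data). Dates throughout are *derived
#' dates*: integer days since the patient's birth, day 0 being the day of
#' birth, as used in de-identified claims databases.
#'
#' @param patients Tibble with columns `patient_id`, `sex`,
#'   `race_ethnicity`, `census_division`, `birth_year`,
#'   `household_children`.
#' @param enrollment Tibble with `patient_id`, `start_day`, `end_day`
#'   (inclusive); spans for one patient must be non-overlapping.
#' @param claims Tibble with `patient_id`, `claim_id`, `service_day`,
#'   `setting` (`inpatient`/`outpatient`/`pharmacy`), `allowed_amount`,
#'   `dx_system` (`ICD9`/`ICD10`), and the pipe-delimited code fields
#'   `diagnosis_codes` (first-listed code first), `procedure_codes`,
#'   `revenue_codes` (empty string for none).
#' @param ground_truth Optional tibble of planted labels (see
#'   [generate_population()]).
#'
#' @return A validated `claims_dataset` object.
#' @export
claims_dataset <- function(patients, enrollment, claims, ground_truth = NULL) {
  x <- structure(
    list(patients = as_tibble(patients),
         enrollment = as_tibble(enrollment),
         claims = as_tibble(claims),
         ground_truth = if (!is.null(ground_truth)) as_tibble(ground_truth)),
    class = "claims_dataset"
  )
  validate_claims_dataset(x)
}

validate_claims_dataset <- function(x) {
  p <- x$patients; e <- x$enrollment; cl <- x$claims
  need <- function(df, cols, tab) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      abort(paste0(tab, " table is missing column(s): ",
                   paste(miss, collapse = ", ")),
            class = "phenoclaims_schema_error")
    }
  }
  need(p, c("patient_id", "sex", "race_ethnicity", "census_division",
            "birth_year", "household_children"), "patients")
  need(e, c("patient_id", "start_day", "end_day"), "enrollment")
  need(cl, c("patient_id", "claim_id", "service_day", "setting",
             "allowed_amount", "dx_system", "diagnosis_codes",
             "procedure_codes", "revenue_codes"), "claims")

  if (anyDuplicated(p$patient_id)) {
    abort("patient_id values are not unique.",
          class = "phenoclaims_validation_error")
  }
  stray <- setdiff(unique(c(e$patient_id, cl$patient_id)), p$patient_id)
  if (length(stray) > 0) {
    abort(paste0("enrollment/claims reference unknown patient_id: ",
                 paste(utils::head(stray, 5), collapse = ", ")),
          class = "phenoclaims_validation_error")
  }
  if (nrow(e) > 0) {
    if (any(e$start_day > e$end_day) || any(e$start_day < 0)) {
      abort("enrollment spans must satisfy 0 <= start_day <= end_day.",
            class = "phenoclaims_validation_error")
    }
    es <- e |> arrange(.data$patient_id, .data$start_day) |>
      group_by(.data$patient_id) |>
      mutate(overlap = .data$start_day <= dplyr::lag(.data$end_day,
                                                     default = -1)) |>
      ungroup()
    if (any(es$overlap)) {
      bad <- unique(es$patient_id[es$overlap])
      abort(paste0("Overlapping enrollment spans for patient(s): ",
                   paste(utils::head(bad, 5), collapse = ", ")),
            class = "phenoclaims_validation_error")
    }
    x$enrollment <- es |> select(-"overlap")
  }
  if (nrow(cl) > 0) {
    if (any(cl$service_day < 0)) {
      abort("claims must have service_day >= 0.",
            class = "phenoclaims_validation_error")
    }
    if (any(cl$allowed_amount < 0)) {
      abort("claims must have allowed_amount >= 0.",
            class = "phenoclaims_validation_error")
    }
    empty <- cl$diagnosis_codes == "" & cl$procedure_codes == "" &
      cl$revenue_codes == ""
    if (any(empty)) {
      abort(paste0("Claims with no codes at all: claim_id ",
                   paste(utils::head(cl$claim_id[empty], 5), collapse = ", ")),
            class = "phenoclaims_validation_error")
    }
  }
  x
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset>\n")
  cat("  patients:   ", nrow(x$patients), "\n", sep = "")
  cat("  enrollment: ", nrow(x$enrollment), " spans\n", sep = "")
  cat("  claims:     ", nrow(x$claims), "\n", sep = "")
  if (!is.null(x$ground_truth)) {
    tab <- table(x$ground_truth$label)
    cat("  ground truth labels: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Long (one row per code) views of the pipe-delimited claim code fields.
split_codes <- function(claims, field, value_name) {
  keep <- claims[claims[[field]] != "", , drop = FALSE]
  if (nrow(keep) == 0) {
    return(tibble(patient_id = character(), claim_id = integer(),
                  service_day = numeric(), setting = character(),
                  dx_system = character(),
                  !!value_name := character(), position = integer()))
  }
  parts <- strsplit(keep[[field]], "|", fixed = TRUE)
  lens <- lengths(parts)
  out <- tibble(
    patient_id = rep(keep$patient_id, lens),
    claim_id = rep(keep$claim_id, lens),
    service_day = rep(keep$service_day, lens),
    setting = rep(keep$setting, lens),
    dx_system = rep(keep$dx_system, lens),
    !!value_name := unlist(parts, use.names = FALSE),
    position = unlist(lapply(lens, seq_len), use.names = FALSE)
  )
  out
}

dx_long <- function(claims) split_codes(claims, "diagnosis_codes", "code")
px_long <- function(claims) split_codes(claims, "procedure_codes", "code")
rv_long <- function(claims) split_codes(claims, "revenue_codes", "code")

#' Write / read a claims dataset as a directory of CSV files
#'
#' `write_dataset()` writes `patients.csv`, `enrollment.csv`, `claims.csv`
#' and (when present) `ground_truth.csv`; `read_dataset()` reads them back
#' and re-validates every invariant, so a hand-edited file with, say,
#' overlapping enrollment spans is rejected with the offending patient ids.
#' The round trip is lossless.
#'
#' @param dataset A `claims_dataset`.
#' @param directory Directory to write to / read from (created if missing).
#' @return `write_dataset()` returns `directory` invisibly; `read_dataset()`
#'   returns a `claims_dataset`.
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "claims_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(dataset$patients, file.path(directory, "patients.csv"),
                   progress = FALSE)
  readr::write_csv(dataset$enrollment, file.path(directory, "enrollment.csv"),
                   progress = FALSE)
  readr::write_csv(dataset$claims, file.path(directory, "claims.csv"),
                   progress = FALSE)
  if (!is.null(dataset$ground_truth)) {
    readr::write_csv(dataset$ground_truth,
                     file.path(directory, "ground_truth.csv"), progress = FALSE)
  }
  invisible(directory)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(directory) {
  rd <- function(file, types) {
    path <- file.path(directory, file)
    if (!file.exists(path)) abort(paste0("Missing file: ", path))
    readr::read_csv(path, col_types = types, progress = FALSE)
  }
  patients <- rd("patients.csv", readr::cols(
    patient_id = readr::col_character(), sex = readr::col_character(),
    race_ethnicity = readr::col_character(),
    census_division = readr::col_character(),
    birth_year = readr::col_integer(),
    household_children = readr::col_integer()))
  enrollment <- rd("enrollment.csv", readr::cols(
    patient_id = readr::col_character(), start_day = readr::col_double(),
    end_day = readr::col_double()))
  claims <- rd("claims.csv", readr::cols(
    patient_id = readr::col_character(), claim_id = readr::col_integer(),
    service_day = readr::col_double(), setting = readr::col_character(),
    allowed_amount = readr::col_double(), dx_system = readr::col_character(),
    diagnosis_codes = readr::col_character(),
    procedure_codes = readr::col_character(),
    revenue_codes = readr::col_character()))
  for (f in c("diagnosis_codes", "procedure_codes", "revenue_codes")) {
    claims[[f]][is.na(claims[[f]])] <- ""
  }
  gt_path <- file.path(directory, "ground_truth.csv")
  ground_truth <- NULL
  if (file.exists(gt_path)) {
    ground_truth <- readr::read_csv(gt_path, col_types = readr::cols(
      patient_id = readr::col_character(), label = readr::col_character(),
      newborn = readr::col_logical(), planted_gap = readr::col_logical(),
      index_day = readr::col_double(), index_route = readr::col_character()),
      progress = FALSE)
  }
  claims_dataset(patients, enrollment, claims, ground_truth)
}
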