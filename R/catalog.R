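#' Load a curated code catalog
#'
#' Reads the delimited catalog file that drives all classification in the
#' pipeline: diagnosis codes with their genetic-disease tier
#' (`possible` / `probable` / `definite`), easy-to-diagnose flag,
#' clinical-presentation group, congenital-anomaly and MCA flags,
#' ID/DD/epilepsy flags and age-of-presentation window; CPT/HCPCS procedure
#' codes categorized as `genetic_test` or `other_workup`; and NICU/PICU
#' revenue codes.
#'
#' The file is a UTF-8 comma- or tab-delimited table (autodetected) with one
#' header row and columns `kind` (`diagnosis`, `procedure` or `revenue`),
#' `code`, `code_system`, `tier`, `easy_to_diagnose`,
#' `clinical_presentation_group`, `organ_system`, `anomaly_flag`,
#' `mca_specific_flag`, `id_flag`, `dd_flag`, `e_flag`, `age_min_days`,
#' `age_max_days`, `category`, `unit`. Columns irrelevant to a row's `kind`
#' are left blank. Codes are matched exactly after normalization (uppercase,
#' periods stripped); any range expansion must be done when building the file.
#'
#' @param path Path to the catalog file.
#' @param strict If `TRUE` (default) any invariant violation aborts; if
#'   `FALSE`, violating rows are dropped with a warning naming the row
#'   numbers, and for duplicated `(code, code_system)` pairs the first
#'   occurrence wins.
#'
#' @return A `code_catalog` object: a list with tibbles `diagnosis`,
#'   `procedure` and `revenue`, plus the `organ_systems` vocabulary.
#'
#' @examples
#' cat <- load_catalog(demo_catalog_path())
#' cat
#' @export
load_catalog <- function(path, strict = TRUE) {
  assert_flag(strict, "strict")
  if (!file.exists(path)) abort(paste0("Catalog file not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)

  required <- c("kind", "code", "code_system", "tier", "easy_to_diagnose",
                "clinical_presentation_group", "organ_system", "anomaly_flag",
                "mca_specific_flag", "id_flag", "dd_flag", "e_flag",
                "age_min_days", "age_max_days", "category", "unit")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Catalog is missing required column(s): ",
                 paste(missing, collapse = ", ")), class = "phenoclaims_schema_error")
  }

  raw <- raw |> mutate(.row = dplyr::row_number() + 1L)  # file line numbers
  as_bool <- function(x) {
    out <- rep(FALSE, length(x))
    out[!is.na(x) & toupper(trimws(x)) %in% c("TRUE", "T", "1", "YES")] <- TRUE
    out
  }

  bad <- function(rows, why) {
    if (length(rows) == 0) return(invisible(NULL))
    msg <- paste0("Catalog rows ", paste(rows, collapse = ", "), ": ", why)
    if (strict) abort(msg, class = "phenoclaims_validation_error") else warn(msg)
  }

  dx <- raw |> filter(.data$kind == "diagnosis")
  px <- raw |> filter(.data$kind == "procedure")
  rv <- raw |> filter(.data$kind == "revenue")
  unknown <- raw |> filter(!.data$kind %in% c("diagnosis", "procedure", "revenue"))
  bad(unknown$.row, "unknown kind (must be diagnosis, procedure or revenue)")

  dx <- dx |>
    mutate(
      code = normalize_code(.data$code),
      code_system = toupper(trimws(.data$code_system)),
      tier = tolower(trimws(.data$tier)),
      easy_to_diagnose = as_bool(.data$easy_to_diagnose),
      anomaly_flag = as_bool(.data$anomaly_flag),
      mca_specific_flag = as_bool(.data$mca_specific_flag),
      id_flag = as_bool(.data$id_flag),
      dd_flag = as_bool(.data$dd_flag),
      e_flag = as_bool(.data$e_flag),
      age_min_days = ifelse(is.na(.data$age_min_days) | trimws(.data$age_min_days) == "",
                            0, suppressWarnings(as.numeric(.data$age_min_days))),
      age_max_days = ifelse(is.na(.data$age_max_days) | trimws(.data$age_max_days) == "",
                            Inf, suppressWarnings(as.numeric(.data$age_max_days)))
    )

  drop_rows <- function(df, bad_idx, why) {
    bad(df$.row[bad_idx], why)
    df[!seq_len(nrow(df)) %in% bad_idx, , drop = FALSE]
  }

  dx <- drop_rows(dx, which(!dx$code_system %in% c("ICD9", "ICD10")),
                  "diagnosis code_system must be ICD9 or ICD10")
  dx <- drop_rows(dx, which(!dx$tier %in% c("possible", "probable", "definite")),
                  "tier must be possible, probable or definite")
  dx <- drop_rows(dx, which(is.na(dx$age_min_days) | is.na(dx$age_max_days) |
                              dx$age_min_days > dx$age_max_days |
                              dx$age_max_days < 0),
                  "age window empty or malformed (age_min_days must be <= age_max_days, window must contain some age >= 0)")
  dx <- drop_rows(dx, which(dx$mca_specific_flag & !dx$anomaly_flag),
                  "mca_specific_flag requires anomaly_flag")

  dup <- function(df, why) {
    if (nrow(df) == 0) return(df)
    key <- paste(df$code, df$code_system)
    d <- duplicated(key)
    if (any(d)) {
      bad(df$.row[d], paste0(why, ": ", paste(unique(df$code[d]), collapse = ", ")))
      df <- df[!d, , drop = FALSE]
    }
    df
  }
  dx <- dup(dx, "duplicate (code, code_system)")

  px <- px |>
    mutate(code = normalize_code(.data$code),
           code_system = toupper(trimws(.data$code_system)),
           category = tolower(trimws(.data$category)))
  px <- drop_rows(px, which(!px$code_system %in% c("CPT", "HCPCS")),
                  "procedure code_system must be CPT or HCPCS")
  px <- drop_rows(px, which(!px$category %in% c("genetic_test", "other_workup")),
                  "category must be genetic_test or other_workup")
  px <- dup(px, "duplicate (code, code_system)")

  rv <- rv |>
    mutate(code = normalize_code(.data$code),
           unit = toupper(trimws(.data$unit)))
  rv <- drop_rows(rv, which(!rv$unit %in% c("NICU", "PICU")),
                  "revenue unit must be NICU or PICU")
  if (nrow(rv) > 0) {
    d <- duplicated(rv$code)
    if (any(d)) {
      bad(rv$.row[d], paste0("duplicate revenue code: ",
                             paste(unique(rv$code[d]), collapse = ", ")))
      rv <- rv[!d, , drop = FALSE]
    }
  }

  diagnosis <- dx |>
    select("code", "code_system", "tier", "easy_to_diagnose",
           "clinical_presentation_group", "organ_system", "anomaly_flag",
           "mca_specific_flag", "id_flag", "dd_flag", "e_flag",
           "age_min_days", "age_max_days")
  procedure <- px |> select("code", "code_system", "category")
  revenue <- rv |> select("code", "unit")

  new_code_catalog(diagnosis, procedure, revenue)
}

new_code_catalog <- function(diagnosis, procedure, revenue) {
  structure(
    list(
      diagnosis = as_tibble(diagnosis),
      procedure = as_tibble(procedure),
      revenue = as_tibble(revenue),
      organ_systems = sort(unique(stats::na.omit(diagnosis$organ_system)))
    ),
    class = "code_catalog"
  )
}

#' @export
print.code_catalog <- function(x, ...) {
  cat("<code_catalog>\n")
  cat("  diagnosis codes: ", nrow(x$diagnosis),
      " (possible ", sum(x$diagnosis$tier == "possible"),
      ", probable ", sum(x$diagnosis$tier == "probable"),
      ", definite ", sum(x$diagnosis$tier == "definite"), ")\n", sep = "")
  cat("  procedure codes: ", nrow(x$procedure),
      " (genetic_test ", sum(x$procedure$category == "genetic_test"),
      ", other_workup ", sum(x$procedure$category == "other_workup"), ")\n", sep = "")
  cat("  revenue codes:   ", nrow(x$revenue), "\n", sep = "")
  cat("  organ systems:   ", paste(x$organ_systems, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Path to the bundled demonstration catalog
#'
#' A small synthetic catalog (~40 codes) spanning every tier, flag and
#' category so the full pipeline can be exercised. It is illustrative only
#' and is not the curated code list used in any published study.
#'
#' @return File path of the bundled catalog CSV.
#' @export
demo_catalog_path <- function() {
  system.file("extdata", "demo_catalog.csv", package = "phenoclaims",
              mustWork = TRUE)
}

#' Classify a diagnosis code against the catalog
#'
#' Looks up a diagnosis code and returns its genetic-disease tier when the
#' code is present for the given coding system *and* the patient's age in
#' days falls inside the code's age-of-presentation window. The age window
#' encodes that some presentations suggest a genetic disorder only at
#' certain ages (isolated scoliosis in a newborn versus an adolescent).
#' Unknown codes never error; they classify as `NA`.
#'
#' @param catalog A `code_catalog`.
#' @param code Diagnosis code (vectorised).
#' @param code_system `"ICD9"` or `"ICD10"` (recycled against `code`).
#' @param age_days Age at the service date, in days since birth (recycled).
#'
#' @return Character vector of tiers (`"possible"`, `"probable"`,
#'   `"definite"`) with `NA` where no catalog entry applies.
#' @export
classify_diagnosis <- function(catalog, code, code_system, age_days) {
  stopifnot(inherits(catalog, "code_catalog"))
  if (any(is.na(age_days)) || any(age_days < 0)) {
    abort("`age_days` must be nonnegative.")
  }
  q <- tibble(code = normalize_code(code),
              code_system = toupper(as.character(code_system)),
              age_days = as.numeric(age_days))
  hit <- q |>
    left_join(catalog$diagnosis, by = c("code", "code_system")) |>
    mutate(tier = ifelse(!is.na(.data$tier) &
                           .data$age_days >= .data$age_min_days &
                           .data$age_days <= .data$age_max_days,
                         .data$tier, NA_character_))
  hit$tier
}

#' Look up the full diagnosis entry for a code
#'
#' As [classify_diagnosis()] but returns the matching catalog rows (age
#' window applied), which carry the flags used by the MCA/ID/DD/E rule.
#'
#' @inheritParams classify_diagnosis
#' @return A tibble with one row per query; non-matching queries have `NA`
#'   in the catalog columns.
#' @export
lookup_diagnosis <- function(catalog, code, code_system, age_days) {
  stopifnot(inherits(catalog, "code_catalog"))
  if (any(is.na(age_days)) || any(age_days < 0)) {
    abort("`age_days` must be nonnegative.")
  }
  q <- tibble(code = normalize_code(code),
              code_system = toupper(as.character(code_system)),
              age_days = as.numeric(age_days))
  out <- q |> left_join(catalog$diagnosis, by = c("code", "code_system"))
  in_window <- !is.na(out$tier) & out$age_days >= out$age_min_days &
    out$age_days <= out$age_max_days
  catalog_cols <- setdiff(names(catalog$diagnosis), c("code", "code_system"))
  out[!in_window, catalog_cols] <- NA
  out
}

#' Classify a procedure code as genetic test or other workup
#'
#' @param catalog A `code_catalog`.
#' @param code Procedure code (vectorised).
#' @param code_system `"CPT"` or `"HCPCS"` (recycled).
#' @return Character vector: `"genetic_test"`, `"other_workup"`, or `NA` for
#'   codes absent from the catalog.
#' @export
classify_procedure <- function(catalog, code, code_system) {
  stopifnot(inherits(catalog, "code_catalog"))
  q <- tibble(code = normalize_code(code),
              code_system = toupper(as.character(code_system)))
  (q |> left_join(catalog$procedure, by = c("code", "code_system")))$category
}

#' Classify a revenue code as a NICU or PICU room-and-board code
#'
#' @param catalog A `code_catalog`.
#' @param code Revenue code (vectorised).
#' @return Character vector: `"NICU"`, `"PICU"`, or `NA`.
#' @export
classify_revenue <- function(catalog, code) {
  stopifnot(inherits(catalog, "code_catalog"))
  q <- tibble(code = normalize_code(code))
  (q |> left_join(catalog$revenue, by = "code"))$unit
}
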