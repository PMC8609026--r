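# Shared fixture builders: everything is constructed in code.

pct <- phenoclaims:::pct

demo_cat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_catalog(demo_catalog_path())
    cache
  }
})

make_patients <- function(ids, sex = "M", race = "white",
                          division = "division_1", birth_year = 2010L,
                          children = 1L) {
  tibble::tibble(patient_id = ids, sex = sex, race_ethnicity = race,
                 census_division = division, birth_year = birth_year,
                 household_children = children)
}

span <- function(id, s, e) {
  tibble::tibble(patient_id = id, start_day = s, end_day = e)
}

clm <- function(id, day, dx = character(), sys = "ICD10",
                px = character(), rv = character(), amount = 10,
                setting = "outpatient") {
  tibble::tibble(
    patient_id = id, claim_id = 0L, service_day = day, setting = setting,
    allowed_amount = amount, dx_system = sys,
    diagnosis_codes = paste(dx, collapse = "|"),
    procedure_codes = paste(px, collapse = "|"),
    revenue_codes = paste(rv, collapse = "|"))
}

mk_ds <- function(claims = NULL, spans = NULL, ids = NULL) {
  claims <- if (is.null(claims)) clm("x", 0, dx = "NC1")[0, ] else
    dplyr::bind_rows(claims)
  ids <- ids %||% unique(c(claims$patient_id, spans$patient_id))
  spans <- if (is.null(spans)) span(ids, 0, 10000) else
    dplyr::bind_rows(spans)
  claims$claim_id <- seq_len(nrow(claims))
  claims_dataset(make_patients(ids), spans, claims)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random small fixture for oracle-equivalence checks: codes drawn from the
# demo catalog plus junk codes, random spans (sometimes with a gap),
# random multi-code claims.
random_fixture <- function(seed, max_patients = 12) {
  withr::with_seed(seed, {
    cat_ <- demo_cat()
    n <- sample(2:max_patients, 1)
    ids <- sprintf("R%03d", seq_len(n))
    dx_pool <- c(cat_$diagnosis$code, sprintf("JUNK%d", 1:6))
    sys_pool <- c("ICD9", "ICD10")
    px_pool <- c(cat_$procedure$code, "99999")
    rv_pool <- c(cat_$revenue$code, "0110")
    spans <- dplyr::bind_rows(lapply(ids, function(id) {
      if (runif(1) < 0.3) {
        cut <- sample(100:2000, 1)
        span(id, c(0, cut + sample(2:200, 1)),
             c(cut, cut + sample(300:3000, 1)))
      } else {
        span(id, 0, sample(500:4000, 1))
      }
    }))
    claims <- dplyr::bind_rows(lapply(ids, function(id) {
      k <- sample(1:8, 1)
      dplyr::bind_rows(lapply(seq_len(k), function(j) {
        clm(id, sample(0:3000, 1),
            dx = sample(dx_pool, sample(0:3, 1)),
            sys = sample(sys_pool, 1),
            px = if (runif(1) < 0.4) sample(px_pool, sample(1:2, 1))
            else character(),
            rv = if (runif(1) < 0.2) sample(rv_pool, 1) else character(),
            amount = round(rlnorm(1, 5, 1), 2),
            setting = sample(c("inpatient", "outpatient", "pharmacy"), 1))
      }))
    }))
    # Drop claims that ended up with no codes at all.
    keep <- !(claims$diagnosis_codes == "" & claims$procedure_codes == "" &
                claims$revenue_codes == "")
    if (!any(keep)) {
      claims <- clm(ids[1], 10, dx = "JUNK1")
    } else {
      claims <- claims[keep, , drop = FALSE]
    }
    claims$claim_id <- seq_len(nrow(claims))
    claims_dataset(make_patients(ids), spans, claims)
  })
}

# Random units for matching oracle checks.
random_units <- function(seed, n_cases = NULL, n_controls = NULL) {
  withr::with_seed(seed, {
    n_cases <- n_cases %||% sample(2:20, 1)
    n_controls <- n_controls %||% sample(2:20, 1)
    mk <- function(prefix, n) {
      tibble::tibble(
        patient_id = sprintf("%s%03d", prefix, seq_len(n)),
        colour = sample(c("red", "green", "blue"), n, replace = TRUE),
        size = sample(1:3, n, replace = TRUE),
        age = runif(n, 0, 20))
    }
    list(cases = mk("C", n_cases), controls = mk("K", n_controls))
  })
}
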