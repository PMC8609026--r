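#' Configuration for the synthetic claims generator
#'
#' Returns the generator's parameter list. Defaults emulate the published
#' population structure of a large US pediatric claims cohort: cohort
#' prevalences of roughly 9.4% (Broad, of which 0.8% MCA/ID/DD/E and 0.2%
#' Conservative), a small critically-ill-newborn slice, NICU stays averaging
#' ~24 days among affected newborns, and an early post-index cost elevation
#' that decays to steady state over about 12 months.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; the generator is fully reproducible for a
#'   fixed seed.
#' @param prevalence Named vector of planted label prevalences for
#'   `broad_only`, `mca_id_dd_e` and `conservative`; the remainder of the
#'   population is unlabeled (`none`). Must sum to at most 1.
#' @param newborn_fraction Fraction of labeled patients planted as
#'   critically-ill newborns (index at age 0–28 days plus NICU
#'   room-and-board claims).
#' @param gap_probability Fraction of labeled patients given a planted
#'   enrollment gap inside their pre-index lookback window, so the
#'   continuous-enrollment filter has a non-trivial kill set. Set to 0 for
#'   complete enrollment.
#' @param gap_mean_days Mean of the geometric gap-length distribution.
#' @param claims_per_month Background (non-catalog) claim rate per
#'   patient-month of enrollment.
#' @param cost_meanlog,cost_sdlog Named per-setting log-normal parameters
#'   for claim allowed amounts (USD).
#' @param enrichment_multiplier Early post-index cost multiplier for labeled
#'   patients (> 1 plants a detectable case-versus-control cost elevation).
#' @param enrichment_decay_months Months over which the planted cost
#'   elevation decays to the background rate.
#' @param nicu_los_mean Mean planted NICU length of stay (days) for labeled
#'   newborns (geometric).
#' @param picu_probability Probability that a labeled patient has PICU
#'   revenue-coded claims.
#' @param genetic_test_delay_mean Mean days from index to first genetic test
#'   for conservative-labeled patients (exponential).
#' @param transition_probability Probability that a labeled patient with a
#'   possible/probable index later receives a first-listed definite-tier
#'   diagnosis (plants diagnostic transitions).
#' @param followup_min,followup_max Post-index enrollment length range
#'   (days).
#'
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_patients = 1000,
    seed = 20260101L,
    prevalence = c(broad_only = 0.084, mca_id_dd_e = 0.008,
                   conservative = 0.002),
    newborn_fraction = 0.025,
    gap_probability = 0.05,
    gap_mean_days = 60,
    claims_per_month = 0.6,
    cost_meanlog = c(inpatient = log(3000), outpatient = log(150),
                     pharmacy = log(40)),
    cost_sdlog = c(inpatient = 1, outpatient = 1, pharmacy = 0.8),
    enrichment_multiplier = 6,
    enrichment_decay_months = 12,
    nicu_los_mean = 24,
    picu_probability = 0.2,
    genetic_test_delay_mean = 150,
    transition_probability = 0.15,
    followup_min = 365,
    followup_max = 1825) {
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    prevalence = prevalence, newborn_fraction = newborn_fraction,
    gap_probability = gap_probability, gap_mean_days = gap_mean_days,
    claims_per_month = claims_per_month,
    cost_meanlog = cost_meanlog, cost_sdlog = cost_sdlog,
    enrichment_multiplier = enrichment_multiplier,
    enrichment_decay_months = enrichment_decay_months,
    nicu_los_mean = nicu_los_mean, picu_probability = picu_probability,
    genetic_test_delay_mean = genetic_test_delay_mean,
    transition_probability = transition_probability,
    followup_min = followup_min, followup_max = followup_max
  )
  need <- c("broad_only", "mca_id_dd_e", "conservative")
  if (!all(need %in% names(cfg$prevalence))) {
    abort("`prevalence` must name broad_only, mca_id_dd_e and conservative.")
  }
  if (any(cfg$prevalence < 0) || sum(cfg$prevalence) > 1) {
    abort("Prevalences must be nonnegative and sum to at most 1.")
  }
  rates <- c(cfg$newborn_fraction, cfg$gap_probability, cfg$claims_per_month,
             cfg$picu_probability, cfg$transition_probability)
  if (any(rates < 0)) abort("All rates must be nonnegative.")
  if (cfg$n_patients < 0) abort("`n_patients` must be nonnegative.")
  structure(cfg, class = "generator_config")
}

# Candidate code pools for planting, restricted to codes valid at a given
# age. Kept as closures over the catalog so the generator draws from them
# without re-filtering.
planting_pools <- function(catalog) {
  dx <- catalog$diagnosis
  flagless <- !dx$anomaly_flag & !dx$mca_specific_flag & !dx$id_flag &
    !dx$dd_flag & !dx$e_flag
  list(
    pp_clean = dx[dx$tier %in% c("possible", "probable") &
                    !dx$easy_to_diagnose & flagless, , drop = FALSE],
    definite_clean = dx[dx$tier == "definite" & !dx$easy_to_diagnose &
                          flagless, , drop = FALSE],
    anomaly = dx[dx$anomaly_flag & !dx$mca_specific_flag &
                   !dx$easy_to_diagnose, , drop = FALSE],
    mca_specific = dx[dx$mca_specific_flag & !dx$easy_to_diagnose, ,
                      drop = FALSE],
    idde = dx[(dx$id_flag | dx$dd_flag | dx$e_flag) & !dx$easy_to_diagnose &
                !dx$anomaly_flag, , drop = FALSE],
    genetic_test = catalog$procedure[
      catalog$procedure$category == "genetic_test", , drop = FALSE],
    other_workup = catalog$procedure[
      catalog$procedure$category == "other_workup", , drop = FALSE],
    nicu = catalog$revenue[catalog$revenue$unit == "NICU", , drop = FALSE],
    picu = catalog$revenue[catalog$revenue$unit == "PICU", , drop = FALSE]
  )
}

valid_at <- function(pool, age) {
  pool[pool$age_min_days <= age & pool$age_max_days >= age, , drop = FALSE]
}

pick_row <- function(pool) pool[sample.int(nrow(pool), 1L), , drop = FALSE]

#' Generate a synthetic claims population with planted ground truth
#'
#' Simulates patients, enrollment spans and claims such that every planted
#' label is recoverable by the cohort algorithms: an `mca_id_dd_e` patient
#' receives either a multiple-anomaly-specific code, single-anomaly codes in
#' two distinct organ systems, or an ID/DD/epilepsy code; a `conservative`
#' patient receives a possible/probable index diagnosis plus at least one
#' genetic-test procedure claim; a `broad_only` patient receives a
#' qualifying code that triggers no other cohort; unlabeled patients carry
#' only codes absent from the catalog. Labeled newborns additionally receive
#' NICU revenue-coded claims starting at the index day. The ground-truth
#' table is emitted separately and is never consumed by the pipeline stages.
#'
#' @param config A [generator_config()].
#' @param catalog A `code_catalog` holding at least one plantable code of
#'   every kind the configuration requires.
#' @return A `claims_dataset` whose `ground_truth` table carries the planted
#'   `label`, `newborn` and `planted_gap` flags, planted `index_day` and
#'   `index_route`.
#' @export
generate_population <- function(config, catalog) {
  stopifnot(inherits(config, "generator_config"),
            inherits(catalog, "code_catalog"))
  pools <- planting_pools(catalog)
  labelled_any <- sum(config$prevalence) > 0
  if (labelled_any) {
    need <- c("pp_clean", "definite_clean", "anomaly", "mca_specific",
              "idde", "genetic_test", "other_workup", "nicu")
    for (k in need) {
      if (nrow(pools[[k]]) == 0) {
        abort(paste0("Catalog has no plantable code of kind: ", k),
              class = "phenoclaims_config_error")
      }
    }
    if (length(unique(valid_at(pools$anomaly, 10)$organ_system)) < 2) {
      abort("Catalog needs newborn-valid anomaly codes in >=2 organ systems.",
            class = "phenoclaims_config_error")
    }
  }

  with_seed(derive_seed(config$seed, "generate"), {
    n <- config$n_patients
    prev <- config$prevalence
    labels <- if (n == 0) character() else sample(
      c("none", "broad_only", "mca_id_dd_e", "conservative"), n,
      replace = TRUE,
      prob = c(1 - sum(prev), prev[["broad_only"]], prev[["mca_id_dd_e"]],
               prev[["conservative"]]))

    patients <- tibble(
      patient_id = sprintf("P%06d", seq_len(n)),
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.512, 0.488)),
      race_ethnicity = sample(
        c("white", "hispanic", "black", "asian", "unknown"), n,
        replace = TRUE, prob = c(0.61, 0.13, 0.09, 0.05, 0.12)),
      census_division = sample(sprintf("division_%d", 1:9), n, replace = TRUE),
      birth_year = sample(2007:2017, n, replace = TRUE),
      household_children = sample(1:5, n, replace = TRUE,
                                  prob = c(0.35, 0.35, 0.18, 0.08, 0.04))
    )

    labelled <- labels != "none"
    newborn <- labelled & runif(n) < config$newborn_fraction
    index_day <- rep(NA_real_, n)
    index_day[newborn] <- sample(0:28, sum(newborn), replace = TRUE)
    ped <- labelled & !newborn
    index_day[ped] <- sample(29:3650, sum(ped), replace = TRUE)

    followup <- sample(config$followup_min:config$followup_max, n,
                       replace = TRUE)
    # Labeled patients are enrolled from birth so their pre-index lookback is
    # covered; unlabeled patients enroll at varied ages (as controls do in
    # real plans), which is what their index date — start of the first
    # enrollment period — reflects.
    start_day <- ifelse(labelled | runif(n) < 0.4, 0,
                        sample(1:2500, n, replace = TRUE))
    end_day <- ifelse(labelled, index_day + followup, start_day + followup)

    # Planted enrollment gap straddling the pre-index lookback window, so the
    # continuous-enrollment rule (and only that rule) excludes these patients.
    lookback <- pmin(180, index_day)
    gap_ok <- labelled & index_day >= 4
    planted_gap <- gap_ok & runif(n) < config$gap_probability
    gap_start <- gap_end <- rep(NA_real_, n)
    if (any(planted_gap)) {
      i <- which(planted_gap)
      gs <- pmax(1, index_day[i] - ceiling(lookback[i] / 2))
      glen <- 1 + rgeom(length(i), 1 / config$gap_mean_days)
      ge <- pmin(gs + glen, index_day[i] - 1)
      gap_start[i] <- gs
      gap_end[i] <- ge
    }

    enrollment <- tibble(patient_id = patients$patient_id,
                         start_day = start_day, end_day = end_day)
    if (any(planted_gap)) {
      i <- which(planted_gap)
      enrollment <- bind_rows(
        enrollment[-i, ],
        tibble(patient_id = patients$patient_id[i], start_day = 0,
               end_day = gap_start[i] - 1),
        tibble(patient_id = patients$patient_id[i],
               start_day = gap_end[i] + 1, end_day = end_day[i])
      ) |> arrange(.data$patient_id, .data$start_day)
    }

    # --- planted claims -------------------------------------------------
    planted <- vector("list", n)
    routes <- rep(NA_character_, n)
    mk <- function(pid, day, dx_code = "", dx_system = "ICD10",
                   px_code = "", rv_code = "", setting = "outpatient",
                   amount = NULL) {
      if (is.null(amount)) {
        amount <- rlnorm(length(day), config$cost_meanlog[[setting]],
                         config$cost_sdlog[[setting]])
      }
      tibble(patient_id = pid, service_day = day, setting = setting,
             allowed_amount = amount, dx_system = dx_system,
             diagnosis_codes = dx_code, procedure_codes = px_code,
             revenue_codes = rv_code)
    }

    for (i in which(labelled)) {
      pid <- patients$patient_id[i]
      idx <- index_day[i]
      lab <- labels[i]
      rows <- list()
      index_tier <- NA_character_

      if (lab == "broad_only") {
        route <- sample(c("pp_dx", "definite_dx", "workup"), 1,
                        prob = c(0.5, 0.3, 0.2))
        routes[i] <- route
        if (route == "pp_dx") {
          e <- pick_row(valid_at(pools$pp_clean, idx))
          index_tier <- e$tier
          rows <- c(rows, list(mk(pid, idx, e$code, e$code_system)))
        } else if (route == "definite_dx") {
          e <- pick_row(valid_at(pools$definite_clean, idx))
          rows <- c(rows, list(mk(pid, idx, e$code, e$code_system)))
        } else {
          e <- pick_row(pools$other_workup)
          rows <- c(rows, list(mk(pid, idx, px_code = e$code)))
        }
      } else if (lab == "mca_id_dd_e") {
        route <- sample(c("mca_specific", "two_systems", "idde"), 1,
                        prob = c(0.4, 0.3, 0.3))
        if (route == "two_systems" &&
            length(unique(valid_at(pools$anomaly, idx)$organ_system)) < 2) {
          route <- "mca_specific"
        }
        routes[i] <- route
        if (route == "mca_specific") {
          e <- pick_row(valid_at(pools$mca_specific, idx))
          index_tier <- e$tier
          rows <- c(rows, list(mk(pid, idx, e$code, e$code_system)))
        } else if (route == "two_systems") {
          av <- valid_at(pools$anomaly, idx)
          systems <- sample(unique(av$organ_system), 2)
          for (s in systems) {
            e <- pick_row(av[av$organ_system == s, , drop = FALSE])
            rows <- c(rows, list(mk(pid, idx, e$code, e$code_system)))
            if (is.na(index_tier)) index_tier <- e$tier
          }
        } else {
          e <- pick_row(valid_at(pools$idde, idx))
          index_tier <- e$tier
          rows <- c(rows, list(mk(pid, idx, e$code, e$code_system)))
        }
      } else { # conservative
        routes[i] <- "pp_dx_plus_test"
        e <- pick_row(valid_at(pools$pp_clean, idx))
        index_tier <- e$tier
        rows <- c(rows, list(mk(pid, idx, e$code, e$code_system)))
        delay <- min(round(rexp(1, 1 / config$genetic_test_delay_mean)),
                     followup[i])
        gt <- pick_row(pools$genetic_test)
        rows <- c(rows, list(mk(pid, idx + delay, px_code = gt$code)))
        if (runif(1) < 0.4) {
          delay2 <- min(delay + sample(30:180, 1), followup[i])
          gt2 <- pick_row(pools$genetic_test)
          rows <- c(rows, list(mk(pid, idx + delay2, px_code = gt2$code)))
        }
      }

      # Planted diagnostic transition to a definite-tier primary code.
      if (!is.na(index_tier) && index_tier %in% c("possible", "probable") &&
          runif(1) < config$transition_probability) {
        tday <- idx + min(sample(30:300, 1), followup[i])
        e <- pick_row(valid_at(pools$definite_clean, tday))
        rows <- c(rows, list(mk(pid, tday, e$code, e$code_system)))
      }

      # NICU confinement for critically-ill newborns.
      if (newborn[i]) {
        los <- min(1 + rgeom(1, 1 / config$nicu_los_mean), 120)
        days <- idx:(idx + los - 1)
        rv <- pools$nicu$code[sample.int(nrow(pools$nicu), 1)]
        rows <- c(rows, list(mk(pid, days, rv_code = rv,
                                setting = "inpatient")))
      }

      # Occasional PICU claims for labeled patients.
      if (nrow(pools$picu) > 0 && runif(1) < config$picu_probability) {
        pdays <- idx + sample(0:min(300, followup[i]), sample(1:3, 1),
                              replace = TRUE)
        rows <- c(rows, list(mk(pid, pdays, rv_code = pools$picu$code[1],
                                setting = "inpatient")))
      }

      # Early post-index cost elevation decaying to the background rate.
      if (config$enrichment_multiplier > 1) {
        bins <- 0:(config$enrichment_decay_months - 1)
        emit <- runif(length(bins)) < 0.8
        if (any(emit)) {
          b <- bins[emit]
          bday <- idx + 30 * b + sample(0:29, length(b), replace = TRUE)
          ok <- bday <= end_day[i]
          if (any(ok)) {
            b <- b[ok]; bday <- bday[ok]
            setting <- ifelse(runif(length(b)) < 0.3, "inpatient",
                              "outpatient")
            amt <- rlnorm(length(b), config$cost_meanlog[setting],
                          config$cost_sdlog[setting]) *
              config$enrichment_multiplier * exp(-b / 3)
            rows <- c(rows, list(tibble(
              patient_id = pid, service_day = bday, setting = setting,
              allowed_amount = amt, dx_system = "ICD10",
              diagnosis_codes = "NC000", procedure_codes = "",
              revenue_codes = "")))
          }
        }
      }
      planted[[i]] <- bind_rows(rows)
    }

    # --- background (non-catalog) claims for everyone -------------------
    bg_pool <- sprintf("NC%03d", 0:50)
    months <- pmax((end_day - start_day + 1) / 30, 0)
    n_bg <- rpois(n, config$claims_per_month * months)
    bg <- tibble(
      patient_id = rep(patients$patient_id, n_bg),
      start = rep(start_day, n_bg),
      end = rep(end_day, n_bg)
    )
    if (nrow(bg) > 0) {
      bg <- bg |>
        mutate(service_day = floor(runif(n(), .data$start, .data$end + 1)),
               setting = sample(c("outpatient", "inpatient", "pharmacy"),
                                n(), replace = TRUE,
                                prob = c(0.7, 0.1, 0.2)),
               allowed_amount = rlnorm(
                 n(), config$cost_meanlog[.data$setting],
                 config$cost_sdlog[.data$setting]),
               dx_system = "ICD10",
               diagnosis_codes = sample(bg_pool, n(), replace = TRUE),
               procedure_codes = "", revenue_codes = "") |>
        select(-"start", -"end")
    } else {
      bg <- NULL
    }

    claims <- bind_rows(c(planted[!vapply(planted, is.null, logical(1))],
                          list(bg))) |>
      arrange(.data$patient_id, .data$service_day) |>
      mutate(claim_id = dplyr::row_number()) |>
      relocate("claim_id", .after = "patient_id")
    if (nrow(claims) == 0) {
      claims <- tibble(patient_id = character(), claim_id = integer(),
                       service_day = numeric(), setting = character(),
                       allowed_amount = numeric(), dx_system = character(),
                       diagnosis_codes = character(),
                       procedure_codes = character(),
                       revenue_codes = character())
    }

    ground_truth <- tibble(
      patient_id = patients$patient_id,
      label = labels,
      newborn = newborn,
      planted_gap = planted_gap,
      index_day = index_day,
      index_route = routes
    )

    claims_dataset(patients, enrollment, claims, ground_truth)
  })
}
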