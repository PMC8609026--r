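# Independent brute-force reimplementations used as oracles. Everything here
# is deliberately plain loops over parsed rows — no shared code paths with
# the package internals beyond exported data containers.

o_norm <- function(x) toupper(gsub(".", "", trimws(x), fixed = TRUE))

o_split <- function(s) if (s == "") character() else
  strsplit(s, "|", fixed = TRUE)[[1]]

# Parse one patient's claims into flat event lists.
o_events <- function(claims, cat_) {
  dx <- list(); px <- list(); rv <- list(); any_dx <- FALSE; any_px <- FALSE
  for (r in seq_len(nrow(claims))) {
    day <- claims$service_day[r]
    sys <- claims$dx_system[r]
    codes <- o_split(claims$diagnosis_codes[r])
    for (pos in seq_along(codes)) {
      code <- o_norm(codes[pos])
      hit <- which(cat_$diagnosis$code == code &
                     cat_$diagnosis$code_system == sys)
      if (length(hit) == 1) {
        any_dx <- TRUE
        e <- cat_$diagnosis[hit, ]
        if (day >= e$age_min_days && day <= e$age_max_days &&
            !e$easy_to_diagnose) {
          dx[[length(dx) + 1]] <- data.frame(
            day = day, code = code, tier = e$tier,
            anomaly = e$anomaly_flag, mca_spec = e$mca_specific_flag,
            idde = e$id_flag || e$dd_flag || e$e_flag,
            organ = e$organ_system, pos = pos)
        }
      }
    }
    for (code in o_split(claims$procedure_codes[r])) {
      code <- o_norm(code)
      hit <- which(cat_$procedure$code == code)
      if (length(hit) >= 1) {
        any_px <- TRUE
        cats <- cat_$procedure$category[hit]
        category <- if ("genetic_test" %in% cats) "genetic_test" else
          "other_workup"
        px[[length(px) + 1]] <- data.frame(day = day, code = code,
                                           category = category)
      }
    }
    for (code in o_split(claims$revenue_codes[r])) {
      code <- o_norm(code)
      hit <- which(cat_$revenue$code == code)
      if (length(hit) == 1) {
        rv[[length(rv) + 1]] <- data.frame(day = day,
                                           unit = cat_$revenue$unit[hit])
      }
    }
  }
  list(dx = do.call(rbind, dx), px = do.call(rbind, px),
       rv = do.call(rbind, rv), any_dx = any_dx, any_px = any_px)
}

o_pick_index <- function(cands) {
  # cands: data.frame(day, code, category)
  if (is.null(cands) || nrow(cands) == 0) return(NULL)
  prio <- c(definite = 1, probable = 2, possible = 3, genetic_test = 4,
            other_cpt_hcpcs = 5)
  best <- NULL
  for (r in seq_len(nrow(cands))) {
    c_ <- cands[r, ]
    if (is.null(best) ||
        c_$day < best$day ||
        (c_$day == best$day && prio[[c_$category]] < prio[[best$category]]) ||
        (c_$day == best$day && prio[[c_$category]] == prio[[best$category]] &&
           c_$code < best$code)) {
      best <- c_
    }
  }
  best
}

o_enrolled <- function(spans, idx, bridge = 0) {
  if (nrow(spans) == 0) return(FALSE)
  spans <- spans[order(spans$start_day), , drop = FALSE]
  merged <- list(c(spans$start_day[1], spans$end_day[1]))
  for (r in seq_len(nrow(spans))[-1]) {
    last <- merged[[length(merged)]]
    if (spans$start_day[r] <= last[2] + bridge + 1) {
      merged[[length(merged)]] <- c(last[1], max(last[2], spans$end_day[r]))
    } else {
      merged[[length(merged) + 1]] <- c(spans$start_day[r], spans$end_day[r])
    }
  }
  L <- min(180, idx)
  for (m in merged) if (m[1] <= idx - L && m[2] >= idx) return(TRUE)
  FALSE
}

o_in_enrollment <- function(spans, day) {
  any(spans$start_day <= day & spans$end_day >= day)
}

# Full brute-force cohort assignment for one dataset.
oracle_assign <- function(ds, cat_, bridge = 0) {
  out <- list()
  for (pid in ds$patients$patient_id) {
    claims <- ds$claims[ds$claims$patient_id == pid, , drop = FALSE]
    spans <- ds$enrollment[ds$enrollment$patient_id == pid, , drop = FALSE]
    ev <- o_events(claims, cat_)
    dx <- ev$dx

    dx_c <- if (!is.null(dx)) data.frame(day = dx$day, code = dx$code,
                                         category = dx$tier) else NULL
    px_c <- if (!is.null(ev$px)) data.frame(
      day = ev$px$day, code = ev$px$code,
      category = ifelse(ev$px$category == "genetic_test", "genetic_test",
                        "other_cpt_hcpcs")) else NULL
    idx_b <- o_pick_index(rbind(dx_c, px_c))
    idx_c <- o_pick_index(dx_c)

    two_sys <- !is.null(dx) &&
      length(unique(dx$organ[dx$anomaly])) >= 2
    mca_rows <- if (!is.null(dx)) dx[dx$mca_spec | dx$idde |
                                       (dx$anomaly & two_sys), , drop = FALSE]
    else NULL
    idx_m <- o_pick_index(
      if (!is.null(mca_rows) && nrow(mca_rows) > 0)
        data.frame(day = mca_rows$day, code = mca_rows$code,
                   category = mca_rows$tier) else NULL)

    has_gt <- !is.null(ev$px) && any(ev$px$category == "genetic_test")
    nicu_ever <- !is.null(ev$rv) &&
      any(ev$rv$unit == "NICU" &
            vapply(ev$rv$day, function(d) o_in_enrollment(spans, d),
                   logical(1)))

    in_broad <- !is.null(idx_b) && o_enrolled(spans, idx_b$day, bridge)
    over18 <- in_broad && idx_b$day > 18 * 365
    in_broad <- in_broad && !over18
    in_mca <- in_broad && !is.null(idx_m) &&
      o_enrolled(spans, idx_m$day, bridge)
    in_cons <- in_broad && !is.null(idx_c) &&
      idx_c$category %in% c("possible", "probable") && has_gt &&
      o_enrolled(spans, idx_c$day, bridge)

    population <- if (in_broad && idx_b$day <= 28 && nicu_ever) {
      "critically_ill_newborn"
    } else if (in_broad) {
      "pediatric"
    } else if (!ev$any_dx && !ev$any_px) {
      "control"
    } else "excluded"

    out[[pid]] <- data.frame(
      patient_id = pid, in_broad = in_broad, in_mca_id_dd_e = in_mca,
      in_conservative = in_cons, population = population,
      broad_index_day = if (in_broad) idx_b$day else NA_real_,
      broad_index_category = if (in_broad) idx_b$category else NA_character_)
  }
  do.call(rbind, out)
}

# --- matching oracles ---------------------------------------------------

o_signature <- function(units, rules) {
  keys <- character(nrow(units))
  for (i in seq_len(nrow(units))) {
    parts <- character()
    for (nm in names(rules)) {
      v <- units[[nm]][i]
      if (is.null(rules[[nm]])) {
        parts <- c(parts, as.character(v))
      } else {
        edges <- rules[[nm]]
        b <- sum(v >= edges) - 1
        b <- max(0, min(b, length(edges) - 2))
        parts <- c(parts, as.character(b))
      }
    }
    keys[i] <- paste(parts, collapse = "~")
  }
  keys
}

oracle_l1 <- function(cases, controls, rules) {
  kc <- o_signature(cases, rules)
  kk <- o_signature(controls, rules)
  tot <- 0
  for (key in union(unique(kc), unique(kk))) {
    tot <- tot + abs(mean(kc == key) - mean(kk == key))
  }
  tot / 2
}

oracle_pair_count <- function(cases, controls, rules) {
  kc <- o_signature(cases, rules)
  kk <- o_signature(controls, rules)
  tot <- 0
  for (key in intersect(unique(kc), unique(kk))) {
    tot <- tot + min(sum(kc == key), sum(kk == key))
  }
  tot
}

# --- outcome oracles ----------------------------------------------------

oracle_genetic_tests <- function(cohort, ds, cat_) {
  res <- list()
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]; idx <- cohort$index_day[i]
    claims <- ds$claims[ds$claims$patient_id == pid, , drop = FALSE]
    ev <- o_events(claims, cat_)
    pairs <- character()
    if (!is.null(ev$px)) {
      g <- ev$px[ev$px$category == "genetic_test" & ev$px$day >= idx, ,
                 drop = FALSE]
      pairs <- unique(paste(g$day, g$code))
      first_day <- if (nrow(g) > 0) min(g$day) else NA
    } else first_day <- NA
    res[[pid]] <- data.frame(patient_id = pid, n_tests = length(pairs),
                             days_to_first = if (length(pairs) > 0)
                               first_day - idx else NA_real_)
  }
  do.call(rbind, res)
}

oracle_nicu_days <- function(cohort, ds, cat_) {
  res <- numeric(nrow(cohort))
  picu <- logical(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    claims <- ds$claims[ds$claims$patient_id == pid, , drop = FALSE]
    spans <- ds$enrollment[ds$enrollment$patient_id == pid, , drop = FALSE]
    ev <- o_events(claims, cat_)
    if (!is.null(ev$rv)) {
      ok <- vapply(ev$rv$day, function(d) o_in_enrollment(spans, d),
                   logical(1))
      res[i] <- length(unique(ev$rv$day[ev$rv$unit == "NICU" & ok]))
      picu[i] <- any(ev$rv$unit == "PICU" & ok)
    }
  }
  data.frame(patient_id = cohort$patient_id, nicu_days = res,
             picu = picu)
}

oracle_transitions <- function(cohort, ds, cat_) {
  counts <- c(possible_to_probable = 0, possible_to_definite = 0,
              probable_to_definite = 0, genetic_test_to_definite = 0,
              other_cpt_hcpcs_to_definite = 0)
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    idx <- cohort$index_day[i]
    from <- cohort$index_category[i]
    claims <- ds$claims[ds$claims$patient_id == pid, , drop = FALSE]
    ev <- o_events(claims, cat_)
    dx <- ev$dx
    tiers <- if (!is.null(dx))
      unique(dx$tier[dx$pos == 1 & dx$day > idx]) else character()
    if (from == "possible" && "probable" %in% tiers) {
      counts["possible_to_probable"] <- counts["possible_to_probable"] + 1
    }
    if (from == "possible" && "definite" %in% tiers) {
      counts["possible_to_definite"] <- counts["possible_to_definite"] + 1
    }
    if (from == "probable" && "definite" %in% tiers) {
      counts["probable_to_definite"] <- counts["probable_to_definite"] + 1
    }
    if (from == "genetic_test" && "definite" %in% tiers) {
      counts["genetic_test_to_definite"] <-
        counts["genetic_test_to_definite"] + 1
    }
    if (from == "other_cpt_hcpcs" && "definite" %in% tiers) {
      counts["other_cpt_hcpcs_to_definite"] <-
        counts["other_cpt_hcpcs_to_definite"] + 1
    }
  }
  counts
}

oracle_cost_bins <- function(cohort, ds, n_bins) {
  out <- list()
  for (b in seq_len(n_bins) - 1) {
    n_contrib <- 0; sums <- c(total = 0, inpatient = 0, outpatient = 0)
    for (i in seq_len(nrow(cohort))) {
      pid <- cohort$patient_id[i]; idx <- cohort$index_day[i]
      lo <- idx + 30 * b; hi <- lo + 29
      spans <- ds$enrollment[ds$enrollment$patient_id == pid, , drop = FALSE]
      covered <- any(spans$start_day <= lo & spans$end_day >= hi)
      if (!covered) next
      n_contrib <- n_contrib + 1
      cls <- ds$claims[ds$claims$patient_id == pid &
                         ds$claims$service_day >= lo &
                         ds$claims$service_day <= hi, , drop = FALSE]
      sums["total"] <- sums["total"] + sum(cls$allowed_amount)
      sums["inpatient"] <- sums["inpatient"] +
        sum(cls$allowed_amount[cls$setting == "inpatient"])
      sums["outpatient"] <- sums["outpatient"] +
        sum(cls$allowed_amount[cls$setting == "outpatient"])
    }
    out[[b + 1]] <- data.frame(bin = b, n = n_contrib,
                               total = sums[["total"]],
                               inpatient = sums[["inpatient"]],
                               outpatient = sums[["outpatient"]])
  }
  do.call(rbind, out)
}
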