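#' Define a coarsening scheme for exact matching
#'
#' Each named argument is a covariate rule: `NULL` for a categorical
#' covariate (matched exactly on its raw value) or a strictly increasing
#' numeric vector of bin edges for a numeric covariate, binned half-open
#' `[edge_i, edge_{i+1})`, 0-based bin indices.
#'
#' @param ... Named covariate rules.
#' @return A `coarsening_scheme` object.
#' @examples
#' coarsening_scheme(sex = NULL, race_ethnicity = NULL,
#'                   age_years = c(0, 1, 5, 12, 19))
#' @export
coarsening_scheme <- function(...) {
  rules <- list(...)
  if (length(rules) == 0 || is.null(names(rules)) || any(names(rules) == "")) {
    abort("All coarsening rules must be named.")
  }
  for (nm in names(rules)) {
    r <- rules[[nm]]
    if (!is.null(r)) {
      if (!is.numeric(r) || length(r) < 2 || any(diff(r) <= 0)) {
        abort(paste0("Bin edges for `", nm,
                     "` must be strictly increasing and length >= 2."))
      }
    }
  }
  structure(rules, class = "coarsening_scheme")
}

#' Default matching covariates
#'
#' Race/ethnicity, sex, census division, birth year and number of children
#' in the household are matched exactly; for the pediatric population, age
#' at index is additionally coarsened into 0–1, 1–5, 5–12 and 12–19 year
#' bins.
#'
#' @param pediatric Include the age-at-index rule?
#' @return A `coarsening_scheme`.
#' @export
default_scheme <- function(pediatric = TRUE) {
  rules <- list(race_ethnicity = NULL, sex = NULL, census_division = NULL,
                birth_year = NULL, household_children = NULL)
  if (pediatric) rules$age_years <- c(0, 1, 5, 12, 19)
  do.call(coarsening_scheme, rules)
}

#' Coarsen units into exact-match signatures
#'
#' @param units Tibble with one row per unit carrying every covariate named
#'   in the scheme (missing values are an error).
#' @param scheme A [coarsening_scheme()].
#' @return `units` with an added `.signature` character column. Numeric
#'   values outside the outermost edges are assigned to the boundary bin
#'   with a warning.
#' @export
coarsen <- function(units, scheme) {
  stopifnot(inherits(scheme, "coarsening_scheme"))
  units <- as_tibble(units)
  miss <- setdiff(names(scheme), names(units))
  if (length(miss) > 0) {
    abort(paste0("Units are missing covariate(s): ",
                 paste(miss, collapse = ", ")))
  }
  parts <- lapply(names(scheme), function(nm) {
    x <- units[[nm]]
    if (any(is.na(x))) abort(paste0("Missing values in covariate `", nm, "`."))
    edges <- scheme[[nm]]
    if (is.null(edges)) return(as.character(x))
    idx <- findInterval(x, edges) - 1L   # half-open [edge_i, edge_{i+1})
    n_bins <- length(edges) - 1L
    out_of_range <- idx < 0L | idx > n_bins - 1L
    if (any(out_of_range)) {
      warn(paste0(sum(out_of_range), " value(s) of `", nm,
                  "` outside the outermost bin edges; assigned to the ",
                  "boundary bin."))
      idx <- pmin(pmax(idx, 0L), n_bins - 1L)
    }
    as.character(idx)
  })
  units$.signature <- do.call(paste, c(parts, sep = "\x1f"))
  units
}

#' L1 multivariate imbalance between two groups
#'
#' Half the summed absolute difference of the groups' relative frequencies
#' over the multivariate coarsened signature bins: 0 means perfectly
#' matched, 1 means completely unmatched (disjoint supports).
#'
#' @param cases,controls Tibbles of units (non-empty).
#' @param scheme A [coarsening_scheme()].
#' @return A number in `[0, 1]`.
#' @export
l1_imbalance <- function(cases, controls, scheme) {
  if (nrow(as_tibble(cases)) == 0 || nrow(as_tibble(controls)) == 0) {
    abort("Both groups must be non-empty.")
  }
  sc <- coarsen(cases, scheme)$.signature
  sk <- coarsen(controls, scheme)$.signature
  bins <- union(unique(sc), unique(sk))
  fc <- table(factor(sc, levels = bins)) / length(sc)
  fk <- table(factor(sk, levels = bins)) / length(sk)
  sum(abs(as.numeric(fc) - as.numeric(fk))) / 2
}

#' Coarsened exact matching with k-to-k (1:1) pruning
#'
#' Within each shared coarsened-signature stratum,
#' `min(n_cases, n_controls)` one-to-one pairs are formed by seeded uniform
#' random selection without replacement; cases in strata with no controls
#' (or in excess of the stratum's controls) are pruned. Matched pairs share
#' an identical coarsened signature, so the post-match L1 imbalance over
#' retained units is 0 and never exceeds the pre-match L1.
#'
#' @param cases,controls Tibbles of units with a `patient_id` column and the
#'   scheme covariates (non-empty).
#' @param scheme A [coarsening_scheme()].
#' @param seed Integer seed for within-stratum selection; results are
#'   deterministic for a fixed seed.
#' @return A `match_result`: list with `pairs` (tibble `case_id`,
#'   `control_id`, `signature`), `pruned_cases`, `pre_l1`, `post_l1`,
#'   `strata` (per-stratum counts) and `n` components. [tidy()] returns
#'   the pairs, [glance()] the one-row summary.
#' @export
cem_match_k2k <- function(cases, controls, scheme, seed = 1L) {
  cases <- as_tibble(cases); controls <- as_tibble(controls)
  if (nrow(cases) == 0 || nrow(controls) == 0) {
    abort("Both groups must be non-empty.")
  }
  stopifnot("patient_id" %in% names(cases),
            "patient_id" %in% names(controls))
  pre_l1 <- l1_imbalance(cases, controls, scheme)
  sc <- coarsen(cases, scheme)
  sk <- coarsen(controls, scheme)

  strata <- dplyr::full_join(
    sc |> count(.data$.signature, name = "n_cases"),
    sk |> count(.data$.signature, name = "n_controls"),
    by = ".signature") |>
    mutate(n_cases = dplyr::coalesce(.data$n_cases, 0L),
           n_controls = dplyr::coalesce(.data$n_controls, 0L),
           n_pairs = pmin(.data$n_cases, .data$n_controls)) |>
    arrange(.data$.signature)

  pairs <- with_seed(derive_seed(seed, "k2k"), {
    purrr::map_dfr(which(strata$n_pairs > 0), function(i) {
      sig <- strata$.signature[i]
      k <- strata$n_pairs[i]
      case_ids <- sc$patient_id[sc$.signature == sig]
      control_ids <- sk$patient_id[sk$.signature == sig]
      tibble(case_id = sort(case_ids)[sample.int(length(case_ids))][seq_len(k)],
             control_id = sort(control_ids)[
               sample.int(length(control_ids))][seq_len(k)],
             signature = sig)
    })
  })
  if (nrow(pairs) == 0) {
    pairs <- tibble(case_id = character(), control_id = character(),
                    signature = character())
  }
  pruned <- setdiff(cases$patient_id, pairs$case_id)
  post_l1 <- if (nrow(pairs) > 0) {
    l1_imbalance(sc[sc$patient_id %in% pairs$case_id, , drop = FALSE],
                 sk[sk$patient_id %in% pairs$control_id, , drop = FALSE],
                 scheme)
  } else NA_real_

  structure(
    list(pairs = pairs, pruned_cases = pruned, pre_l1 = pre_l1,
         post_l1 = post_l1,
         strata = strata |> rename(signature = ".signature"),
         n_cases = nrow(cases), n_controls = nrow(controls), seed = seed),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result: coarsened exact matching, k-to-k>\n")
  cat("  cases: ", x$n_cases, "  controls: ", x$n_controls,
      "  pairs: ", nrow(x$pairs), "  pruned cases: ",
      length(x$pruned_cases), "\n", sep = "")
  cat(sprintf("  L1 imbalance: %.4f (pre) -> %s (post)\n", x$pre_l1,
              ifelse(is.na(x$post_l1), "NA", sprintf("%.4f", x$post_l1))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname cem_match_k2k
#' @param x A `match_result`.
#' @method tidy match_result
#' @export
tidy.match_result <- function(x, ...) x$pairs

#' @rdname cem_match_k2k
#' @method glance match_result
#' @export
glance.match_result <- function(x, ...) {
  tibble(n_cases = x$n_cases, n_controls = x$n_controls,
         n_pairs = nrow(x$pairs), n_pruned_cases = length(x$pruned_cases),
         n_strata = nrow(x$strata), pre_l1 = x$pre_l1, post_l1 = x$post_l1)
}
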