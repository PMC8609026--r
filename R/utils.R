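#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join semi_join distinct n bind_rows rename
#'   row_number first slice across all_of if_else count pull relocate
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats rbinom rgeom rlnorm rpois runif setNames t.test rexp
NULL

# Normalize a billing code for exact matching: uppercase, periods and
# surrounding whitespace stripped.  "q24.9" and "Q249" are the same code.
normalize_code <- function(code) {
  toupper(gsub(".", "", trimws(as.character(code)), fixed = TRUE))
}

# Percent formatting used throughout the reporting layer: one decimal,
# half rounded away from zero (matches the convention of printed claims
# tables, where 44.672 renders as 44.7 and 0.25 as 0.3).
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

pct <- function(num, den, digits = 1) {
  ifelse(den > 0, round_half_away(100 * num / den, digits), NA_real_)
}

# Per-stage seed derivation: every stage draws from a distinct stream that is
# a pure function of (root seed, stage label), so stages can be re-run in any
# order without perturbing each other.  Kept below 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h) %% .Machine$integer.max)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

is_flag <- function(x) is.logical(x) && length(x) == 1 && !is.na(x)

assert_flag <- function(x, name) {
  if (!is_flag(x)) abort(paste0("`", name, "` must be TRUE or FALSE."))
  invisible(x)
}
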