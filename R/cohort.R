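# Cohort file dialect, validation, and the exclusion cascade.

COHORT_COLUMNS <- c("id", "sex", "race", "age", "ldl", "hdl", "sbp", "dbp",
                    "smoker", "diabetes", "crp", "g9p21", "kif6",
                    "prior_mi", "prior_stroke", "followup_years", "mi_event")

# Fields that must be non-missing for a row to enter the analysis
# (everything needed to compute the risk score and the three markers,
# plus the outcome).
MODEL_FIELDS <- c("sex", "age", "ldl", "hdl", "sbp", "dbp", "smoker",
                  "diabetes", "crp", "g9p21", "kif6", "followup_years",
                  "mi_event")

#' Read a participant cohort file
#'
#' Comma-delimited text, one header row, columns exactly
#' `id, sex, race, age, ldl, hdl, sbp, dbp, smoker, diabetes, crp, g9p21,
#' kif6, prior_mi, prior_stroke, followup_years, mi_event`. Booleans are
#' 0/1; missing values are empty fields. Types and ranges are validated;
#' structural violations (wrong columns, non-numeric measurements,
#' out-of-range values) are errors, while missing fields are kept as `NA`
#' for [apply_exclusions()] to handle.
#'
#' @param path File path.
#' @return Data frame with the columns above; `smoker`, `diabetes`,
#'   `prior_mi`, `prior_stroke`, `mi_event` as logical, `g9p21`/`kif6` as
#'   integer allele counts.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  validate_cohort(raw)
}

#' Write a participant cohort file
#'
#' Inverse of [read_cohort()]: logical columns are written as 0/1, missing
#' values as empty fields. Valid rows round-trip exactly.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[COHORT_COLUMNS]
  for (b in c("smoker", "diabetes", "prior_mi", "prior_stroke", "mi_event")) {
    out[[b]] <- as.integer(out[[b]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate a cohort data frame
#'
#' @param cohort Candidate data frame.
#' @return The cohort with canonical column types, or an error.
#' @export
validate_cohort <- function(cohort) {
  if (!identical(sort(names(cohort)), sort(COHORT_COLUMNS))) {
    stop("cohort must have columns exactly: ",
         paste(COHORT_COLUMNS, collapse = ", "), call. = FALSE)
  }
  cohort <- cohort[COHORT_COLUMNS]
  cohort$id <- as.character(cohort$id)
  ok_level <- function(x, levels, name) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) stop("invalid ", name, ": ",
                       paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    x
  }
  cohort$sex <- ok_level(cohort$sex, c("male", "female"), "sex")
  cohort$race <- ok_level(cohort$race, c("white", "black", "other"), "race")
  num_range <- function(col, lo, hi) {
    x <- cohort[[col]]
    if (!is.numeric(x)) stop("column '", col, "' must be numeric",
                             call. = FALSE)
    bad <- !is.na(x) & (!is.finite(x) | x < lo | x > hi)
    if (any(bad)) stop("column '", col, "' out of range [", lo, ", ", hi,
                       "]", call. = FALSE)
    as.numeric(x)
  }
  cohort$age <- num_range("age", 65, 120)
  cohort$ldl <- num_range("ldl", 1, 1000)
  cohort$hdl <- num_range("hdl", 1, 500)
  cohort$sbp <- num_range("sbp", 50.001, 299.999)
  cohort$dbp <- num_range("dbp", 20.001, 199.999)
  cohort$crp <- num_range("crp", 0, Inf)
  cohort$followup_years <- num_range("followup_years", 0, Inf)
  for (g in c("g9p21", "kif6")) {
    x <- cohort[[g]]
    if (!all(is.na(x) | x %in% 0:2)) {
      stop("column '", g, "' must hold allele counts 0/1/2", call. = FALSE)
    }
    cohort[[g]] <- as.integer(x)
  }
  for (b in c("smoker", "diabetes", "prior_mi", "prior_stroke", "mi_event")) {
    x <- cohort[[b]]
    if (!all(is.na(x) | x %in% c(0, 1, TRUE, FALSE))) {
      stop("column '", b, "' must be boolean 0/1", call. = FALSE)
    }
    cohort[[b]] <- as.logical(x)
  }
  cohort
}

#' Apply the analysis exclusion cascade
#'
#' Removes participants with a baseline history of MI, a baseline history of
#' stroke, race recorded as neither white nor black, or missing data in any
#' model field (risk-score covariates, markers, outcome). The rules overlap:
#' a row violating several counts once in the union but appears in each
#' per-rule tally. Filtering is order-independent.
#'
#' @param cohort Validated cohort data frame.
#' @return List with `cohort` (retained rows) and `ledger`, an
#'   `exclusion_ledger` holding per-rule counts, the union count and
#'   n before/after.
#' @export
apply_exclusions <- function(cohort) {
  flag <- function(x) !is.na(x) & x
  excl <- list(
    baseline_mi     = flag(cohort$prior_mi),
    baseline_stroke = flag(cohort$prior_stroke),
    race_other      = !is.na(cohort$race) & cohort$race == "other",
    missing_fields  = Reduce(`|`, lapply(cohort[MODEL_FIELDS], is.na)) |
                      is.na(cohort$race) | is.na(cohort$prior_mi) |
                      is.na(cohort$prior_stroke)
  )
  drop <- Reduce(`|`, excl)
  ledger <- structure(
    list(counts = vapply(excl, sum, integer(1)),
         n_initial = nrow(cohort),
         n_excluded = sum(drop),
         n_final = nrow(cohort) - sum(drop)),
    class = "exclusion_ledger")
  kept <- cohort[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) stop("exclusions removed every participant",
                             call. = FALSE)
  rownames(kept) <- NULL
  list(cohort = kept, ledger = ledger)
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("Exclusion cascade:", x$n_initial, "->", x$n_final,
      "participants\n")
  for (r in names(x$counts)) {
    cat(sprintf("  %-16s %d\n", r, x$counts[[r]]))
  }
  cat("  union excluded  ", x$n_excluded, "\n")
  invisible(x)
}
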