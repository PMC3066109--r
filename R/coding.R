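# Framingham-style covariate coding: category bins, reference levels, and
# the per-participant design coding used by the Cox models.

LDL_LEVELS <- c("<100", "100-129", "130-159", "160-189", ">=190")
HDL_LEVELS <- c("<35", "35-44", "45-49", "50-59", ">=60")
BP_LEVELS  <- c("optimal", "normal", "high-normal", "HTN-I", "HTN-II-IV")

LDL_REF <- "100-129"
BP_REF  <- "normal"

#' Reference HDL category for a sex
#'
#' The HDL reference band is sex-specific: 45-49 mg/dL for men, 50-59 mg/dL
#' for women, matching the bands in which the respective sex means fall.
#'
#' @param sex "male" or "female".
#' @return A single HDL category label.
#' @export
hdl_reference <- function(sex) {
  sex <- match.arg(sex, c("male", "female"))
  if (sex == "male") "45-49" else "50-59"
}

#' Categorize LDL cholesterol
#'
#' Half-open, left-closed bins: [0,100), [100,130), [130,160), [160,190),
#' [190, Inf). The 100-129 band is the model reference.
#'
#' @param ldl LDL-C in mg/dL; finite and positive.
#' @return Factor with levels `<100`, `100-129`, `130-159`, `160-189`,
#'   `>=190`.
#' @export
categorize_ldl <- function(ldl) {
  check_measurement(ldl, "ldl", lower = 0)
  factor(LDL_LEVELS[findInterval(ldl, c(100, 130, 160, 190)) + 1L],
         levels = LDL_LEVELS)
}

#' Categorize HDL cholesterol
#'
#' Bins [0,35), [35,45), [45,50), [50,60), [60, Inf), left-closed. The bin
#' itself does not depend on sex; sex only selects which bin is the model
#' reference (see [hdl_reference()]).
#'
#' @param hdl HDL-C in mg/dL; finite and positive.
#' @return Factor with levels `<35`, `35-44`, `45-49`, `50-59`, `>=60`.
#' @export
categorize_hdl <- function(hdl) {
  check_measurement(hdl, "hdl", lower = 0)
  factor(HDL_LEVELS[findInterval(hdl, c(35, 45, 50, 60)) + 1L],
         levels = HDL_LEVELS)
}

#' Categorize blood pressure (JNC-V bands)
#'
#' SBP bands <120, 120-129, 130-139, 140-159, >=160 mmHg and DBP bands
#' <80, 80-84, 85-89, 90-99, >=100 mmHg each imply a category
#' (optimal, normal, high-normal, HTN-I, HTN-II-IV); the participant is
#' assigned the HIGHER of the two. "Normal" is the model reference.
#'
#' @param sbp Systolic pressure, mmHg; must lie in (50, 300).
#' @param dbp Diastolic pressure, mmHg; must lie in (20, 200).
#' @return Factor with levels `optimal`, `normal`, `high-normal`, `HTN-I`,
#'   `HTN-II-IV`.
#' @export
categorize_bp <- function(sbp, dbp) {
  check_measurement(sbp, "sbp", lower = 50, upper = 300)
  check_measurement(dbp, "dbp", lower = 20, upper = 200)
  cs <- findInterval(sbp, c(120, 130, 140, 160)) + 1L
  cd <- findInterval(dbp, c(80, 85, 90, 100)) + 1L
  factor(BP_LEVELS[pmax(cs, cd)], levels = BP_LEVELS)
}

check_measurement <- function(x, name, lower, upper = Inf) {
  bad <- !is.finite(x) | x <= lower | x >= upper
  if (any(bad)) {
    stop("invalid measurement for '", name, "': ",
         paste(utils::head(format(x[bad]), 3L), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Code a cohort's covariates for Cox modelling
#'
#' Applies the Framingham category coders, codes the SNP markers (additive
#' allele count for the 9p21.3-style SNP, dominant carrier indicator for the
#' KIF6-style SNP) and scales the biomarker per a supplied standard
#' deviation so its coefficient is per-SD.
#'
#' @param cohort Data frame of participants (see [read_cohort()] for the
#'   column contract); no missing values in model fields.
#' @param sd_crp Positive scalar: the standard deviation used to scale CRP
#'   (normally the sex-specific sample SD, see [crp_sd()]).
#' @return Data frame of coded covariates: `age`, `smoker`, `diabetes`,
#'   `ldl_cat`, `hdl_cat`, `bp_cat`, `crp_per_sd`, `g9p21_additive`,
#'   `kif6_dominant`, carrying `id` and `sex` along.
#' @export
code_covariates <- function(cohort, sd_crp) {
  if (!is.numeric(sd_crp) || length(sd_crp) != 1L || !is.finite(sd_crp) ||
      sd_crp <= 0) {
    stop("degenerate CRP scale: sd_crp must be a positive finite scalar",
         call. = FALSE)
  }
  fields <- c("age", "ldl", "hdl", "sbp", "dbp", "smoker", "diabetes",
              "crp", "g9p21", "kif6")
  miss <- vapply(cohort[fields], function(v) any(is.na(v)), logical(1))
  if (any(miss)) {
    stop("missing values in model fields: ",
         paste(fields[miss], collapse = ", "),
         "; remove incomplete rows first (see apply_exclusions)",
         call. = FALSE)
  }
  if (!all(cohort$g9p21 %in% 0:2) || !all(cohort$kif6 %in% 0:2)) {
    stop("allele counts must be 0, 1 or 2", call. = FALSE)
  }
  data.frame(
    id             = cohort$id,
    sex            = cohort$sex,
    age            = cohort$age,
    smoker         = as.integer(cohort$smoker),
    diabetes       = as.integer(cohort$diabetes),
    ldl_cat        = categorize_ldl(cohort$ldl),
    hdl_cat        = categorize_hdl(cohort$hdl),
    bp_cat         = categorize_bp(cohort$sbp, cohort$dbp),
    crp_per_sd     = cohort$crp / sd_crp,
    g9p21_additive = as.integer(cohort$g9p21),
    kif6_dominant  = as.integer(cohort$kif6 >= 1L),
    stringsAsFactors = FALSE
  )
}

#' Sex-specific sample SD of CRP
#'
#' @param cohort Participant data frame.
#' @param sex "male" or "female".
#' @return The sample standard deviation of `crp` within that sex.
#' @export
crp_sd <- function(cohort, sex) {
  sex <- match.arg(sex, c("male", "female"))
  x <- cohort$crp[cohort$sex == sex]
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least 2 CRP values to estimate an SD",
                           call. = FALSE)
  stats::sd(x)
}

# Names of the marker design columns, in report order.
MARKER_COLS <- c("g9p21_additive", "kif6_dominant", "crp_per_sd")

#' Build the Cox design matrix from coded covariates
#'
#' Expands the categorical factors into treatment-contrast indicator columns
#' against the model reference levels (LDL 100-129, BP normal, HDL
#' sex-specific) and appends any requested marker columns. All rows must be
#' of one sex, since the HDL reference differs by sex and models are fit
#' separately.
#'
#' @param coded Output of [code_covariates()], a single sex.
#' @param markers Character vector, subset of
#'   `c("g9p21_additive", "kif6_dominant", "crp_per_sd")`; the marker
#'   columns appended after the Framingham block. Default none (base model).
#' @return Numeric matrix, one row per participant.
#' @export
build_design <- function(coded, markers = character(0)) {
  stopifnot(all(markers %in% MARKER_COLS))
  sexes <- unique(coded$sex)
  if (length(sexes) != 1L) {
    stop("design matrix is sex-specific; got rows for: ",
         paste(sexes, collapse = ", "), call. = FALSE)
  }
  dummies <- function(f, ref, prefix) {
    lev <- setdiff(levels(f), ref)
    m <- vapply(lev, function(l) as.numeric(f == l), numeric(length(f)))
    m <- matrix(m, nrow = length(f),
                dimnames = list(NULL, paste0(prefix, lev)))
    m
  }
  x <- cbind(
    age      = coded$age,
    smoker   = coded$smoker,
    diabetes = coded$diabetes,
    dummies(coded$ldl_cat, LDL_REF, "ldl"),
    dummies(coded$hdl_cat, hdl_reference(sexes), "hdl"),
    dummies(coded$bp_cat, BP_REF, "bp")
  )
  for (m in markers) {
    x <- cbind(x, coded[[m]])
    colnames(x)[ncol(x)] <- m
  }
  x
}
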