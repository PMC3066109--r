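# Synthetic elderly-cohort generator: covariate marginals matching the
# study's baseline table, Hardy-Weinberg genotypes, lognormal CRP, and an
# exponential event/death/administrative-censoring follow-up process with
# configurable true hazard ratios.

#' Simulation configuration
#'
#' Defaults reproduce the white analysis cohort's marginal structure: sample
#' sizes 1495 men / 2156 women; age 73.3 (5.7) and 72.3 (5.4) years;
#' current smoking 10% / 12%; diabetes 13% / 8%; LDL 124 (33) / 135 (37)
#' and HDL 48 (13) / 59 (16) mg/dL; a lognormal CRP whose parameters put
#' 26% of the population above 3 mg/L; allele frequencies 0.5 (9p21.3-like
#' SNP) and 0.408 (KIF6-like SNP), back-solved under Hardy-Weinberg from
#' carrier fractions of 75% and 65%. True marker hazard ratios default to
#' the sex-specific estimates of the motivating analysis (men: 1.22 per
#' allele, 1.42 for carriers, 1.28 per CRP SD; women: 1.16, 1.05, 1.15).
#' The event process is exponential with the stated baseline hazard for the
#' mean-covariate participant; death is an independent exponential
#' competing censoring process, and follow-up is administratively censored.
#'
#' @param n_male,n_female Cohort sizes per sex.
#' @param age_mean,age_sd Target observed mean/SD of age per sex
#'   (c(male, female)); ages are truncated below at 65 (study entry) and
#'   the latent mean is shifted so the observed mean hits the target.
#' @param smoking,diabetes Prevalences per sex.
#' @param ldl_mean,ldl_sd,hdl_mean,hdl_sd Lipid marginals, mg/dL, per sex.
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd Blood-pressure marginals, mmHg,
#'   per sex.
#' @param crp_meanlog,crp_sdlog Lognormal CRP parameters (mg/L scale).
#' @param q9p21,qkif6 Risk-allele frequencies.
#' @param hr_9p21,hr_kif6,hr_crp True marker hazard ratios per sex
#'   (per allele, carrier vs non-carrier, per sample SD).
#' @param hr_age,hr_diabetes True hazard ratios for the non-marker signal
#'   (per year of age; diabetes yes/no).
#' @param base_hazard Baseline MI hazard, events/person-year, for the
#'   mean-covariate participant, per sex.
#' @param death_rate Death (competing censoring) rate, events/person-year.
#' @param censor_years Administrative censoring time, years.
#' @param p_black,p_prior_mi,p_prior_stroke,p_missing_crp Optional
#'   contamination knobs (all default 0) to exercise the exclusion cascade:
#'   probability of black race, baseline MI, baseline stroke, missing CRP.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_male = 1495, n_female = 2156,
                       age_mean = c(73.3, 72.3), age_sd = c(5.7, 5.4),
                       smoking = c(0.10, 0.12), diabetes = c(0.13, 0.08),
                       ldl_mean = c(124, 135), ldl_sd = c(33, 37),
                       hdl_mean = c(48, 59), hdl_sd = c(13, 16),
                       sbp_mean = c(135, 134), sbp_sd = c(21, 21),
                       dbp_mean = c(71, 70), dbp_sd = c(11, 11),
                       crp_meanlog = 0.4553, crp_sdlog = 1.0,
                       q9p21 = 0.5, qkif6 = 0.408,
                       hr_9p21 = c(1.22, 1.16), hr_kif6 = c(1.42, 1.05),
                       hr_crp = c(1.28, 1.15),
                       hr_age = c(1.044, 1.044),
                       hr_diabetes = c(exp(0.57), exp(0.66)),
                       base_hazard = c(0.010, 0.006),
                       death_rate = 0.045, censor_years = 16.5,
                       p_black = 0, p_prior_mi = 0, p_prior_stroke = 0,
                       p_missing_crp = 0) {
  two <- function(x, nm) {
    x <- rep_len(as.numeric(x), 2L)
    if (any(!is.finite(x))) stop("invalid config field: ", nm, call. = FALSE)
    stats::setNames(x, c("male", "female"))
  }
  cfg <- list(
    n = stats::setNames(c(n_male, n_female), c("male", "female")),
    age_mean = two(age_mean, "age_mean"), age_sd = two(age_sd, "age_sd"),
    smoking = two(smoking, "smoking"), diabetes = two(diabetes, "diabetes"),
    ldl_mean = two(ldl_mean, "ldl_mean"), ldl_sd = two(ldl_sd, "ldl_sd"),
    hdl_mean = two(hdl_mean, "hdl_mean"), hdl_sd = two(hdl_sd, "hdl_sd"),
    sbp_mean = two(sbp_mean, "sbp_mean"), sbp_sd = two(sbp_sd, "sbp_sd"),
    dbp_mean = two(dbp_mean, "dbp_mean"), dbp_sd = two(dbp_sd, "dbp_sd"),
    crp_meanlog = crp_meanlog, crp_sdlog = crp_sdlog,
    q9p21 = q9p21, qkif6 = qkif6,
    hr_9p21 = two(hr_9p21, "hr_9p21"), hr_kif6 = two(hr_kif6, "hr_kif6"),
    hr_crp = two(hr_crp, "hr_crp"), hr_age = two(hr_age, "hr_age"),
    hr_diabetes = two(hr_diabetes, "hr_diabetes"),
    base_hazard = two(base_hazard, "base_hazard"),
    death_rate = death_rate, censor_years = censor_years,
    p_black = p_black, p_prior_mi = p_prior_mi,
    p_prior_stroke = p_prior_stroke, p_missing_crp = p_missing_crp
  )
  probs <- c(cfg$smoking, cfg$diabetes, q9p21, qkif6, p_black, p_prior_mi,
             p_prior_stroke, p_missing_crp)
  if (any(probs < 0 | probs > 1)) {
    stop("prevalences and allele frequencies must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(c(cfg$base_hazard, death_rate) < 0) || censor_years <= 0 ||
      any(cfg$n < 1)) {
    stop("rates must be >= 0, censor_years > 0 and cohort sizes >= 1",
         call. = FALSE)
  }
  if (any(c(cfg$age_sd, cfg$ldl_sd, cfg$hdl_sd, cfg$sbp_sd, cfg$dbp_sd,
            crp_sdlog) <= 0)) {
    stop("scale parameters must be positive", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Truncated normal via inverse-CDF sampling.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Latent mean such that the mean of a normal truncated below at `lower`
# equals `target`.
latent_mean_for_truncated <- function(target, sd, lower) {
  f <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a)) - target
  }
  stats::uniroot(f, c(target - 4 * sd, target + sd))$root
}

#' Draw genotypes in Hardy-Weinberg proportions
#'
#' Allele counts 0/1/2 with probabilities (1-q)^2, 2q(1-q), q^2 -- i.e.
#' binomial(2, q).
#'
#' @param q Risk-allele frequency in [0, 1].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Integer vector of allele counts.
#' @export
hardy_weinberg_draw <- function(q, n, seed = NULL) {
  stopifnot(q >= 0, q <= 1, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(n, 2L, q)
}

#' Generate a synthetic cohort
#'
#' Covariates are drawn independently per the configuration (truncated
#' normals for age, lipids and blood pressure; Bernoulli smoking/diabetes;
#' Hardy-Weinberg genotypes; lognormal CRP). The MI event time is
#' exponential with rate `base_hazard * exp(lp)` where the linear predictor
#' applies the configured true log-hazard-ratios to the mean-centered
#' marker and non-marker signal columns (CRP entering per within-sex sample
#' SD, the KIF6-like SNP as a carrier indicator, the 9p21.3-like SNP as an
#' allele count). Death is an independent exponential time; follow-up is
#' the minimum of event, death and administrative censoring, and
#' `mi_event` marks whether the MI came first. Measurements are rounded to
#' realistic precision (integer mmHg and mg/dL, CRP to 0.001 mg/L).
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   cohorts.
#' @param sex "all" (default), "male" or "female": which strata to draw.
#' @return Cohort data frame in the standard column layout (see
#'   [read_cohort()]).
#' @export
generate_cohort <- function(config, seed = NULL,
                            sex = c("all", "male", "female")) {
  stopifnot(inherits(config, "sim_config"))
  sex <- match.arg(sex)
  if (!is.null(seed)) set.seed(seed)
  sexes <- if (sex == "all") c("male", "female") else sex
  out <- lapply(sexes, function(sx) generate_sex(config, sx))
  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  cohort
}

generate_sex <- function(cfg, sx) {
  n <- cfg$n[[sx]]
  mu_age <- latent_mean_for_truncated(cfg$age_mean[[sx]], cfg$age_sd[[sx]], 65)
  age <- round(rtnorm(n, mu_age, cfg$age_sd[[sx]], lower = 65, upper = 110), 1)
  ldl <- round(rtnorm(n, cfg$ldl_mean[[sx]], cfg$ldl_sd[[sx]], 30, 400))
  hdl <- round(rtnorm(n, cfg$hdl_mean[[sx]], cfg$hdl_sd[[sx]], 10, 150))
  sbp <- round(rtnorm(n, cfg$sbp_mean[[sx]], cfg$sbp_sd[[sx]], 90, 250))
  dbp <- round(rtnorm(n, cfg$dbp_mean[[sx]], cfg$dbp_sd[[sx]], 40, 130))
  smoker <- stats::rbinom(n, 1L, cfg$smoking[[sx]]) == 1L
  diabetes <- stats::rbinom(n, 1L, cfg$diabetes[[sx]]) == 1L
  crp <- round(stats::rlnorm(n, cfg$crp_meanlog, cfg$crp_sdlog), 3)
  g9p21 <- hardy_weinberg_draw(cfg$q9p21, n)
  kif6 <- hardy_weinberg_draw(cfg$qkif6, n)

  center <- function(x) x - mean(x)
  lp <- log(cfg$hr_age[[sx]]) * center(age) +
        log(cfg$hr_diabetes[[sx]]) * center(as.numeric(diabetes)) +
        log(cfg$hr_9p21[[sx]]) * center(g9p21) +
        log(cfg$hr_kif6[[sx]]) * center(as.numeric(kif6 >= 1L)) +
        log(cfg$hr_crp[[sx]]) * center(crp / stats::sd(crp))
  rate <- cfg$base_hazard[[sx]] * exp(lp)
  t_mi <- rep(Inf, n)
  t_mi[rate > 0] <- stats::rexp(sum(rate > 0), rate[rate > 0])
  t_death <- if (cfg$death_rate > 0) stats::rexp(n, cfg$death_rate) else
    rep(Inf, n)
  followup <- pmin(t_mi, t_death, cfg$censor_years)
  mi_event <- t_mi <= followup

  race <- ifelse(stats::runif(n) < cfg$p_black, "black", "white")
  prior_mi <- stats::runif(n) < cfg$p_prior_mi
  prior_stroke <- stats::runif(n) < cfg$p_prior_stroke
  crp[stats::runif(n) < cfg$p_missing_crp] <- NA_real_

  data.frame(
    id = sprintf("%s%05d", if (sx == "male") "M" else "F", seq_len(n)),
    sex = sx, race = race, age = age, ldl = ldl, hdl = hdl,
    sbp = sbp, dbp = dbp, smoker = smoker, diabetes = diabetes,
    crp = crp, g9p21 = g9p21, kif6 = kif6,
    prior_mi = prior_mi, prior_stroke = prior_stroke,
    followup_years = round(followup, 4), mi_event = mi_event,
    stringsAsFactors = FALSE
  )
}

#' Calibrate the follow-up process to a target median time at risk
#'
#' Bisects the death (competing censoring) rate until cohorts of size `n`
#' have the target median follow-up. If the target is unreachable even with
#' no deaths because the administrative censoring time is too short, the
#' censoring time is first extended. Each evaluation averages the medians
#' of `reps` independent cohorts to push the Monte-Carlo error of the
#' estimated median well below `tol`, and uses common random numbers (the
#' same seed block at every death rate) so the evaluated median is monotone
#' in the death rate and bisection converges.
#'
#' @param config A [sim_config()].
#' @param target_median Target median time at risk, years (default 12.6).
#' @param n Cohort size per evaluation (split across sexes in the config's
#'   proportions); default 10000.
#' @param seed Base seed for the common-random-number evaluations.
#' @param tol Convergence tolerance on the median, years.
#' @param reps Cohort replicates averaged per evaluation.
#' @return The config with `death_rate` (and possibly `censor_years`)
#'   adjusted.
#' @export
calibrate_followup <- function(config, target_median = 12.6, n = 10000,
                               seed = 1, tol = 0.04, reps = 20L) {
  stopifnot(inherits(config, "sim_config"), target_median > 0)
  prop_m <- config$n[["male"]] / sum(config$n)
  sized <- function(cfg) {
    cfg$n <- stats::setNames(
      c(round(n * prop_m), n - round(n * prop_m)), c("male", "female"))
    cfg
  }
  med_at <- function(cfg, rate) {
    cfg$death_rate <- rate
    cfg <- sized(cfg)
    mean(vapply(seq_len(reps), function(r) {
      stats::median(generate_cohort(cfg, seed = seed + r - 1L)$followup_years)
    }, numeric(1)))
  }
  cfg <- config
  if (med_at(cfg, 0) < target_median - tol) {
    cfg$censor_years <- max(cfg$censor_years, 2 * target_median)
    if (med_at(cfg, 0) < target_median - tol) {
      stop("calibration failure: target median unreachable", call. = FALSE)
    }
  }
  lo <- 0
  hi <- 1
  if (med_at(cfg, hi) > target_median + tol) {
    stop("calibration failure: median above target even at death rate 1",
         call. = FALSE)
  }
  for (i in seq_len(60L)) {
    mid <- (lo + hi) / 2
    m <- med_at(cfg, mid)
    if (abs(m - target_median) <= tol) {
      cfg$death_rate <- mid
      return(cfg)
    }
    if (m > target_median) lo <- mid else hi <- mid
  }
  stop("calibration failure: bisection did not converge", call. = FALSE)
}

#' Write a simulated cohort with provenance
#'
#' Writes the cohort CSV plus an adjacent `<path>.provenance.json` echoing
#' the seed and full configuration.
#'
#' @param config A [sim_config()].
#' @param path Output CSV path.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
simulate_to_file <- function(config, path, seed) {
  cohort <- generate_cohort(config, seed = seed)
  write_cohort(cohort, path)
  jsonlite::write_json(
    list(seed = seed, config = unclass(config)),
    paste0(path, ".provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
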