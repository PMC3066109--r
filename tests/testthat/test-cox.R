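test_that("log partial likelihood at beta = 0 matches the hand-computed product", {
  # 4 subjects, all events at distinct times: risk sets shrink 4,3,2,1 and
  # at beta = 0 each event's probability is uniform on its risk set
  x <- matrix(c(1, 0, 1, 0), ncol = 1)
  fit <- fit_cox(x, time = 1:4, event = rep(TRUE, 4))
  expect_equal(fit$loglik_null, log(1 / 4 * 1 / 3 * 1 / 2), tolerance = 1e-12)
  expect_equal(loglik_brute(0, x, 1:4, rep(TRUE, 4)), log(1 / 24),
               tolerance = 1e-12)
})

test_that("beta-hat matches a grid/numeric search of the explicit partial likelihood", {
  x <- matrix(c(1, 0, 1, 0), ncol = 1)
  tm <- 1:4
  ev <- rep(TRUE, 4)
  fit <- fit_cox(x, tm, ev)
  opt <- optimize(function(b) loglik_brute(b, x, tm, ev),
                  c(-5, 5), maximum = TRUE, tol = 1e-9)
  expect_equal(unname(fit$beta), opt$maximum, tolerance = 1e-6)
  expect_equal(fit$loglik, opt$objective, tolerance = 1e-10)
  # the score is numerically zero at the optimum: nudging beta lowers loglik
  expect_lt(loglik_brute(fit$beta + 1e-4, x, tm, ev), fit$loglik)
  expect_lt(loglik_brute(fit$beta - 1e-4, x, tm, ev), fit$loglik)
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("fit agrees with survival::coxph (Breslow ties) on random small data", {
  skip_if_not_installed("survival")
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(10:30, 1)
    p <- sample(1:3, 1)
    x <- matrix(rnorm(n * p), n, p)
    tm <- round(rexp(n), 1) + 0.05        # induces ties
    ev <- runif(n) < 0.6
    if (!any(ev)) ev[1] <- TRUE
    fit <- fit_cox(x, tm, ev)
    ref <- survival::coxph(survival::Surv(tm, ev) ~ x, ties = "breslow")
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-5)
    expect_equal(unname(fit$var), unname(vcov(ref)), tolerance = 1e-5)
    expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-7)
  }
})

test_that("degenerate designs are rejected with informative errors", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_cox(cbind(x, x[, 1]), time = 1:10,
                       event = rep(c(TRUE, FALSE), 5)), "rank-deficient")
  expect_error(fit_cox(x, 1:10, rep(FALSE, 10)), "no events")
  # perfect separation: the exposed group has all events strictly earlier,
  # so the likelihood is monotone in beta; on this covariate scale the
  # estimate runs past the magnitude guard
  xs <- matrix(rep(c(0.05, 0), each = 6), ncol = 1)
  tms <- c(1:6, 101:106)
  evs <- rep(TRUE, 12)
  expect_error(fit_cox(xs, tms, evs), "separation")
})

test_that("hazard_ratio_ci reproduces printed HR/CI round trips", {
  fake <- structure(list(beta = c(marker = 0.3507),
                         var = matrix(0.1261^2, 1, 1)), class = "cox_fit")
  ci <- hazard_ratio_ci(fake, "marker")
  expect_equal(round(ci$hr, 2), 1.42)
  expect_equal(round(ci$ci_low, 2), 1.11)
  expect_equal(round(ci$ci_high, 2), 1.82)
  expect_lt(ci$p, 0.01)
  # null coefficient: HR 1, CI straddles 1
  fake0 <- structure(list(beta = c(m = 0), var = matrix(0.25, 1, 1)),
                     class = "cox_fit")
  ci0 <- hazard_ratio_ci(fake0, 1)
  expect_equal(ci0$hr, 1)
  expect_true(ci0$ci_low < 1 && ci0$ci_high > 1)
  expect_equal(ci0$p, 1)
  # closed form at beta = ln 2, se = 0.5
  fake2 <- structure(list(beta = c(m = log(2)), var = matrix(0.25, 1, 1)),
                     class = "cox_fit")
  ci2 <- hazard_ratio_ci(fake2, "m")
  expect_equal(ci2$ci_low, 2 * exp(-qnorm(0.975) * 0.5), tolerance = 1e-12)
  expect_equal(ci2$ci_high, 2 * exp(qnorm(0.975) * 0.5), tolerance = 1e-12)
})

test_that("Breslow baseline equals the hand Nelson-Aalen computation when beta-hat = 0", {
  # x chosen so the score at beta = 0 vanishes: events at t=1 (risk set of
  # 3) and t=2 (risk set of 2), censored at 3
  x <- matrix(c(0, 5, 1), ncol = 1)
  fit <- fit_cox(x, time = 1:3, event = c(TRUE, TRUE, FALSE))
  expect_equal(unname(fit$beta), 0, tolerance = 1e-9)
  base <- breslow_baseline_survival(fit, horizon = 2)
  expect_equal(base$cumhaz, 1 / 3 + 1 / 2, tolerance = 1e-9)
  expect_equal(base$s0, exp(-(1 / 3 + 1 / 2)), tolerance = 1e-9)
  # no events before the horizon
  expect_equal(breslow_baseline_survival(fit, horizon = 0.5)$s0, 1)
  # monotone in the horizon; held beyond the last observed time
  expect_lte(breslow_baseline_survival(fit, 2)$s0,
             breslow_baseline_survival(fit, 1)$s0)
  expect_warning(b10 <- breslow_baseline_survival(fit, 10), "exceeds")
  expect_equal(b10$cumhaz, base$cumhaz)
})

test_that("Breslow cumulative hazard matches Nelson-Aalen on a null-covariate fit", {
  set.seed(23)
  n <- 40
  tm <- round(rexp(n, 0.2), 2) + 0.01
  ev <- runif(n) < 0.7
  ev[1] <- TRUE
  # permutation-independent covariate, fit then compare at its own beta-hat
  # only when beta-hat is ~0 is Breslow = Nelson-Aalen, so force it by
  # using a covariate independent of time and checking against the brute
  # cumulative hazard evaluated at beta-hat instead
  x <- matrix(rnorm(n), ncol = 1)
  fit <- fit_cox(x, tm, ev)
  # brute-force Breslow denominator at beta-hat
  lp <- (x - mean(x)) * fit$beta
  H <- function(t) {
    s <- 0
    for (u in sort(unique(tm[ev]))) {
      if (u <= t) s <- s + sum(ev & tm == u) / sum(exp(lp[tm >= u]))
    }
    s
  }
  for (t in c(2, 5, max(tm))) {
    expect_equal(breslow_baseline_survival(fit, t)$cumhaz, H(t),
                 tolerance = 1e-9)
  }
})

test_that("predicted risk follows p = 1 - s0^exp(lp) and is monotone in lp", {
  cohort <- random_cohort(400, seed = 61)
  sub <- cohort[cohort$sex == "male", ]
  coded <- code_covariates(sub, crp_sd(cohort, "male"))
  x <- build_design(coded, markers = "crp_per_sd")
  fit <- fit_cox(x, sub$followup_years, sub$mi_event)
  base <- breslow_baseline_survival(fit, 10)
  # mean-covariate participant gets exactly 1 - s0
  expect_equal(predict_t_year_risk(fit, base, matrix(fit$means, 1)),
               1 - base$s0, tolerance = 1e-12)
  p <- predict_t_year_risk(fit, base, x)
  lp <- drop(sweep(x, 2, fit$means) %*% fit$beta)
  expect_true(all(diff(p[order(lp)]) >= 0))
  expect_true(all(p >= 0 & p <= 1))
  # closed form: s0 = 0.9 and lp = ln 2 gives 1 - 0.81
  fake_base <- structure(list(horizon = 10, cumhaz = -log(0.9), s0 = 0.9),
                         class = "baseline_risk")
  fake_fit <- structure(list(beta = c(z = 1), var = matrix(1),
                             means = 0), class = "cox_fit")
  expect_equal(predict_t_year_risk(fake_fit, fake_base, matrix(log(2))),
               1 - 0.9^2, tolerance = 1e-12)
})

test_that("shifting a covariate by a constant changes neither beta-hat nor risks", {
  cohort <- random_cohort(300, seed = 71)
  sub <- cohort[cohort$sex == "female", ]
  coded <- code_covariates(sub, crp_sd(cohort, "female"))
  x <- build_design(coded, markers = "kif6_dominant")
  f1 <- fit_cox(x, sub$followup_years, sub$mi_event)
  x2 <- x
  x2[, "age"] <- x2[, "age"] + 100
  f2 <- fit_cox(x2, sub$followup_years, sub$mi_event)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-7)
  b1 <- breslow_baseline_survival(f1, 10)
  b2 <- breslow_baseline_survival(f2, 10)
  expect_equal(b1$s0, b2$s0, tolerance = 1e-7)
  expect_equal(predict_t_year_risk(f1, b1, x),
               predict_t_year_risk(f2, b2, x2), tolerance = 1e-7)
})

test_that("beta-hat bias shrinks as the cohort grows (consistency)", {
  truth <- log(1.42)
  bias <- sapply(c(500, 2000, 8000), function(n) {
    est <- sapply(1:8, function(r) {
      # all other true effects off, so the carrier-only model is correctly
      # specified and beta-hat should be consistent for log(1.42)
      cfg <- sim_config(n_male = n, n_female = 2, hr_9p21 = 1, hr_crp = 1,
                        hr_age = 1, hr_diabetes = 1)
      ch <- generate_cohort(cfg, seed = 1000 * n + r, sex = "male")
      carrier <- as.numeric(ch$kif6 >= 1)
      fit <- fit_cox(matrix(carrier, ncol = 1,
                            dimnames = list(NULL, "kif6_dominant")),
                     ch$followup_years, ch$mi_event)
      fit$beta[[1]]
    })
    abs(mean(est) - truth)
  })
  expect_lt(bias[3], 0.05)
  expect_lt(bias[3], bias[1] + 0.02)
})

test_that("fits serialize to JSON with coefficients, grid and s0", {
  cohort <- random_cohort(900, seed = 81)
  sub <- cohort[cohort$sex == "male", ]
  coded <- code_covariates(sub, crp_sd(cohort, "male"))
  x <- build_design(coded)
  fit <- fit_cox(x, sub$followup_years, sub$mi_event)
  path <- withr::local_tempfile(fileext = ".json")
  write_cox_fit(fit, path, horizon = 10)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(unlist(got$beta), fit$beta, tolerance = 1e-12)
  expect_equal(got$s0, breslow_baseline_survival(fit, 10)$s0,
               tolerance = 1e-12)
  expect_equal(got$event_times$time, fit$baseline$time, tolerance = 1e-12)
})
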