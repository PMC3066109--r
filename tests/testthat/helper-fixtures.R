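# Shared fixture builders: tiny in-code cohorts and score vectors.

# One fully specified participant row; override any field.
participant <- function(...) {
  row <- list(
    id = "P1", sex = "male", race = "white", age = 72, ldl = 124, hdl = 48,
    sbp = 118, dbp = 76, smoker = FALSE, diabetes = FALSE, crp = 2.5,
    g9p21 = 1L, kif6 = 1L, prior_mi = FALSE, prior_stroke = FALSE,
    followup_years = 10, mi_event = FALSE
  )
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

# Bind participant rows, giving each a distinct id.
small_cohort <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  out$id <- sprintf("P%d", seq_len(nrow(out)))
  out
}

# A random but valid cohort for property-style tests.
random_cohort <- function(n, seed) {
  cfg <- sim_config(n_male = ceiling(n / 2), n_female = floor(n / 2))
  generate_cohort(cfg, seed = seed)
}

# Resize a sim_config to a total cohort size, keeping sex proportions.
config_with_n <- function(cfg, n_total) {
  prop_m <- cfg$n[["male"]] / sum(cfg$n)
  n_m <- round(n_total * prop_m)
  cfg$n <- c(male = n_m, female = n_total - n_m)
  cfg
}

# Explicit Breslow log partial likelihood by direct risk-set enumeration;
# independent of the fitting code (no shared helpers).
loglik_brute <- function(beta, x, time, event) {
  x <- as.matrix(x)
  lp <- drop(x %*% beta)
  ll <- 0
  for (t in sort(unique(time[event]))) {
    dead <- which(event & time == t)
    risk <- which(time >= t)
    ll <- ll + sum(lp[dead]) - length(dead) * log(sum(exp(lp[risk])))
  }
  ll
}
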