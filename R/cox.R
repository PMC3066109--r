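# Cox proportional-hazards fitting by direct Newton-Raphson maximisation of
# the Breslow-ties log partial likelihood, plus the Breslow baseline-hazard
# estimator and t-year absolute risk.

# Reverse cumulative sums over rows of a matrix (sum over i >= k).
rev_cumsum_rows <- function(m) {
  if (nrow(m) == 1L) return(m)
  apply(m[nrow(m):1L, , drop = FALSE], 2L, cumsum)[nrow(m):1L, , drop = FALSE]
}

# Log partial likelihood, score and information at beta, for data sorted by
# increasing time. Breslow tie handling: every subject with time >= t_k is
# in the risk set at event time t_k, including those censored at t_k.
cox_derivatives <- function(xc, time, event, beta, what = "all") {
  n <- nrow(xc)
  p <- ncol(xc)
  lp <- drop(xc %*% beta)
  lp <- lp - max(lp)                       # guard exp overflow; cancels in ratios
  w <- exp(lp)
  # positions of the first subject of each tied-time group
  first <- which(!duplicated(time))
  grp <- rep.int(seq_along(first), diff(c(first, n + 1L)))
  r0 <- rev(cumsum(rev(w)))                # risk-set sums at each row
  d <- tabulate(grp[event], nbins = length(first))   # events per distinct time
  has_e <- d > 0L
  f <- first[has_e]
  dk <- d[has_e]
  # the -max(lp) shift contributes -D*max(lp) to each term and cancels
  ll <- sum(lp[event]) - sum(dk * log(r0[f]))
  if (what == "loglik") return(ll)
  s1 <- rev_cumsum_rows(w * xc)            # n x p
  xbar <- s1[f, , drop = FALSE] / r0[f]    # risk-set weighted means per event time
  score <- colSums(xc[event, , drop = FALSE]) - colSums(dk * xbar)
  xx <- xc[, rep(seq_len(p), each = p), drop = FALSE] *
        xc[, rep(seq_len(p), times = p), drop = FALSE]
  s2 <- rev_cumsum_rows(w * xx)            # n x p^2
  m2 <- s2[f, , drop = FALSE] / r0[f]
  info <- matrix(colSums(dk * m2), p, p) - crossprod(sqrt(dk) * xbar)
  list(loglik = ll, score = score, info = info)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the Breslow-ties log partial likelihood by Newton-Raphson with
#' step-halving, starting from beta = 0. Convergence is declared when the
#' maximum absolute score component falls below `tol_score` or the Newton
#' step is smaller than `tol_step`. The covariance is the inverse observed
#' information at the optimum. Everything needed for baseline-hazard
#' estimation (the distinct event times, their event counts and the
#' mean-centered risk-set denominators) is retained in the fit.
#'
#' @param x Numeric design matrix (one column per coefficient, no
#'   intercept); columns must not be collinear.
#' @param time Follow-up time, years, non-negative.
#' @param event Logical event indicator (TRUE = incident MI).
#' @param tol_score,tol_step Convergence tolerances.
#' @param max_iter Iteration cap.
#' @return Object of class `cox_fit`: `beta` (named log-hazard-ratio
#'   vector), `var` (covariance matrix), `loglik`, `loglik_null`, `iter`,
#'   `n`, `n_event`, `means` (sample column means used for centering), and
#'   `baseline` (data frame of distinct event times, event counts and
#'   Breslow denominators evaluated at the estimate with mean-centered
#'   covariates).
#' @export
fit_cox <- function(x, time, event, tol_score = 1e-8, tol_step = 1e-10,
                    max_iter = 30L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  event <- as.logical(event)
  stopifnot(length(time) == nrow(x), length(event) == nrow(x))
  if (any(!is.finite(x)) || any(!is.finite(time)) || any(is.na(event))) {
    stop("design, time and event must be complete and finite", call. = FALSE)
  }
  if (any(time < 0)) stop("negative follow-up time", call. = FALSE)
  if (!any(event)) stop("no events: partial likelihood is flat", call. = FALSE)
  qrx <- qr(scale(x, center = TRUE, scale = FALSE))
  if (qrx$rank < ncol(x)) {
    stop("rank-deficient design: collinear columns ",
         paste(colnames(x)[qrx$pivot[-seq_len(qrx$rank)]], collapse = ", "),
         call. = FALSE)
  }

  ord <- order(time)
  means <- colMeans(x)
  xc <- sweep(x, 2L, means)[ord, , drop = FALSE]
  ts <- time[ord]
  ev <- event[ord]
  p <- ncol(x)

  beta <- numeric(p)
  dv <- cox_derivatives(xc, ts, ev, beta)
  loglik_null <- dv$loglik
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (rcond(dv$info) < 1e-12) {
      stop("information matrix is numerically singular (collinear design?)",
           call. = FALSE)
    }
    step <- solve(dv$info, dv$score)
    # step-halving: never accept a decrease in the partial likelihood
    h <- 1
    repeat {
      cand <- beta + h * step
      ll_cand <- cox_derivatives(xc, ts, ev, cand, what = "loglik")
      if (ll_cand >= dv$loglik - 1e-12 || h < 1e-4) break
      h <- h / 2
    }
    beta <- cand
    if (any(abs(beta) > 50)) {
      stop("divergent fit (|beta| > 50): monotone likelihood / separation",
           call. = FALSE)
    }
    dv <- cox_derivatives(xc, ts, ev, beta)
    if (max(abs(dv$score)) < tol_score || max(abs(h * step)) < tol_step) break
    if (iter >= max_iter) {
      warning("fit_cox: reached max_iter without meeting tolerance")
      break
    }
  }

  # Breslow denominators at beta-hat, centered scale, for H0(t)
  lp <- drop(xc %*% beta)
  w <- exp(lp)
  first <- which(!duplicated(ts))
  grp <- rep.int(seq_along(first), diff(c(first, length(ts) + 1L)))
  r0 <- rev(cumsum(rev(w)))
  d <- tabulate(grp[ev], nbins = length(first))
  keep <- d > 0L
  baseline <- data.frame(time = ts[first][keep], n_event = d[keep],
                         denom = r0[first][keep])

  structure(list(
    beta = stats::setNames(drop(beta), colnames(x)),
    var = structure(solve(dv$info), dimnames = list(colnames(x), colnames(x))),
    loglik = dv$loglik, loglik_null = loglik_null,
    iter = iter, n = nrow(x), n_event = sum(ev),
    means = means, baseline = baseline,
    max_time = max(ts)
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  se <- sqrt(diag(x$var))
  tab <- data.frame(beta = x$beta, hr = exp(x$beta), se = se,
                    z = x$beta / se,
                    p = 2 * stats::pnorm(-abs(x$beta / se)))
  cat("Cox proportional-hazards fit (Breslow ties)\n")
  cat("n =", x$n, " events =", x$n_event,
      " loglik =", format(x$loglik), " iter =", x$iter, "\n")
  print(round(tab, 4))
  invisible(x)
}

#' Hazard ratio with Wald confidence interval and p-value
#'
#' @param fit A `cox_fit`.
#' @param term Column name or index.
#' @param level Confidence level (default 0.95).
#' @return List with `hr`, `ci_low`, `ci_high`, `p`, `beta`, `se`.
#' @export
hazard_ratio_ci <- function(fit, term, level = 0.95) {
  stopifnot(inherits(fit, "cox_fit"))
  j <- if (is.character(term)) match(term, names(fit$beta)) else as.integer(term)
  if (is.na(j) || j < 1L || j > length(fit$beta)) {
    stop("unknown term: ", term, call. = FALSE)
  }
  b <- fit$beta[[j]]
  se <- sqrt(fit$var[j, j])
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(hr = exp(b), ci_low = exp(b - zq * se), ci_high = exp(b + zq * se),
       p = 2 * stats::pnorm(-abs(b / se)), beta = b, se = se)
}

#' Breslow baseline survival at a horizon
#'
#' Cumulative baseline hazard H0(t) = sum over event times t_k <= t of
#' d_k / sum over the risk set of exp((x_i - xbar)' beta); the baseline is
#' therefore that of the mean-covariate participant, and
#' s0 = exp(-H0(horizon)). If the horizon lies beyond the last observed
#' time, H0 is held at its last value with a warning.
#'
#' @param fit A `cox_fit`.
#' @param horizon Positive time in years (default 10).
#' @return Object of class `baseline_risk`: `horizon`, `s0`, `cumhaz`.
#' @export
breslow_baseline_survival <- function(fit, horizon = 10) {
  stopifnot(inherits(fit, "cox_fit"), horizon > 0)
  if (horizon > fit$max_time) {
    warning("horizon ", horizon, " exceeds last observed time ",
            format(fit$max_time), "; cumulative hazard held at last value")
  }
  b <- fit$baseline
  h0 <- sum(b$n_event[b$time <= horizon] / b$denom[b$time <= horizon])
  structure(list(horizon = horizon, cumhaz = h0, s0 = exp(-h0)),
            class = "baseline_risk")
}

#' Predicted t-year absolute risk
#'
#' p = 1 - s0 ^ exp((x - xbar)' beta): the baseline survival raised to the
#' participant's relative hazard, using the same mean-centering convention
#' as the baseline estimator, so the two cancel for the average participant.
#'
#' @param fit A `cox_fit`.
#' @param base A `baseline_risk` from the same fit.
#' @param x Design matrix (or single row) with the fit's columns.
#' @return Numeric vector of predicted event probabilities in [0, 1].
#' @export
predict_t_year_risk <- function(fit, base, x) {
  stopifnot(inherits(fit, "cox_fit"), inherits(base, "baseline_risk"))
  x <- matrix(as.matrix(x), ncol = length(fit$beta))
  lp <- drop(sweep(x, 2L, fit$means) %*% fit$beta)
  1 - base$s0 ^ exp(lp)
}

#' Serialize a Cox fit to JSON
#'
#' Captures the coefficients, covariance, centering means, distinct event
#' times with Breslow denominators, and the 10-year baseline survival, so a
#' fit can be stored alongside a report and reloaded elsewhere.
#'
#' @param fit A `cox_fit`.
#' @param path Output file; created/overwritten.
#' @param horizon Risk horizon recorded with the fit (years).
#' @return `path`, invisibly.
#' @export
write_cox_fit <- function(fit, path, horizon = 10) {
  base <- suppressWarnings(breslow_baseline_survival(fit, horizon))
  obj <- list(
    beta = as.list(fit$beta),
    covariance = unname(apply(fit$var, 1L, as.list)),
    loglik = fit$loglik, n = fit$n, n_event = fit$n_event,
    covariate_means = as.list(fit$means),
    event_times = fit$baseline,
    centering = "covariate means (baseline hazard is for the mean-covariate participant)",
    horizon = horizon, s0 = base$s0
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
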