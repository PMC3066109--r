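# ROC AUC (Mann-Whitney estimator) and the DeLong test for the difference
# between two correlated AUCs, via the structural-components (placement
# values) formulation computed from midranks.

# Midrank placement values: for each case, the fraction of controls it
# beats (ties count 1/2), and symmetrically for controls.
delong_placements <- function(score, event) {
  cases <- score[event]
  controls <- score[!event]
  n1 <- length(cases)
  n0 <- length(controls)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: need at least one event and one non-event",
         call. = FALSE)
  }
  tz <- rank(c(cases, controls), ties.method = "average")
  tx <- rank(cases, ties.method = "average")
  ty <- rank(controls, ties.method = "average")
  v10 <- (tz[seq_len(n1)] - tx) / n0              # per-case placement
  v01 <- 1 - (tz[n1 + seq_len(n0)] - ty) / n1     # per-control placement
  list(v10 = v10, v01 = v01, auc = mean(v10), n1 = n1, n0 = n0)
}

#' ROC area under the curve (Mann-Whitney estimator)
#'
#' The probability that a randomly chosen case scores higher than a
#' randomly chosen control, with ties counted 1/2; equal to the trapezoidal
#' area under the empirical ROC curve. Invariant under strictly monotone
#' transforms of the score.
#'
#' @param score Numeric risk score (higher = more at risk).
#' @param event Logical case indicator.
#' @return Object of class `auc_result` with `auc`, `n_events`,
#'   `n_nonevents`.
#' @export
auc <- function(score, event) {
  event <- as.logical(event)
  stopifnot(length(score) == length(event), !anyNA(score), !anyNA(event))
  pl <- delong_placements(score, event)
  structure(list(auc = pl$auc, n_events = pl$n1, n_nonevents = pl$n0),
            class = "auc_result")
}

#' DeLong test for the difference of two paired AUCs
#'
#' Both scores must be computed on the same participants. The variance of
#' the AUC difference is estimated from the empirical covariance of the
#' per-case and per-control placement values (DeLong's
#' structural-components method); the z statistic is
#' `(auc_aug - auc_base) / se` with a two-sided normal p-value. When the
#' scores are identical (se = 0 and delta = 0) p = 1 by convention.
#'
#' @param score_base,score_aug Paired risk scores.
#' @param event Logical case indicator.
#' @return Object of class `auc_comparison`: `auc_base`, `auc_aug`,
#'   `delta`, `se`, `z`, `p`.
#' @export
compare_auc <- function(score_base, score_aug, event) {
  event <- as.logical(event)
  stopifnot(length(score_base) == length(score_aug),
            length(score_base) == length(event))
  a <- delong_placements(score_base, event)
  b <- delong_placements(score_aug, event)
  d10 <- b$v10 - a$v10
  d01 <- b$v01 - a$v01
  v <- (if (a$n1 > 1L) stats::var(d10) / a$n1 else 0) +
       (if (a$n0 > 1L) stats::var(d01) / a$n0 else 0)
  delta <- b$auc - a$auc
  if (v <= 0) {
    z <- 0
    p <- if (delta == 0) 1 else 0
  } else {
    z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_base = a$auc, auc_aug = b$auc, delta = delta,
                 se = sqrt(max(v, 0)), z = z, p = p),
            class = "auc_comparison")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (%d events, %d non-events)\n",
              x$auc, x$n_events, x$n_nonevents))
  invisible(x)
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC %.4f -> %.4f (delta %+0.4f, se %.4f); DeLong z = %.3f, p = %.4g\n",
              x$auc_base, x$auc_aug, x$delta, x$se, x$z, x$p))
  invisible(x)
}
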