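# Risk categorisation, reclassification tables and the categorical Net
# Reclassification Improvement with its asymptotic z-test.

RISK_BREAKS <- c(0.05, 0.10, 0.20)
RISK_LABELS <- c("0-<5%", "5-<10%", "10-<20%", ">=20%")

#' Assign 10-year risk categories
#'
#' Left-closed bins 0 to <5%, 5 to <10%, 10 to <20%, and 20% or greater;
#' a predicted risk of exactly 0.05 falls in the second category and 0.20
#' in the fourth.
#'
#' @param p10 Predicted probabilities in [0, 1].
#' @return Integer vector of ordinal categories 1-4.
#' @export
assign_risk_category <- function(p10) {
  if (any(!is.finite(p10) | p10 < 0 | p10 > 1)) {
    stop("predicted risks must lie in [0, 1]", call. = FALSE)
  }
  findInterval(p10, RISK_BREAKS) + 1L
}

#' Cross-tabulate base vs augmented risk categories
#'
#' Builds the two 4x4 reclassification matrices (events and non-events;
#' rows = base-model category, columns = augmented-model category) that the
#' NRI is computed from.
#'
#' @param p_base,p_aug Predicted 10-year risks under the base and augmented
#'   models, same participants in the same order.
#' @param event Logical: incident event during follow-up.
#' @return Object of class `reclass_table`: `events` and `nonevents`
#'   matrices, `n_events`, `n_nonevents`, `n_reclassified`,
#'   `pct_reclassified`.
#' @export
build_reclass_table <- function(p_base, p_aug, event) {
  if (length(p_base) != length(p_aug) || length(p_base) != length(event)) {
    stop("p_base, p_aug and event must have equal length", call. = FALSE)
  }
  event <- as.logical(event)
  cb <- factor(assign_risk_category(p_base), levels = 1:4,
               labels = RISK_LABELS)
  ca <- factor(assign_risk_category(p_aug), levels = 1:4,
               labels = RISK_LABELS)
  tab <- function(keep) {
    m <- table(base = cb[keep], augmented = ca[keep])
    matrix(as.integer(m), 4L, 4L, dimnames = dimnames(m))
  }
  ev <- tab(event)
  ne <- tab(!event)
  moved <- sum(ev) + sum(ne) - sum(diag(ev)) - sum(diag(ne))
  structure(list(
    events = ev, nonevents = ne,
    n_events = sum(event), n_nonevents = sum(!event),
    n_reclassified = moved,
    pct_reclassified = 100 * moved / length(event)
  ), class = "reclass_table")
}

#' Net Reclassification Improvement with asymptotic test
#'
#' Among events, movement to a higher category is appropriate; among
#' non-events, movement to a lower category is. The NRI is the sum of the
#' two net proportions,
#' `(up_e - down_e) / n_e + (down_ne - up_ne) / n_ne`, and the z statistic
#' divides it by the square root of
#' `(up_e + down_e) / n_e^2 + (up_ne + down_ne) / n_ne^2`. `net_correct` is
#' the unnormalised count analogue, `(up_e - down_e) + (down_ne - up_ne)`.
#' With no reclassification at all the NRI is 0 and p = 1 by convention.
#'
#' @param table A `reclass_table`.
#' @return Object of class `nri_result`: `nri`, `event_component`,
#'   `nonevent_component`, `net_correct`, `z`, `p`.
#' @export
nri <- function(table) {
  stopifnot(inherits(table, "reclass_table"))
  if (table$n_events == 0L || table$n_nonevents == 0L) {
    stop("NRI requires at least one event and one non-event", call. = FALSE)
  }
  up_down <- function(m) {
    c(up = sum(m[upper.tri(m)]), down = sum(m[lower.tri(m)]))
  }
  e <- up_down(table$events)
  ne <- up_down(table$nonevents)
  comp_e <- (e[["up"]] - e[["down"]]) / table$n_events
  comp_ne <- (ne[["down"]] - ne[["up"]]) / table$n_nonevents
  net <- (e[["up"]] - e[["down"]]) + (ne[["down"]] - ne[["up"]])
  v <- (e[["up"]] + e[["down"]]) / table$n_events^2 +
       (ne[["up"]] + ne[["down"]]) / table$n_nonevents^2
  if (v == 0) {
    z <- 0
    p <- 1
  } else {
    z <- (comp_e + comp_ne) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(nri = comp_e + comp_ne,
                 event_component = comp_e, nonevent_component = comp_ne,
                 net_correct = as.integer(net), z = z, p = p),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("NRI = %.4f (events %+0.4f, non-events %+0.4f); net correctly reclassified = %d; z = %.3f, p = %.4g\n",
              x$nri, x$event_component, x$nonevent_component,
              x$net_correct, x$z, x$p))
  invisible(x)
}
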