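# Kaplan-Meier estimation and the two-group log-rank test, delegated to
# the survival package behind a small stable surface.

#' Kaplan-Meier survival curves per cluster
#'
#' Product-limit estimate of survival with right censoring for each
#' cluster of patients; the curve steps only at observed event times.
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicator (1 = event observed, 0 = censored).
#' @param labels Cluster labels, one per patient (>= 1 record each).
#' @return Named list (one element per cluster) of data.frames with
#'   columns `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(time, event, labels) {
  stopifnot(length(time) == length(event),
            length(time) == length(labels))
  if (any(time <= 0)) stop("follow-up time must be > 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  labels <- as.factor(labels)
  fits <- lapply(levels(labels), function(g) {
    keep <- labels == g
    fit <- survival::survfit(
      survival::Surv(time[keep], event[keep]) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, n_censor = fit$n.censor,
               survival = fit$surv)
  })
  names(fits) <- levels(labels)
  fits
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of event-time distributions between two
#' patient clusters: observed versus expected events accumulated over the
#' pooled event times with the hypergeometric variance, referred to a
#' 1-df chi-square distribution.
#'
#' @inheritParams km_estimate
#' @param labels Cluster labels with exactly two levels.
#' @return List with `chi_square`, `p_value`, `df`, and the per-group
#'   `observed` and `expected` event counts.
#' @export
logrank_test <- function(time, event, labels) {
  stopifnot(length(time) == length(event),
            length(time) == length(labels))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("need exactly two clusters")
  if (sum(event) < 1) stop("log-rank test needs at least one event")
  sd_fit <- survival::survdiff(
    survival::Surv(time, event) ~ labels)
  chisq <- unname(sd_fit$chisq)
  list(chi_square = chisq,
       p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
       df = 1L,
       observed = unname(sd_fit$obs),
       expected = unname(sd_fit$exp))
}
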