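#' Kaplan-Meier product-limit estimate
#'
#' Standard convention: at tied times events precede censorings. Greenwood's
#' formula supplies the variance. Implemented directly (and checked against
#' the `survival` package in the test suite).
#'
#' @param times follow-up in months (>= 0).
#' @param events logical / 0-1 event indicators.
#' @return object of class `km_curve`: data frame `steps` (time, n_risk,
#'   n_event, n_censor, survival, se) over distinct event times, plus n.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop_ki67("empty input", "ki67cta_config_error")
  if (any(times < 0)) stop_ki67("negative times", "ki67cta_config_error")
  events <- as.logical(events)
  stopifnot(length(events) == length(times), !any(is.na(times)),
            !any(is.na(events)))
  ts <- sort(unique(times[events]))
  n <- length(times)
  surv <- 1; var_sum <- 0
  steps <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), n_censor = integer(0),
                      survival = numeric(0), se = numeric(0))
  for (t in ts) {
    at_risk <- sum(times >= t)
    d <- sum(times == t & events)
    cens <- sum(times == t & !events)
    surv <- surv * (1 - d / at_risk)
    var_sum <- var_sum + d / (at_risk * (at_risk - d + 1e-300))
    steps <- rbind(steps, data.frame(
      time = t, n_risk = at_risk, n_event = d, n_censor = cens,
      survival = surv, se = surv * sqrt(var_sum)))
  }
  structure(list(steps = steps, n = n,
                 n_events = sum(events)), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve: n=%d, %d events, final S=%.3f>\n",
              x$n, x$n_events,
              if (nrow(x$steps)) x$steps$survival[nrow(x$steps)] else 1))
  invisible(x)
}

#' Survival probability at given times
#' @param curve a `km_curve`.
#' @param t times (months).
#' @return S(t), right-continuous step function starting at 1.
#' @export
km_survival_at <- function(curve, t) {
  st <- curve$steps
  vapply(t, function(tt) {
    i <- which(st$time <= tt)
    if (length(i) == 0) 1 else st$survival[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Observed-minus-expected statistic with the standard hypergeometric
#' variance for ties, 1 degree of freedom, no continuity correction.
#'
#' @param times follow-up in months.
#' @param events event indicators.
#' @param group two-level grouping vector.
#' @return object of class `logrank_result`: chisq, df = 1, p_value,
#'   observed and expected events per group.
#' @export
logrank <- function(times, events, group) {
  events <- as.logical(events)
  g <- as.factor(group)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop_ki67("need exactly two non-empty groups", "ki67cta_config_error")
  g1 <- g == levels(g)[1]
  ts <- sort(unique(times[events]))
  o_minus_e <- 0; v <- 0
  obs <- c(0, 0); expd <- c(0, 0)
  for (t in ts) {
    at <- times >= t
    n_t <- sum(at); n1 <- sum(at & g1)
    d <- sum(times == t & events)
    d1 <- sum(times == t & events & g1)
    e1 <- d * n1 / n_t
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n_t > 1)
      v <- v + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
    obs <- obs + c(d1, d - d1)
    expd <- expd + c(e1, d - e1)
  }
  chisq <- if (v > 0) o_minus_e^2 / v else 0
  structure(list(chisq = chisq, df = 1L,
                 p_value = stats::pchisq(chisq, 1, lower.tail = FALSE),
                 observed = stats::setNames(obs, levels(g)),
                 expected = stats::setNames(expd, levels(g))),
            class = "logrank_result")
}

#' Median follow-up by reverse Kaplan-Meier
#'
#' Censoring is treated as the event and events as censored; the median of
#' the resulting curve is the median potential follow-up.
#'
#' @param times follow-up in months.
#' @param events event indicators.
#' @return list: months (NA when not reached), reached flag.
#' @export
median_followup <- function(times, events) {
  if (length(times) == 0) stop_ki67("empty input", "ki67cta_config_error")
  rk <- km_estimate(times, !as.logical(events))
  st <- rk$steps
  cross <- which(st$survival <= 0.5)
  if (length(cross) == 0)
    return(list(months = NA_real_, reached = FALSE))
  list(months = st$time[min(cross)], reached = TRUE)
}
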