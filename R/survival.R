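## Survival stratification by predicted neoepitope load: quartile
## grouping, Kaplan-Meier curves, log-rank test, and the high-vs-low
## hazard ratio from a single-covariate proportional-hazards fit.

#' Predicted neoepitope load per patient
#'
#' Counts, per patient, the peptides whose prediction score passes the
#' cutoff (score >= cutoff for higher-is-positive predictors, <= for
#' lower-is-positive ones such as percentile ranks). The cutoff is
#' typically taken from \code{\link{sensSpecIntersection}}.
#'
#' @inheritParams rocCurve
#' @param patient_ids patient of each peptide.
#' @param cutoff decision threshold.
#' @return named integer vector, patient -> count (zeros included).
#' @export
neoepitopeLoad <- function(scores, patient_ids, cutoff,
                           higher_is_positive = TRUE) {
  hit <- if (higher_is_positive) scores >= cutoff else scores <= cutoff
  patients <- sort(unique(patient_ids))
  vapply(stats::setNames(patients, patients),
         function(p) sum(hit[patient_ids == p]), integer(1))
}

#' Quartile groups of neoepitope load
#'
#' Splits patients into four groups by the quartiles of their load:
#' "high" at or above the third quartile, "low" at or below the first,
#' "medium_high" strictly between the second and third, "medium_low"
#' above the first and at or below the second. Quartiles use linear
#' interpolation (R type 7) by default. When quartiles coincide the
#' precedence is high, then low, then the middle groups.
#'
#' @param loads named numeric vector of per-patient loads (>= 4
#'   patients).
#' @param type quantile algorithm (see \code{\link[stats]{quantile}}).
#' @return named factor with levels low, medium_low, medium_high, high.
#' @export
quantileGroups <- function(loads, type = 7) {
  if (length(loads) < 4L) stop("need at least 4 patients to form quartiles")
  q <- stats::quantile(loads, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  if (length(unique(loads)) == 1L)
    warning("all loads identical: every patient falls in a single group")
  g <- vapply(loads, function(v) {
    if (v >= q[3]) "high"
    else if (v <= q[1]) "low"
    else if (v > q[2]) "medium_high"
    else "medium_low"
  }, character(1))
  factor(g, levels = c("low", "medium_low", "medium_high", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over \code{survival::survfit} returning the step
#' function as a plain table (starting at time 0, survival 1).
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators (0 = censored).
#' @return data.frame with columns time, n_risk, n_event, survival.
#' @export
kmEstimator <- function(times, events) {
  if (!length(times)) stop("empty input")
  if (any(times <= 0)) stop("times must be positive")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = c(0, fit$time),
             n_risk = c(length(times), fit$n.risk),
             n_event = c(0, fit$n.event),
             survival = c(1, fit$surv))
}

#' Log-rank test across groups
#'
#' Wrapper over \code{survival::survdiff}.
#'
#' @param times,events as in \code{\link{kmEstimator}}.
#' @param groups group label per patient (>= 2 non-empty groups).
#' @return list with chi2, df, p.
#' @export
logrankTest <- function(times, events, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Hazard ratio of the high vs. low load group
#'
#' Fits a proportional-hazards model with the single binary covariate
#' 1(group == "high") by Newton iteration on the Breslow partial
#' likelihood, and returns the hazard ratio exp(beta) with a Wald
#' p-value.
#'
#' @param times,events as in \code{\link{kmEstimator}}.
#' @param groups labels containing "high" and "low" (other labels are
#'   dropped).
#' @return list with hr, beta, se, p.
#' @export
coxHrHighVsLow <- function(times, events, groups) {
  keep <- groups %in% c("high", "low")
  times <- times[keep]; events <- events[keep]
  x <- as.numeric(groups[keep] == "high")
  if (!any(x == 1) || !any(x == 0))
    stop("both the high and the low group must be non-empty")
  if (sum(events[x == 1]) == 0 || sum(events[x == 0]) == 0)
    stop("a group without events gives a monotone partial likelihood")

  ord <- order(times)
  times <- times[ord]; events <- events[ord]; x <- x[ord]
  ev_times <- unique(times[events == 1])
  beta <- 0
  for (iter in 1:50) {
    U <- 0; I <- 0
    for (t in ev_times) {
      risk <- times >= t
      d_idx <- events == 1 & times == t
      d <- sum(d_idx)
      w <- exp(beta * x[risk])
      s0 <- sum(w)
      s1 <- sum(w * x[risk])
      mu <- s1 / s0
      U <- U + sum(x[d_idx]) - d * mu
      I <- I + d * (mu - mu^2)   # for binary x, E[x^2] = E[x]
    }
    step <- U / I
    beta <- beta + step
    if (abs(step) < 1e-9) break
  }
  se <- 1 / sqrt(I)
  z <- beta / se
  list(hr = exp(beta), beta = beta, se = se, p = 2 * stats::pnorm(-abs(z)))
}

#' Survival stratification by predicted neoepitope load
#'
#' End-to-end convenience: computes per-patient loads at the cutoff,
#' forms quartile groups, runs the log-rank test over all four groups
#' and the proportional-hazards comparison of high vs. low.
#'
#' @inheritParams neoepitopeLoad
#' @param surv data.frame with columns patient_id, time, event.
#' @return list with loads, groups, km (per-group KM tables), logrank,
#'   cox.
#' @export
survivalByLoad <- function(scores, patient_ids, cutoff, surv,
                           higher_is_positive = TRUE) {
  loads <- neoepitopeLoad(scores, patient_ids, cutoff, higher_is_positive)
  loads <- loads[names(loads) %in% surv$patient_id]
  groups <- quantileGroups(loads)
  idx <- match(names(loads), surv$patient_id)
  times <- surv$time[idx]; events <- surv$event[idx]
  km <- lapply(split(seq_along(times), groups), function(i)
    if (length(i)) kmEstimator(times[i], events[i]) else NULL)
  lr <- logrankTest(times, events, groups)
  cox <- tryCatch(coxHrHighVsLow(times, events, as.character(groups)),
                  error = function(e) list(hr = NA_real_, beta = NA_real_,
                                           se = NA_real_, p = NA_real_,
                                           note = conditionMessage(e)))
  list(loads = loads, groups = groups, km = km, logrank = lr, cox = cox)
}
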