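#' Kaplan-Meier estimate of the survivor function
#'
#' Product-limit estimate with the standard convention that observations
#' censored at an event time are still at risk at that time. Estimation is
#' delegated to \code{survival::survfit}; the result is repackaged as a
#' light-weight step function with at-risk/event counts per time.
#'
#' @param obs Data.frame with \code{time} (months) and \code{event} (0/1)
#'   columns.
#' @param conf.level Confidence level for the pointwise log-scale interval.
#' @return A \code{km_curve}: times, at-risk/event/censor counts, survival
#'   and CI bounds per time, sample size \code{n} and \code{max_time}
#'   (largest observed time, event or censored).
#' @export
km_estimate <- function(obs, conf.level = 0.95) {
  obs <- as_observations(obs)
  if (nrow(obs) == 0L) stop("km_estimate needs at least one observation")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = obs,
                           conf.int = conf.level, conf.type = "log")
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, surv = fit$surv,
                 lower = fit$lower, upper = fit$upper,
                 n = nrow(obs), n_events = sum(obs$event),
                 max_time = max(obs$time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =", x$n_events,
      ", follow-up to", format(x$max_time, digits = 4), "months\n")
  invisible(x)
}

#' Survivor probability at a time point
#'
#' Right-continuous step-function value of the KM curve at \code{t}. Queries
#' beyond the largest observed follow-up time are refused (returned as
#' \code{NA}) rather than extrapolated.
#'
#' @param curve A \code{km_curve}.
#' @param t Nonnegative time(s) in months.
#' @return Numeric vector of survival probabilities; \code{NA} where
#'   \code{t} exceeds the curve's follow-up.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), all(t >= 0))
  idx <- findInterval(t, curve$time)
  out <- ifelse(idx == 0, 1, curve$surv[pmax(idx, 1L)])
  out[t > curve$max_time] <- NA_real_
  out
}

#' Restricted mean survival time from a KM curve
#'
#' Area under the KM step function up to \code{tau} (capped at the curve's
#' follow-up limit).
#'
#' @param curve A \code{km_curve}.
#' @param tau Upper integration limit in months.
#' @return Restricted mean survival in months.
#' @export
km_rmst <- function(curve, tau) {
  stopifnot(inherits(curve, "km_curve"), tau > 0)
  tau <- min(tau, curve$max_time)
  tt <- c(0, curve$time[curve$time < tau], tau)
  ss <- c(1, curve$surv[curve$time < tau])
  sum(diff(tt) * ss)
}

#' Export a KM curve as a data.frame
#'
#' @param curve A \code{km_curve}.
#' @return Data.frame with time, n_risk, n_event, survival and CI bounds.
#' @export
km_table <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  data.frame(time = curve$time, n_risk = curve$n_risk,
             n_event = curve$n_event, n_censor = curve$n_censor,
             survival = curve$surv, lower = curve$lower, upper = curve$upper)
}

# Coerce/validate survival observations: a data.frame with time >= 0 and
# event in {0,1}.
as_observations <- function(obs) {
  if (!is.data.frame(obs) || !all(c("time", "event") %in% names(obs)))
    stop("observations must be a data.frame with 'time' and 'event'")
  if (any(is.na(obs$time)) || any(obs$time < 0)) stop("times must be nonnegative")
  if (!all(obs$event %in% c(0, 1))) stop("event indicator must be 0/1")
  obs[c("time", "event")]
}
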