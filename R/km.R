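#' Kaplan-Meier product-limit estimator
#'
#' From-definition product-limit estimate with Greenwood variance and
#' complementary log-log pointwise confidence intervals. A record censored
#' at an event time is treated as censored just after the events at that
#' time (it remains in the risk set for them).
#'
#' @param time nonnegative event/censoring times.
#' @param event 0/1 event indicators.
#' @param conf_level confidence level for the pointwise bands.
#' @return A `km_fit` with the step function evaluated at the distinct
#'   event times: `time`, `n_risk`, `n_event`, `surv`, `se` (Greenwood SE
#'   of S), `lower`, `upper` (cloglog bands), plus `n` and `n_event_total`.
#' @export
kaplan_meier <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  validate_outcomes(time, event)
  ut <- sort(unique(time[event == 1]))
  n <- length(time)
  if (length(ut) == 0) {
    fit <- list(time = numeric(0), n_risk = integer(0), n_event = integer(0),
                surv = numeric(0), se = numeric(0),
                lower = numeric(0), upper = numeric(0),
                n = n, n_event_total = 0L, conf_level = conf_level)
    return(structure(fit, class = "km_fit"))
  }
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_ev <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_ev / n_risk)
  # Greenwood: var(S) = S^2 * cumsum(d / (r (r - d)))
  gw_term <- ifelse(n_risk > n_ev, n_ev / (n_risk * (n_risk - n_ev)), NA_real_)
  gw <- cumsum(gw_term)
  se <- surv * sqrt(gw)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  # cloglog band: on v = log(-log S), se_v = se_S / (S |log S|)
  lower <- upper <- rep(NA_real_, length(surv))
  pos <- which(surv > 0 & surv < 1 & is.finite(se))
  se_v <- se[pos] / (surv[pos] * abs(log(surv[pos])))
  lower[pos] <- surv[pos]^exp(z * se_v)
  upper[pos] <- surv[pos]^exp(-z * se_v)
  lower[surv == 1] <- 1; upper[surv == 1] <- 1
  lower[surv == 0] <- 0; upper[surv == 0] <- 0
  structure(list(time = ut, n_risk = n_risk, n_event = n_ev,
                 surv = surv, se = se, lower = lower, upper = upper,
                 n = n, n_event_total = sum(event), conf_level = conf_level),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param fit a `km_fit`.
#' @param t times at which to evaluate (vectorised).
#' @param what `"surv"`, `"lower"`, or `"upper"`.
#' @return Right-continuous step-function values; 1 before the first event.
#' @export
km_surv <- function(fit, t, what = c("surv", "lower", "upper")) {
  what <- match.arg(what)
  vals <- c(1, fit[[what]])
  idx <- findInterval(t, fit$time) + 1L
  vals[idx]
}

#' Median survival time with confidence interval
#'
#' The median is the first time at which the survival step function drops
#' to 0.5 or below; if survival never reaches 0.5 the median is not
#' reached (`NA`, rendered as "NR"). Confidence limits are the first
#' crossing times of the complementary log-log confidence bands
#' (Brookmeyer-Crowley style).
#'
#' @param fit a `km_fit`.
#' @return List with `median`, `lower`, `upper` (each `NA` if not reached).
#' @export
km_median_ci <- function(fit) {
  first_at_or_below <- function(vals) {
    i <- which(vals <= 0.5 + 1e-12)
    if (length(i) == 0) NA_real_ else fit$time[min(i)]
  }
  list(median = first_at_or_below(fit$surv),
       lower = first_at_or_below(ifelse(is.na(fit$lower), fit$surv, fit$lower)),
       upper = first_at_or_below(ifelse(is.na(fit$upper), fit$surv, fit$upper)))
}

#' @export
print.km_fit <- function(x, ...) {
  med <- km_median_ci(x)
  fmt <- function(v) if (is.na(v)) "NR" else sprintf("%.1f", v)
  cat(sprintf("<Kaplan-Meier: n = %d, events = %d, median = %s (%s-%s)>\n",
              x$n, x$n_event_total, fmt(med$median), fmt(med$lower), fmt(med$upper)))
  invisible(x)
}

#' @export
plot.km_fit <- function(x, xlab = "Months", ylab = "Recurrence-free survival",
                        conf = TRUE, add = FALSE, col = 1, ...) {
  t_step <- c(0, rep(x$time, each = 2))
  s_step <- c(1, 1, rep(x$surv, each = 2)[-(2 * length(x$surv))])
  if (!add) {
    graphics::plot(t_step, s_step, type = "l", ylim = c(0, 1),
                   xlab = xlab, ylab = ylab, col = col, ...)
  } else {
    graphics::lines(t_step, s_step, col = col, ...)
  }
  if (conf && length(x$time) > 0) {
    graphics::lines(x$time, x$lower, lty = 3, type = "s", col = col)
    graphics::lines(x$time, x$upper, lty = 3, type = "s", col = col)
  }
  invisible(x)
}
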