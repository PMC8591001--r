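#' Cumulative baseline hazard from a baseline survival table
#'
#' `H0(t) = -ln S0(t)`, interpolated linearly in `ln H0` versus `ln t`
#' between table knots (exact when the baseline is Weibull). Below the
#' first positive knot the line through the first two positive-hazard
#' knots is extended (so `H0(0) = 0`); beyond the last knot the default is
#' an error, with an optional flat extension.
#'
#' @param baseline a `baseline_survival` table.
#' @param t times (vectorised, >= 0).
#' @param extend `"error"` (default) or `"flat"` for t beyond the table.
#' @return Cumulative baseline hazard values.
#' @export
baseline_cumhaz <- function(baseline, t, extend = c("error", "flat")) {
  extend <- match.arg(extend)
  stopifnot(inherits(baseline, "baseline_survival"))
  knots <- baseline[baseline$survival < 1, , drop = FALSE]
  if (nrow(knots) < 2) stop("baseline table needs at least 2 knots with S0 < 1", call. = FALSE)
  lt <- log(knots$time)
  lh <- log(-log(knots$survival))
  tmax <- max(baseline$time)
  if (any(t < 0)) stop("times must be nonnegative", call. = FALSE)
  over <- t > tmax
  if (any(over) && extend == "error") {
    stop("time(s) beyond the baseline table (max ", tmax,
         "); use extend = \"flat\" to allow a flat extension", call. = FALSE)
  }
  tt <- pmin(t, tmax)
  out <- numeric(length(t))
  pos <- tt > 0
  # rule = 2 clamps above; below the first knot we extend the first segment
  slope1 <- (lh[2] - lh[1]) / (lt[2] - lt[1])
  ltt <- log(tt[pos])
  interp <- stats::approx(lt, lh, xout = ltt, rule = 2)$y
  below <- ltt < lt[1]
  interp[below] <- lh[1] + slope1 * (ltt[below] - lt[1])
  out[pos] <- exp(interp)
  out
}

#' Invert a cumulative baseline hazard
#'
#' Maps a cumulative-hazard value back to a time via the same log-log
#' interpolation as [baseline_cumhaz()]. Values beyond the hazard at the
#' last knot map to `Inf` (the event lies beyond the table's support).
#'
#' @param baseline a `baseline_survival`.
#' @param h cumulative-hazard values (>= 0).
#' @return Times; `Inf` where `h` exceeds the table's range.
#' @export
baseline_cumhaz_inv <- function(baseline, h) {
  stopifnot(inherits(baseline, "baseline_survival"))
  knots <- baseline[baseline$survival < 1, , drop = FALSE]
  lt <- log(knots$time)
  lh <- log(-log(knots$survival))
  hmax <- exp(lh[length(lh)])
  out <- rep(Inf, length(h))
  if (any(h < 0)) stop("cumulative hazard must be nonnegative", call. = FALSE)
  out[h == 0] <- 0
  ok <- h > 0 & h <= hmax
  lhh <- log(h[ok])
  slope1 <- (lt[2] - lt[1]) / (lh[2] - lh[1])
  interp <- stats::approx(lh, lt, xout = lhh, rule = 2)$y
  below <- lhh < lh[1]
  interp[below] <- lt[1] + slope1 * (lhh[below] - lh[1])
  out[ok] <- exp(interp)
  out
}

#' Calibration slope of a linear predictor
#'
#' Cox regression with the score's linear predictor as the only
#' covariate; a slope near 1 indicates correctly specified relative
#' risks in the validation cohort.
#'
#' @param lp linear predictors.
#' @param time,event outcome vectors.
#' @param conf_level confidence level.
#' @return List with `slope`, `lower`, `upper`, `se`, and the underlying
#'   `fit`.
#' @export
calibration_slope <- function(lp, time, event, conf_level = 0.95) {
  fit <- fit_cox(matrix(lp, dimnames = list(NULL, "lp")), time, event)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- fit$coefficients[["lp"]]; se <- fit$se[["lp"]]
  list(slope = b, lower = b - z * se, upper = b + z * se, se = se, fit = fit)
}

#' Transform event times through the derivation baseline
#'
#' Each time `t` becomes `T* = H0(t) = -ln S0(t)`; event indicators are
#' unchanged. Zero transformed times are floored at a small positive
#' epsilon so the log-time likelihood is defined.
#'
#' @param time,event outcome vectors.
#' @param baseline a `baseline_survival`.
#' @param eps positive floor for `T*`.
#' @param extend passed to [baseline_cumhaz()].
#' @return data.frame with columns `tstar` and `event`.
#' @export
transform_time <- function(time, event, baseline, eps = 1e-10,
                           extend = c("error", "flat")) {
  tstar <- baseline_cumhaz(baseline, time, extend = match.arg(extend))
  data.frame(tstar = pmax(tstar, eps), event = event)
}

#' Weibull calibration of a risk score (validation by calibration)
#'
#' Embeds a published proportional-hazards score in the Weibull model
#' `ln(T*) = mu + gamma * LP + sigma * W`, where `T*` is the event time
#' transformed by the derivation model's cumulative baseline hazard and
#' `W` has a type 1 (minimum) extreme value distribution. When the score
#' is perfectly calibrated, `H0(T) * exp(LP)` is unit exponential, so the
#' reference point is `(mu, gamma, sigma) = (0, -1, 1)`: `mu` measures
#' the accuracy of the overall risk level, `gamma` the impact of the LP
#' (values in (-1, 0) mean the score exaggerates prognostic differences),
#' and `sigma` the shape of the baseline hazard. Wald tests are reported
#' against `mu = 0`, `gamma = 0` (the conventional significance test),
#' `gamma = -1` (the perfect-calibration contrast) and `sigma = 1`.
#'
#' @param lp linear predictors.
#' @param time,event outcome vectors.
#' @param baseline a `baseline_survival` (the derivation model's S0).
#' @param conf_level confidence level for the Wald intervals.
#' @return A `weibull_calibration` with `coefficients` (mu, gamma, sigma),
#'   `se`, `ci` (matrix), `tests` (data.frame of the four contrasts),
#'   `vcov`, `loglik`, and the `baseline` used.
#' @export
fit_weibull_calibration <- function(lp, time, event, baseline,
                                    conf_level = 0.95) {
  tr <- transform_time(time, event, baseline)
  fit <- fit_weibull_aft(lp, tr$tstar, tr$event)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  cf <- fit$coefficients; se <- fit$se
  ci <- cbind(lower = cf - z * se, upper = cf + z * se)
  # sigma CI on the log scale (respects positivity)
  ls <- log(cf[["sigma"]]); ls_se <- sqrt(fit$vcov["log_sigma", "log_sigma"])
  ci["sigma", ] <- exp(c(ls - z * ls_se, ls + z * ls_se))
  wald_p <- function(est, null, se) 2 * stats::pnorm(-abs((est - null) / se))
  tests <- data.frame(
    contrast = c("mu = 0", "gamma = 0", "gamma = -1", "sigma = 1"),
    estimate = c(cf[["mu"]], cf[["gamma"]], cf[["gamma"]], cf[["sigma"]]),
    p = c(wald_p(cf[["mu"]], 0, se[["mu"]]),
          wald_p(cf[["gamma"]], 0, se[["gamma"]]),
          wald_p(cf[["gamma"]], -1, se[["gamma"]]),
          wald_p(ls, 0, ls_se)))
  structure(list(coefficients = cf, se = se, ci = ci, tests = tests,
                 vcov = fit$vcov, loglik = fit$loglik,
                 n = fit$n, n_event = fit$n_event),
            class = "weibull_calibration")
}

#' @export
coef.weibull_calibration <- function(object, ...) object$coefficients

#' @export
print.weibull_calibration <- function(x, ...) {
  cat(sprintf("<weibull_calibration: n = %d, events = %d>\n", x$n, x$n_event))
  tab <- cbind(estimate = x$coefficients, se = x$se, x$ci)
  print(round(tab, 4))
  cat("tests:\n")
  print(data.frame(x$tests[1:2], p = signif(x$tests$p, 3)), row.names = FALSE)
  cat("perfect calibration corresponds to (mu, gamma, sigma) = (0, -1, 1)\n")
  invisible(x)
}

#' Recalibrated survival probability
#'
#' Evaluates the Weibull-calibration survival function
#' `S(t|LP)_cal = exp(-exp((1/sigma) * (ln(-ln S0(t)) - mu - gamma*LP)))`.
#' At `(mu, gamma, sigma) = (0, 0, 1)` this reduces to `S0(t)`; at
#' `(0, -1, 1)` it reduces to the original proportional-hazards
#' prediction `S0(t)^exp(LP)`.
#'
#' @param t time(s), within the baseline table's support.
#' @param lp linear predictor(s); `t` and `lp` are recycled to a common
#'   length.
#' @param cal a `weibull_calibration`, or a numeric vector
#'   `c(mu, gamma, sigma)`.
#' @param baseline a `baseline_survival`.
#' @param extend passed to [baseline_cumhaz()].
#' @return Survival probabilities in (0, 1].
#' @export
recalibrated_survival <- function(t, lp, cal, baseline,
                                  extend = c("error", "flat")) {
  if (inherits(cal, "weibull_calibration")) cal <- cal$coefficients
  stopifnot(length(cal) == 3, cal[[3]] > 0)
  h0 <- baseline_cumhaz(baseline, t, extend = match.arg(extend))
  mu <- cal[[1]]; gamma <- cal[[2]]; sigma <- cal[[3]]
  # H0(t) = 0 (t at or before the first knot with S0 = 1) -> survival 1
  out <- exp(-exp((log(h0) - mu - gamma * lp) / sigma))
  out[h0 == 0] <- 1
  out
}

#' Per-patient survival predicted by the original score
#'
#' `S(t|LP) = S0(t)^exp(LP)` on the published score scale (reference
#' LP = 0).
#'
#' @inheritParams recalibrated_survival
#' @return Survival probabilities.
#' @export
predicted_survival <- function(t, lp, baseline, extend = c("error", "flat")) {
  h0 <- baseline_cumhaz(baseline, t, extend = match.arg(extend))
  exp(-h0 * exp(lp))
}

#' Grouped calibration curves (observed versus predicted)
#'
#' Per risk group: the Kaplan-Meier curve with its confidence band, the
#' mean of the per-patient survival curves predicted by the original
#' score, and, when a calibration fit is supplied, the mean recalibrated
#' curves. Returns the plotted numbers so the figure is fully
#' reproducible from the table.
#'
#' @param lp linear predictors.
#' @param time,event outcome vectors.
#' @param groups factor of risk groups (empty groups are dropped with a
#'   warning).
#' @param baseline a `baseline_survival`.
#' @param cal optional `weibull_calibration`.
#' @param grid evaluation times (default 49 points up to the baseline
#'   table's horizon).
#' @param plot draw the figure (base graphics) as well.
#' @return data.frame with columns `group`, `time`, `km`, `km_lower`,
#'   `km_upper`, `predicted`, and `recalibrated` (NA when `cal` absent).
#' @export
calibration_plot_grouped <- function(lp, time, event, groups, baseline,
                                     cal = NULL, grid = NULL, plot = TRUE) {
  groups <- droplevels_with_warning(groups)
  if (is.null(grid)) grid <- seq(0, max(baseline$time), length.out = 49)
  rows <- lapply(levels(groups), function(g) {
    idx <- which(groups == g)
    km <- kaplan_meier(time[idx], event[idx])
    pred <- vapply(grid, function(tt) mean(predicted_survival(tt, lp[idx], baseline)),
                   numeric(1))
    recal <- if (is.null(cal)) rep(NA_real_, length(grid)) else
      vapply(grid, function(tt) mean(recalibrated_survival(tt, lp[idx], cal, baseline)),
             numeric(1))
    data.frame(group = g, time = grid,
               km = km_surv(km, grid),
               km_lower = km_surv(km, grid, "lower"),
               km_upper = km_surv(km, grid, "upper"),
               predicted = pred, recalibrated = recal)
  })
  tab <- do.call(rbind, rows)
  tab$group <- factor(tab$group, levels = levels(groups))
  if (plot) {
    cols <- seq_along(levels(groups))
    graphics::plot(NULL, xlim = range(grid), ylim = c(0, 1),
                   xlab = "Months since surgery",
                   ylab = "Recurrence-free survival")
    for (i in seq_along(levels(groups))) {
      g <- levels(groups)[i]
      sub <- tab[tab$group == g, ]
      graphics::lines(sub$time, sub$km, type = "s", col = cols[i])
      graphics::lines(sub$time, sub$predicted, col = cols[i], lwd = 2)
      if (!is.null(cal)) graphics::lines(sub$time, sub$recalibrated,
                                         col = cols[i], lty = 2, lwd = 2)
    }
    if (length(levels(groups)) > 1) {
      graphics::legend("bottomleft", legend = levels(groups),
                       col = cols, lty = 1, bty = "n")
    }
  }
  tab
}

#' Fixed-time calibration: predicted versus observed at chosen horizons
#'
#' For each risk group and each time point, plots the group's mean
#' predicted survival against the Kaplan-Meier estimate with its
#' confidence interval, to be compared against the 45-degree identity
#' line. Groups with no patients at risk at a time point are omitted with
#' a warning.
#'
#' @inheritParams calibration_plot_grouped
#' @param times evaluation horizons (months), default 12 and 24.
#' @return data.frame with columns `group`, `time`, `predicted`,
#'   `observed`, `observed_lower`, `observed_upper`.
#' @export
calibration_plot_fixed_times <- function(lp, time, event, groups, baseline,
                                         times = c(12, 24), cal = NULL,
                                         plot = TRUE) {
  groups <- droplevels_with_warning(groups)
  rows <- list()
  for (g in levels(groups)) {
    idx <- which(groups == g)
    km <- kaplan_meier(time[idx], event[idx])
    for (tt in times) {
      if (sum(time[idx] >= tt) == 0) {
        warning(sprintf("group '%s' has no patient at risk at %g months; omitted",
                        g, tt), call. = FALSE)
        next
      }
      pred <- mean(if (is.null(cal)) predicted_survival(tt, lp[idx], baseline)
                   else recalibrated_survival(tt, lp[idx], cal, baseline))
      rows[[length(rows) + 1]] <- data.frame(
        group = g, time = tt, predicted = pred,
        observed = km_surv(km, tt),
        observed_lower = km_surv(km, tt, "lower"),
        observed_upper = km_surv(km, tt, "upper"))
    }
  }
  tab <- do.call(rbind, rows)
  if (plot && nrow(tab) > 0) {
    graphics::plot(tab$predicted, tab$observed, xlim = c(0, 1), ylim = c(0, 1),
                   pch = as.integer(factor(tab$time)),
                   col = as.integer(factor(tab$group, levels = levels(groups))),
                   xlab = "Mean predicted survival", ylab = "Observed (KM) survival")
    graphics::segments(tab$predicted, tab$observed_lower,
                       tab$predicted, tab$observed_upper,
                       col = as.integer(factor(tab$group, levels = levels(groups))))
    graphics::abline(0, 1, lty = 2)
  }
  tab
}

droplevels_with_warning <- function(groups) {
  groups <- as.factor(groups)
  empty <- levels(groups)[table(groups) == 0]
  if (length(empty) > 0) {
    warning("dropping empty risk group(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
    groups <- droplevels(groups)
  }
  groups
}
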