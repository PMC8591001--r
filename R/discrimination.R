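#' Harrell's concordance index
#'
#' Over all usable pairs — pairs whose ordering is determined under right
#' censoring, i.e. the smaller time is an observed event and the times
#' differ — the fraction in which the patient with the higher risk score
#' fails first; ties in the score count 1/2.
#'
#' @param lp risk scores (higher = worse prognosis).
#' @param time,event outcome vectors (>= 2 records, >= 1 event).
#' @return Concordance in [0, 1].
#' @export
harrells_c <- function(lp, time, event) {
  n <- length(lp)
  stopifnot(n >= 2, length(time) == n, length(event) == n)
  # usable(i, j): time_i < time_j and event_i = 1
  dt <- outer(time, time, "<")
  usable <- dt & (event == 1)          # recycles event down rows (i index)
  dl <- outer(lp, lp, "-")             # lp_i - lp_j
  conc <- sum(usable & dl > 0) + 0.5 * sum(usable & dl == 0)
  npairs <- sum(usable)
  if (npairs == 0) stop("no usable pairs for Harrell's C", call. = FALSE)
  conc / npairs
}

#' Gonen and Heller's concordance probability K
#'
#' The model-based concordance probability for a proportional-hazards
#' score: an average over all unordered pairs of the logistic function of
#' the pairwise score difference. It depends only on the scores, so it is
#' unaffected by censoring by construction.
#'
#' @param lp risk scores on the log-hazard scale (>= 2 records).
#' @return Concordance probability in [0, 1].
#' @export
gonen_heller_k <- function(lp) {
  n <- length(lp)
  stopifnot(n >= 2)
  d <- outer(lp, lp, "-")              # d[i, j] = lp_i - lp_j
  # pair (i, j), i < j: I(lp_j <= lp_i)/(1 + exp(lp_j - lp_i))
  #                   + I(lp_i <  lp_j)/(1 + exp(lp_i - lp_j))
  upper <- upper.tri(d)
  dij <- d[upper]                      # lp_i - lp_j for i < j
  contrib <- ifelse(dij >= 0, 1 / (1 + exp(-dij)), 1 / (1 + exp(dij)))
  2 * sum(contrib) / (n * (n - 1))
}

#' Royston and Sauerbrei's D and R-squared(D)
#'
#' Prognostic separation: ranks of the scores are replaced by expected
#' standard-normal order statistics (Blom approximation), scaled by
#' `kappa = sqrt(8/pi)`; `D` is the Cox coefficient of this constructed
#' covariate and `R2D = (D^2/kappa^2) / (pi^2/6 + D^2/kappa^2)`.
#'
#' @param lp risk scores (>= 3 distinct values).
#' @param time,event outcome vectors (>= 2 events).
#' @return List with `D` and `r2d`.
#' @export
royston_sauerbrei_r2d <- function(lp, time, event) {
  n <- length(lp)
  stopifnot(sum(event) >= 2)
  if (diff(range(lp)) == 0) return(list(D = 0, r2d = 0))  # no separation
  stopifnot(length(unique(lp)) >= 3)
  kappa <- sqrt(8 / pi)
  r <- rank(lp, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  fit <- fit_cox(matrix(z / kappa, dimnames = list(NULL, "rankit")), time, event)
  D <- fit$coefficients[["rankit"]]
  r2d <- (D^2 / kappa^2) / (pi^2 / 6 + D^2 / kappa^2)
  list(D = D, r2d = r2d)
}

#' Time-dependent AUC (IPCW cumulative/dynamic, integrated)
#'
#' Uno-style inverse-probability-of-censoring-weighted cumulative/dynamic
#' AUC(t): cases at `t` are subjects with an observed event at or before
#' `t` (weighted by the inverse of the censoring-survival function at
#' their event time), controls are subjects still at risk beyond `t`. The
#' curve is evaluated on the grid of event times within the window and
#' integrated with weights proportional to `2 * f(t) * S(t)` from the
#' Kaplan-Meier estimate of the event-time distribution, yielding a
#' single summary AUC for the window.
#'
#' @param lp risk scores.
#' @param time,event outcome vectors.
#' @param horizon upper end of the evaluation window (months).
#' @param times optional explicit time(s); if given, the per-time AUC(t)
#'   vector is returned instead of the integrated summary.
#' @return Summary tdAUC in [0, 1], or the AUC(t) vector when `times` is
#'   supplied.
#' @export
tdauc <- function(lp, time, event, horizon = 24, times = NULL) {
  n <- length(lp)
  stopifnot(length(time) == n, length(event) == n)
  grid <- if (is.null(times)) sort(unique(time[event == 1 & time <= horizon]))
          else times
  if (length(grid) == 0) stop("no events within the window", call. = FALSE)
  # censoring distribution: KM of the censoring indicator
  Gfit <- kaplan_meier(time, 1 - event)
  # G evaluated just before each subject's time (left limit)
  Gt <- km_surv(Gfit, time - 1e-9)
  auc_t <- vapply(grid, function(tt) {
    case <- which(time <= tt & event == 1)
    ctrl <- which(time > tt)
    if (length(case) == 0 || length(ctrl) == 0) return(NA_real_)
    wc <- 1 / Gt[case]
    cmp <- outer(lp[case], lp[ctrl], ">") + 0.5 * outer(lp[case], lp[ctrl], "==")
    num <- sum(wc * rowSums(cmp))
    den <- sum(wc) * length(ctrl)
    num / den
  }, numeric(1))
  if (!is.null(times)) return(auc_t)
  # integration weights 2 f(t) S(t) from the event-time KM
  Sfit <- kaplan_meier(time, event)
  S_at <- km_surv(Sfit, grid)
  S_before <- km_surv(Sfit, grid - 1e-9)
  wts <- 2 * (S_before - S_at) * S_at
  ok <- !is.na(auc_t) & wts > 0
  if (!any(ok)) stop("tdAUC weights degenerate within the window", call. = FALSE)
  sum(auc_t[ok] * wts[ok]) / sum(wts[ok])
}

#' Bootstrap confidence interval for a cohort statistic
#'
#' Resamples records with replacement `B` times; the standard error is
#' the standard deviation of the replicate statistics and the interval is
#' normal-approximation (`estimate +/- z * se`), matching the convention
#' of reporting bootstrap SEs. Replicates on which the statistic fails
#' are skipped and counted; more than 10 percent failures is an error.
#' Deterministic given `seed`; the global RNG state is restored.
#'
#' @param statistic function of a data.frame returning a scalar.
#' @param data data.frame of records.
#' @param B number of bootstrap replicates (>= 2), default 200.
#' @param seed integer seed.
#' @param conf_level confidence level.
#' @return List with `estimate` (statistic on the full data), `se`,
#'   `lower`, `upper`, `B`, `n_failed`.
#' @export
bootstrap_ci <- function(statistic, data, B = 200, seed = 1,
                         conf_level = 0.95) {
  stopifnot(B >= 2, is.data.frame(data))
  est <- statistic(data)
  reps <- with_preserved_rng(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(nrow(data), replace = TRUE)
      tryCatch(statistic(data[idx, , drop = FALSE]),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.1 * B) {
    stop(sprintf("bootstrap failed on %d of %d replicates", n_failed, B),
         call. = FALSE)
  }
  se <- stats::sd(reps, na.rm = TRUE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = est, se = se,
       lower = est - z * se, upper = est + z * se,
       B = B, n_failed = n_failed)
}

#' All four discrimination statistics with bootstrap intervals
#'
#' @param lp risk scores.
#' @param time,event outcome vectors.
#' @param horizon tdAUC window (months).
#' @param B bootstrap replicates (default 200).
#' @param seed integer seed.
#' @return A `discrimination_report` data.frame: one row per statistic
#'   with `estimate`, `se`, `lower`, `upper`.
#' @export
discrimination_report <- function(lp, time, event, horizon = 24,
                                  B = 200, seed = 1) {
  df <- data.frame(lp = lp, time = time, event = event)
  stats_list <- list(
    harrell_c = function(d) harrells_c(d$lp, d$time, d$event),
    gonen_heller_k = function(d) gonen_heller_k(d$lp),
    royston_sauerbrei_r2d = function(d) royston_sauerbrei_r2d(d$lp, d$time, d$event)$r2d,
    tdauc = function(d) tdauc(d$lp, d$time, d$event, horizon))
  rows <- lapply(seq_along(stats_list), function(i) {
    ci <- bootstrap_ci(stats_list[[i]], df, B = B, seed = seed + i - 1)
    data.frame(statistic = names(stats_list)[i], estimate = ci$estimate,
               se = ci$se, lower = ci$lower, upper = ci$upper,
               n_failed = ci$n_failed)
  })
  out <- do.call(rbind, rows)
  attr(out, "B") <- B
  class(out) <- c("discrimination_report", "data.frame")
  out
}
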