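#' Externally validate a risk score on a cohort
#'
#' The central fitting function of the package: runs the full
#' three-stage validation of a published proportional-hazards risk score
#' on a patient cohort — misspecification (calibration slope and the
#' joint offset test), discrimination (Harrell's C, Gonen-Heller K,
#' Royston-Sauerbrei R2D and tdAUC with bootstrap intervals), and
#' calibration (grouped and fixed-time calibration tables plus the
#' Weibull calibration model with recalibrated survival probabilities) —
#' after complete-case filtering, administrative truncation, scoring and
#' risk grouping. Optionally runs offset-constrained extension tests and
#' forward selection.
#'
#' @param cohort a `survalid_cohort` (see [read_cohort()],
#'   [simulate_cohort()]).
#' @param config a `score_config` (see [shipped_score_config()]).
#' @param horizon administrative truncation horizon in months.
#' @param group_mode `"in_sample"` (percentile cut-points from this
#'   cohort) or `"fixed"` (the configuration's published cut-points).
#' @param bootstrap number of bootstrap replicates for the discrimination
#'   intervals.
#' @param seed integer seed driving all randomness (bootstrap).
#' @param recalibrate fit the Weibull calibration model and emit
#'   recalibrated curves.
#' @param update optional character vector of extension candidates
#'   (canonical cohort columns, e.g. `c("hep_b", "hep_c")`) tested one by
#'   one with the linear predictor as offset.
#' @param forward_select optional character vector of candidates for
#'   forward selection (linear predictor as offset).
#' @param out_dir optional directory: tables are written as CSV, the
#'   report as JSON, and the two calibration figures as PDF.
#' @param quiet suppress progress logging (stderr).
#' @return A `score_validation` object; see [summary.score_validation()].
#' @export
validate_score <- function(cohort, config,
                           horizon = 24,
                           group_mode = c("in_sample", "fixed"),
                           bootstrap = 200, seed = 20210707,
                           recalibrate = TRUE,
                           update = NULL, forward_select = NULL,
                           out_dir = NULL, quiet = FALSE) {
  group_mode <- match.arg(group_mode)
  stopifnot(inherits(cohort, "survalid_cohort"), inherits(config, "score_config"))
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  n_input <- nrow(cohort)

  req <- required_fields(config)
  cc <- complete_case_filter(cohort, req)
  log_msg("[complete-case] %d of %d records retained (%d excluded)",
          cc$exclusions$n_retained, n_input, cc$exclusions$n_excluded)
  data <- truncate_followup(cc$cohort, horizon)
  log_msg("[truncate] horizon %g months; %d events", horizon, sum(data$event))

  lp <- compute_lp(data, config)
  groups <- assign_risk_groups(lp, config, mode = group_mode)
  cuts <- attr(groups, "cuts")
  log_msg("[groups] cuts %.3f / %.3f; n = %s", cuts[1], cuts[2],
          paste(table(groups), collapse = "/"))
  time <- data$rfs_months; event <- data$event

  group_table <- .risk_group_table(lp, time, event, groups)

  slope <- calibration_slope(lp, time, event)
  X_terms <- score_design_matrix(data, config)
  joint <- joint_misspecification_test(X_terms, lp, time, event)
  log_msg("[misspecification] slope %.3f (%.3f-%.3f); LR %.2f on %d df, p = %.3g",
          slope$slope, slope$lower, slope$upper,
          joint$statistic, joint$df, joint$p)

  disc <- discrimination_report(lp, time, event, horizon = horizon,
                                B = bootstrap, seed = seed)
  log_msg("[discrimination] %s",
          paste(sprintf("%s %.3f", disc$statistic, disc$estimate), collapse = ", "))

  baseline <- config$baseline_survival
  cal <- NULL
  if (recalibrate) {
    cal <- fit_weibull_calibration(lp, time, event, baseline)
    log_msg("[calibration] mu %.3f, gamma %.3f, sigma %.3f",
            cal$coefficients[["mu"]], cal$coefficients[["gamma"]],
            cal$coefficients[["sigma"]])
  }
  grouped_tab <- calibration_plot_grouped(lp, time, event, groups, baseline,
                                          cal = cal, plot = FALSE)
  fixed_tab <- calibration_plot_fixed_times(lp, time, event, groups, baseline,
                                            times = c(12, min(24, horizon)),
                                            plot = FALSE)

  updates <- NULL
  if (!is.null(update)) {
    updates <- do.call(rbind, lapply(update, function(f) {
      keep <- !is.na(data[[f]])
      r <- offset_extension_test(data[[f]][keep], lp[keep],
                                 time[keep], event[keep])
      data.frame(candidate = f, coefficient = r$coefficient, se = r$se,
                 lower = r$lower, upper = r$upper, p = r$p)
    }))
  }
  fwd <- NULL
  if (!is.null(forward_select)) {
    cand_mat <- as.matrix(as.data.frame(data)[, forward_select, drop = FALSE])
    keep <- stats::complete.cases(cand_mat)
    fwd <- forward_selection(cand_mat[keep, , drop = FALSE], lp[keep],
                             time[keep], event[keep])
  }

  report <- structure(list(
    cohort_label = attr(cohort, "label"),
    score_name = config$name,
    n_input = n_input,
    n_analyzed = nrow(data),
    exclusions = cc$exclusions,
    horizon = horizon,
    group_mode = group_mode,
    group_cuts = cuts,
    group_table = group_table,
    calibration_slope = slope[c("slope", "lower", "upper", "se")],
    misspecification = list(coefficients = joint$coefficients,
                            statistic = joint$statistic,
                            df = joint$df, p = joint$p),
    discrimination = disc,
    weibull_calibration = cal,
    calibration_grouped = grouped_tab,
    calibration_fixed_times = fixed_tab,
    updates = updates,
    forward_selection = fwd,
    seed = seed,
    bootstrap = bootstrap), class = "score_validation")

  if (!is.null(out_dir)) .write_report_files(report, out_dir, lp, time, event,
                                             groups, baseline, cal)
  report
}

#' Design matrix of a score's covariates on their transformed scales
#'
#' One column per configuration term (e.g. the male indicator, the ALBI
#' grade 2/3 indicator, ln AFP), as used by the joint misspecification
#' test and the offset regressions.
#'
#' @param cohort a complete-case `survalid_cohort`.
#' @param config a `score_config`.
#' @return Numeric matrix with one named column per term.
#' @export
score_design_matrix <- function(cohort, config) {
  cov <- .term_covariates(cohort, config)
  cols <- lapply(config$terms, function(tm) {
    .apply_transform(cov[[tm$covariate]], tm$transform)
  })
  names(cols) <- vapply(config$terms, function(tm) {
    if (tm$transform %in% c("identity", "indicator")) tm$covariate
    else paste0(tm$transform, "_", tm$covariate)
  }, character(1))
  do.call(cbind, cols)
}

.risk_group_table <- function(lp, time, event, groups) {
  lev <- levels(groups)
  present <- lev[table(groups) > 0]
  rows <- lapply(lev, function(g) {
    idx <- which(groups == g)
    if (length(idx) == 0) {
      return(data.frame(group = g, n = 0L, pct = 0,
                        median_rfs = NA, median_lower = NA, median_upper = NA,
                        hr = NA, hr_lower = NA, hr_upper = NA))
    }
    med <- km_median_ci(kaplan_meier(time[idx], event[idx]))
    data.frame(group = g, n = length(idx),
               pct = 100 * length(idx) / length(lp),
               median_rfs = med$median, median_lower = med$lower,
               median_upper = med$upper,
               hr = NA_real_, hr_lower = NA_real_, hr_upper = NA_real_)
  })
  tab <- do.call(rbind, rows)
  # hazard ratios versus the low-risk reference group
  others <- setdiff(present, "low")
  if (length(others) > 0 && "low" %in% present) {
    X <- vapply(others, function(g) as.numeric(groups == g),
                numeric(length(groups)))
    X <- matrix(X, ncol = length(others), dimnames = list(NULL, others))
    fit <- fit_cox(X, time, event)
    s <- summary(fit)$table
    tab$hr[tab$group == "low"] <- 1
    for (g in others) {
      tab$hr[tab$group == g] <- s[g, "hr"]
      tab$hr_lower[tab$group == g] <- s[g, "hr_lower"]
      tab$hr_upper[tab$group == g] <- s[g, "hr_upper"]
    }
  }
  tab
}

.write_report_files <- function(report, out_dir, lp, time, event, groups,
                                baseline, cal) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(out_dir, paste0(report$score_name, "_"))
  utils::write.csv(report$group_table, paste0(pre, "risk_groups.csv"),
                   row.names = FALSE)
  utils::write.csv(report$discrimination, paste0(pre, "discrimination.csv"),
                   row.names = FALSE)
  utils::write.csv(report$calibration_grouped, paste0(pre, "calibration_grouped.csv"),
                   row.names = FALSE)
  utils::write.csv(report$calibration_fixed_times,
                   paste0(pre, "calibration_fixed_times.csv"), row.names = FALSE)
  writeLines(render_report(report, "json"), paste0(pre, "report.json"))
  grDevices::pdf(paste0(pre, "calibration_grouped.pdf"), width = 7, height = 5)
  calibration_plot_grouped(lp, time, event, groups, baseline, cal = cal)
  grDevices::dev.off()
  grDevices::pdf(paste0(pre, "calibration_fixed_times.pdf"), width = 5, height = 5)
  calibration_plot_fixed_times(lp, time, event, groups, baseline)
  grDevices::dev.off()
  invisible(NULL)
}

#' Render a validation report
#'
#' @param report a `score_validation`.
#' @param format `"json"` or `"markdown"`.
#' @return A character scalar (deterministic serialization).
#' @export
render_report <- function(report, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    x <- report
    x$weibull_calibration <- if (is.null(x$weibull_calibration)) NULL else
      list(coefficients = as.list(x$weibull_calibration$coefficients),
           se = as.list(x$weibull_calibration$se),
           ci = as.data.frame(x$weibull_calibration$ci),
           tests = x$weibull_calibration$tests)
    x$forward_selection <- if (is.null(x$forward_selection)) NULL else
      list(selected = x$forward_selection$selected,
           steps = lapply(x$forward_selection$steps, function(s)
             list(candidates = s$candidates, selected = s$selected)))
    x$misspecification$coefficients <-
      cbind(term = rownames(x$misspecification$coefficients),
            x$misspecification$coefficients)
    class(x) <- NULL
    return(jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE,
                            digits = NA, null = "null", pretty = TRUE))
  }
  md_num <- function(v, d = 2) ifelse(is.na(v), "NR", formatC(v, digits = d, format = "f"))
  lines <- c(
    sprintf("# Validation of %s on %s", report$score_name, report$cohort_label),
    "",
    sprintf("Analyzed %d of %d records (%d excluded for missing covariates); %g-month horizon.",
            report$n_analyzed, report$n_input, report$exclusions$n_excluded,
            report$horizon),
    "",
    "## Risk groups",
    "",
    "| Group | n (%) | Median RFS (95% CI) | HR (95% CI) |",
    "|---|---|---|---|")
  for (i in seq_len(nrow(report$group_table))) {
    r <- report$group_table[i, ]
    lines <- c(lines, sprintf(
      "| %s | %d (%.0f%%) | %s (%s-%s) | %s |",
      r$group, r$n, r$pct,
      md_num(r$median_rfs, 0), md_num(r$median_lower, 0), md_num(r$median_upper, 0),
      if (is.na(r$hr)) "-" else if (r$hr == 1) "1 (ref)" else
        sprintf("%.1f (%.1f-%.1f)", r$hr, r$hr_lower, r$hr_upper)))
  }
  cs <- report$calibration_slope
  lines <- c(lines, "",
             "## Misspecification", "",
             sprintf("Calibration slope %.2f (95%% CI %.2f-%.2f); joint offset LR test: chi2 = %.2f on %d df, p = %.3g.",
                     cs$slope, cs$lower, cs$upper,
                     report$misspecification$statistic,
                     report$misspecification$df, report$misspecification$p),
             "",
             "## Discrimination", "",
             "| Statistic | Estimate (95% CI) |", "|---|---|")
  for (i in seq_len(nrow(report$discrimination))) {
    r <- report$discrimination[i, ]
    lines <- c(lines, sprintf("| %s | %.2f (%.2f to %.2f) |",
                              r$statistic, r$estimate, r$lower, r$upper))
  }
  if (!is.null(report$weibull_calibration)) {
    cf <- report$weibull_calibration$coefficients
    ci <- report$weibull_calibration$ci
    lines <- c(lines, "", "## Weibull calibration", "",
               sprintf("mu = %.2f (%.2f to %.2f), gamma = %.2f (%.2f to %.2f), sigma = %.2f (%.2f to %.2f); perfect calibration is (0, -1, 1).",
                       cf[["mu"]], ci["mu", 1], ci["mu", 2],
                       cf[["gamma"]], ci["gamma", 1], ci["gamma", 2],
                       cf[["sigma"]], ci["sigma", 1], ci["sigma", 2]))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.score_validation <- function(x, ...) {
  cat(render_report(x, "markdown"), "\n")
  invisible(x)
}

#' Summarise a score validation
#'
#' @param object a `score_validation`.
#' @param ... unused.
#' @return The object, invisibly (prints the markdown report).
#' @export
summary.score_validation <- function(object, ...) print(object)
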