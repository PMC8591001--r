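#' ALBI score and grade
#'
#' The albumin-bilirubin grade summarises liver function as
#' `score = c_bil * log10(bilirubin) + c_alb * albumin` with published
#' constants (0.66, -0.085) and grade cut-points (-2.60, -1.39): grade 1
#' for scores at or below the first cut-point, grade 2 at or below the
#' second, grade 3 otherwise.
#'
#' @param albumin albumin in g/L (> 0), vectorised.
#' @param bilirubin total bilirubin in umol/L (> 0), vectorised.
#' @param config a `score_config`; its `albi` block supplies the constants.
#' @return data.frame with columns `score` and `grade`.
#' @export
compute_albi <- function(albumin, bilirubin, config = shipped_score_config("erasl_pre")) {
  if (any(albumin <= 0, na.rm = TRUE) || any(bilirubin <= 0, na.rm = TRUE)) {
    stop("albumin and bilirubin must be strictly positive", call. = FALSE)
  }
  a <- config$albi
  score <- a$bilirubin_coef * log10(bilirubin) + a$albumin_coef * albumin
  grade <- ifelse(score <= a$cuts[1], 1L, ifelse(score <= a$cuts[2], 2L, 3L))
  data.frame(score = score, grade = grade)
}

# Materialise the covariate matrix a config's terms can reference,
# including derived ALBI-grade and multiplicity indicators.
.term_covariates <- function(cohort, config) {
  df <- as.data.frame(cohort)
  out <- list(
    male = df$male,
    albumin = df$albumin_g_l,
    bilirubin = df$bilirubin_umol_l,
    afp = pmax(df$afp_ug_l, config$afp_floor),
    tumor_size = df$tumor_size_cm,
    tumor_number = df$tumor_number,
    mvi = df$mvi,
    hep_b = df$hep_b,
    hep_c = df$hep_c
  )
  albi <- compute_albi(df$albumin_g_l, df$bilirubin_umol_l, config)
  out$albi_score <- albi$score
  out$albi_grade_23 <- as.numeric(albi$grade >= 2)
  out$albi_grade_2 <- as.numeric(albi$grade == 2)
  out$albi_grade_3 <- as.numeric(albi$grade == 3)
  out$multiple_tumors <- as.numeric(df$tumor_number >= 2)
  out
}

.apply_transform <- function(x, transform) {
  switch(transform,
         identity = x,
         indicator = x,
         log = log(x),
         log10 = log10(x),
         stop("unknown transform '", transform, "'", call. = FALSE))
}

#' Evaluate a risk score's linear predictor on a cohort
#'
#' Computes `LP = sum(coefficient * transform(covariate))` over the
#' configuration's terms for every record. All referenced covariates must
#' be present (apply [complete_case_filter()] first).
#'
#' @param cohort a `survalid_cohort`.
#' @param config a `score_config`.
#' @return Numeric vector of linear predictors, one per record.
#' @export
compute_lp <- function(cohort, config) {
  stopifnot(inherits(cohort, "survalid_cohort"), inherits(config, "score_config"))
  cov <- .term_covariates(cohort, config)
  lp <- numeric(nrow(cohort))
  for (tm in config$terms) {
    x <- cov[[tm$covariate]]
    if (is.null(x)) {
      stop("term references unknown covariate '", tm$covariate, "'", call. = FALSE)
    }
    if (anyNA(x)) {
      bad <- cohort$id[is.na(x)]
      stop(sprintf("covariate '%s' is missing for record(s): %s",
                   tm$covariate, paste(bad, collapse = ", ")), call. = FALSE)
    }
    lp <- lp + tm$coefficient * .apply_transform(x, tm$transform)
  }
  lp
}

#' Covariates a score configuration requires
#'
#' Maps a config's terms back to the canonical cohort columns they need,
#' for use with [complete_case_filter()].
#'
#' @param config a `score_config`.
#' @return Character vector of canonical cohort column names.
#' @export
required_fields <- function(config) {
  base_map <- list(
    male = "male", albumin = "albumin_g_l", bilirubin = "bilirubin_umol_l",
    afp = "afp_ug_l", tumor_size = "tumor_size_cm", tumor_number = "tumor_number",
    mvi = "mvi", hep_b = "hep_b", hep_c = "hep_c",
    albi_score = c("albumin_g_l", "bilirubin_umol_l"),
    albi_grade_23 = c("albumin_g_l", "bilirubin_umol_l"),
    albi_grade_2 = c("albumin_g_l", "bilirubin_umol_l"),
    albi_grade_3 = c("albumin_g_l", "bilirubin_umol_l"),
    multiple_tumors = "tumor_number"
  )
  unique(unlist(lapply(config$terms, function(tm) base_map[[tm$covariate]])))
}

#' Assign low / intermediate / high risk groups
#'
#' Fixed mode uses the configuration's numeric cut-points. In-sample mode
#' computes the configured percentiles (default 50th and 85th) of the
#' supplied scores as cut-points, using the empirical quantile with linear
#' interpolation between order statistics. A score at or below the lower
#' cut-point is low risk, at or below the upper intermediate, else high.
#'
#' @param lp numeric vector of linear predictors.
#' @param config a `score_config`.
#' @param mode `"fixed"` or `"in_sample"`.
#' @return Factor with levels `low`, `intermediate`, `high`; the cut-points
#'   used are attached as attribute `"cuts"`.
#' @export
assign_risk_groups <- function(lp, config, mode = c("in_sample", "fixed")) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    cuts <- config$grouping$cuts
    if (is.null(cuts)) stop("config has no fixed grouping cut-points", call. = FALSE)
  } else {
    if (length(unique(lp)) < 3) {
      stop("in-sample grouping needs at least 3 distinct scores", call. = FALSE)
    }
    p <- config$grouping$percentiles
    if (is.null(p)) p <- c(50, 85)
    cuts <- unname(stats::quantile(lp, probs = p / 100, type = 7))
  }
  grp <- ifelse(lp <= cuts[1], "low", ifelse(lp <= cuts[2], "intermediate", "high"))
  structure(factor(grp, levels = c("low", "intermediate", "high")),
            cuts = cuts)
}
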