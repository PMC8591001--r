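#' Risk-score configurations
#'
#' A score configuration holds everything needed to evaluate a published
#' linear-predictor risk score on a cohort: the term list (covariate,
#' transform, coefficient), the ALBI grade constants, the risk-grouping
#' rule, and the derivation model's baseline survival table S0(t). The two
#' shipped configurations mirror the structure of the preoperative and
#' postoperative ERASL scores; because the exact published constants live
#' in an external supplement, the shipped coefficient values are clearly
#' labelled synthetic stand-ins (see the files under
#' `system.file("extdata", package = "survalid")`).
#'
#' Transforms: `identity`, `log` (natural log), `log10`, `indicator`
#' (covariate used as-is, expected 0/1). Derived covariates available to
#' terms: `albi_grade_23` (ALBI grade 2 or 3), `albi_grade_2`,
#' `albi_grade_3`, `multiple_tumors` (tumor_number >= 2).
#'
#' @name score_config
NULL

.known_transforms <- c("identity", "log", "log10", "indicator")

#' Read a score configuration from YAML
#'
#' @param path YAML file path.
#' @return A validated `score_config` list.
#' @export
read_score_config <- function(path) {
  as_score_config(yaml::read_yaml(path))
}

#' Validate a score configuration
#'
#' @param x a list with components `name`, `terms` (list of
#'   `list(covariate=, transform=, coefficient=)`), `albi`
#'   (`bilirubin_coef`, `albumin_coef`, `cuts` of length 2), `grouping`
#'   (either `cuts` of length 2 or `percentiles` of length 2), and
#'   `baseline_survival` (`time`, `survival` vectors).
#' @param afp_floor positive floor applied to AFP before log transforms.
#' @return A `score_config`.
#' @export
as_score_config <- function(x, afp_floor = 0.1) {
  stopifnot(is.list(x), !is.null(x$name), !is.null(x$terms))
  for (tm in x$terms) {
    if (!all(c("covariate", "transform", "coefficient") %in% names(tm))) {
      stop("each term needs covariate, transform, coefficient", call. = FALSE)
    }
    if (!tm$transform %in% .known_transforms) {
      stop("unknown transform '", tm$transform, "'", call. = FALSE)
    }
  }
  albi <- x$albi
  if (is.null(albi)) {
    albi <- list(bilirubin_coef = 0.66, albumin_coef = -0.085,
                 cuts = c(-2.60, -1.39))
  }
  albi$cuts <- as.numeric(unlist(albi$cuts))
  if (length(albi$cuts) != 2 || diff(albi$cuts) <= 0) {
    stop("albi cuts must be two strictly increasing thresholds", call. = FALSE)
  }
  grouping <- x$grouping
  if (is.null(grouping)) grouping <- list(percentiles = c(50, 85))
  if (!is.null(grouping$percentiles)) {
    p <- as.numeric(unlist(grouping$percentiles))
    if (length(p) != 2 || p[1] <= 0 || p[2] >= 100 || p[1] >= p[2]) {
      stop("grouping percentiles must satisfy 0 < p_low < p_high < 100",
           call. = FALSE)
    }
    grouping$percentiles <- p
  }
  if (!is.null(grouping$cuts)) {
    gc <- as.numeric(unlist(grouping$cuts))
    if (length(gc) != 2 || diff(gc) <= 0) {
      stop("grouping cuts must be two strictly increasing thresholds",
           call. = FALSE)
    }
    grouping$cuts <- gc
  }
  bs <- x$baseline_survival
  if (!is.null(bs)) {
    bs <- as_baseline_survival(data.frame(time = as.numeric(unlist(bs$time)),
                                          survival = as.numeric(unlist(bs$survival))))
  }
  structure(list(name = x$name,
                 terms = x$terms,
                 albi = albi,
                 grouping = grouping,
                 baseline_survival = bs,
                 afp_floor = if (!is.null(x$afp_floor)) x$afp_floor else afp_floor,
                 source = x$source),
            class = "score_config")
}

#' Baseline survival table
#'
#' Validates a derivation-model baseline survival table: times strictly
#' increasing starting at 0, survival starting at 1, nonincreasing, in
#' (0, 1].
#'
#' @param table data frame with columns `time` and `survival`.
#' @return A `baseline_survival` object.
#' @export
as_baseline_survival <- function(table) {
  stopifnot(is.data.frame(table), all(c("time", "survival") %in% names(table)))
  t <- table$time; s <- table$survival
  if (any(diff(t) <= 0)) stop("baseline times must be strictly increasing", call. = FALSE)
  if (t[1] != 0 || s[1] != 1) stop("baseline table must start at (0, 1)", call. = FALSE)
  if (any(s <= 0) || any(s > 1)) stop("baseline survival must lie in (0, 1]", call. = FALSE)
  if (any(diff(s) > 0)) stop("baseline survival must be nonincreasing", call. = FALSE)
  structure(data.frame(time = t, survival = s),
            class = c("baseline_survival", "data.frame"))
}

#' Load a shipped score configuration
#'
#' @param name `"erasl_pre"` or `"erasl_post"`.
#' @return A `score_config`.
#' @export
shipped_score_config <- function(name = c("erasl_pre", "erasl_post")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_synthetic.yaml"),
                      package = "survalid", mustWork = TRUE)
  read_score_config(path)
}

#' @export
print.score_config <- function(x, ...) {
  cat(sprintf("<score_config '%s': %d terms>\n", x$name, length(x$terms)))
  for (tm in x$terms) {
    cat(sprintf("  %+.4f * %s(%s)\n", tm$coefficient, tm$transform, tm$covariate))
  }
  if (!is.null(x$grouping$cuts)) {
    cat(sprintf("  fixed group cuts: %.3f / %.3f\n",
                x$grouping$cuts[1], x$grouping$cuts[2]))
  }
  if (!is.null(x$grouping$percentiles)) {
    cat(sprintf("  percentile rule: %g / %g\n",
                x$grouping$percentiles[1], x$grouping$percentiles[2]))
  }
  invisible(x)
}
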