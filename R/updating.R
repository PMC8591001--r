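#' Offset-constrained extension test for a single candidate covariate
#'
#' Fits a Cox model with the published score's linear predictor as an
#' offset (coefficient fixed at 1) and the candidate as the only free
#' covariate. The candidate's coefficient measures how its hazard ratio
#' in the validation cohort deviates from what the score already
#' attributes to it.
#'
#' @param candidate covariate vector (complete).
#' @param lp linear predictors (offset).
#' @param time,event outcome vectors.
#' @param conf_level confidence level.
#' @return List with `coefficient`, `se`, `lower`, `upper`, `p`, `fit`.
#' @export
offset_extension_test <- function(candidate, lp, time, event,
                                  conf_level = 0.95) {
  if (anyNA(candidate)) stop("candidate has missing values", call. = FALSE)
  fit <- fit_cox(matrix(candidate, dimnames = list(NULL, "candidate")),
                 time, event, offset = lp)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- fit$coefficients[["candidate"]]; se <- fit$se[["candidate"]]
  list(coefficient = b, se = se, lower = b - z * se, upper = b + z * se,
       p = 2 * stats::pnorm(-abs(b / se)), fit = fit)
}

#' Joint misspecification test of a published score
#'
#' Re-estimates all the score's covariates alongside the linear predictor
#' entered as a unit-coefficient offset, and tests by likelihood ratio
#' whether the re-estimated coefficients are jointly different from zero
#' (zero everywhere means the published weights transfer to the
#' validation cohort).
#'
#' @param covariates numeric matrix of the score's covariate columns (on
#'   the transformed scale entering the score).
#' @param lp linear predictors (offset).
#' @param time,event outcome vectors.
#' @return List with `coefficients` (summary table), `statistic`, `df`,
#'   `p`, and the two fits (`full`, `null`).
#' @export
joint_misspecification_test <- function(covariates, lp, time, event) {
  covariates <- as.matrix(covariates)
  if (anyNA(covariates)) stop("covariates have missing values", call. = FALSE)
  full <- fit_cox(covariates, time, event, offset = lp)
  null <- fit_cox(NULL, time, event, offset = lp)
  lrt <- lr_test(null, full, df = ncol(covariates))
  list(coefficients = summary(full)$table,
       statistic = lrt$statistic, df = lrt$df, p = lrt$p,
       full = full, null = null)
}

#' Forward selection of candidate covariates around a published score
#'
#' Starts from the model containing only the linear predictor (as a
#' unit-coefficient offset by default, or as a free covariate) and in
#' successive rounds adds the candidate with the smallest Wald p-value,
#' while that p-value is below the entry threshold. Ties are broken by
#' candidate name. The full trace of every round is returned.
#'
#' @param candidates named numeric matrix or data.frame of candidates.
#' @param lp linear predictors.
#' @param time,event outcome vectors.
#' @param entry_p entry threshold on the Wald p-value (default 0.05).
#' @param lp_mode `"offset"` (coefficient fixed at 1) or `"free"`.
#' @return An `update_trace`: list with `steps` (one element per round,
#'   each holding the per-candidate table, the selected name and the
#'   model log likelihood) and `selected` (names in entry order).
#' @export
forward_selection <- function(candidates, lp, time, event,
                              entry_p = 0.05, lp_mode = c("offset", "free")) {
  lp_mode <- match.arg(lp_mode)
  candidates <- as.matrix(candidates)
  if (is.null(colnames(candidates)) && ncol(candidates) > 0) {
    colnames(candidates) <- paste0("cand", seq_len(ncol(candidates)))
  }
  selected <- character(0)
  remaining <- colnames(candidates)
  steps <- list()
  base_design <- function(sel) {
    base <- candidates[, sel, drop = FALSE]
    if (lp_mode == "free") base <- cbind(lp = lp, base)
    base
  }
  offset <- if (lp_mode == "offset") lp else NULL
  repeat {
    if (length(remaining) == 0) break
    tab <- do.call(rbind, lapply(remaining, function(cand) {
      X <- cbind(base_design(selected), candidates[, cand, drop = FALSE])
      fit <- fit_cox(X, time, event, offset = offset)
      b <- fit$coefficients[[cand]]; se <- fit$se[[cand]]
      data.frame(candidate = cand, coefficient = b, se = se,
                 p = 2 * stats::pnorm(-abs(b / se)),
                 loglik = fit$loglik[["optimum"]])
    }))
    tab <- tab[order(tab$p, tab$candidate), ]
    best <- tab[1, ]
    entered <- best$p < entry_p
    steps[[length(steps) + 1]] <- list(
      candidates = tab,
      selected = if (entered) best$candidate else NA_character_,
      loglik = best$loglik)
    if (!entered) break
    selected <- c(selected, best$candidate)
    remaining <- setdiff(remaining, best$candidate)
  }
  structure(list(steps = steps, selected = selected,
                 entry_p = entry_p, lp_mode = lp_mode),
            class = "update_trace")
}

#' @export
print.update_trace <- function(x, ...) {
  cat(sprintf("<forward selection (lp_mode = %s, entry p < %g): %d selected>\n",
              x$lp_mode, x$entry_p, length(x$selected)))
  for (i in seq_along(x$steps)) {
    st <- x$steps[[i]]
    cat(sprintf("round %d: %s\n", i,
                if (is.na(st$selected)) "(stop)" else paste("selected", st$selected)))
    print(st$candidates, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
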