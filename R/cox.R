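#' Cox proportional-hazards regression with offset support
#'
#' From-definition maximum partial likelihood with the Efron tie
#' correction, fitted by damped Newton-Raphson (step-halving whenever a
#' step fails to increase the partial likelihood). An offset enters the
#' linear predictor with its coefficient fixed at 1, which is how a
#' published score's linear predictor is held constant while deviations
#' from it are estimated. A model with zero free covariates is allowed
#' when an offset is present (the offset-only null model).
#'
#' @param x covariate matrix (n x p); `NULL` or a 0-column matrix for the
#'   offset-only model. Column names are used in reporting.
#' @param time follow-up times.
#' @param event 0/1 event indicators (at least one event).
#' @param offset optional per-record offset (coefficient fixed at 1).
#' @param max_iter maximum Newton iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return A `cox_fit`: `coefficients`, `se`, `vcov`, `loglik` (named
#'   `null` at beta = 0 and `optimum`), `baseline` (Breslow cumulative
#'   baseline hazard at the event times, anchored at covariate value 0 and
#'   offset 0), `iterations`, `grad_norm`, `offset_used`, `n`, `n_event`.
#' @export
fit_cox <- function(x, time, event, offset = NULL,
                    max_iter = 50, tol = 1e-9) {
  if (is.null(x)) x <- matrix(numeric(0), nrow = length(time), ncol = 0)
  x <- as.matrix(x)
  rownames(x) <- NULL
  if (!is.null(offset)) offset <- unname(offset)
  n <- length(time)
  stopifnot(nrow(x) == n, length(event) == n)
  validate_outcomes(time, event)
  if (sum(event) == 0) stop("at least one event is required", call. = FALSE)
  p <- ncol(x)
  if (is.null(colnames(x)) && p > 0) colnames(x) <- paste0("x", seq_len(p))
  if (is.null(offset)) {
    offset <- rep(0, n); offset_used <- FALSE
  } else {
    stopifnot(length(offset) == n); offset_used <- TRUE
  }
  if (p > 0) {
    const <- which(apply(x, 2, function(col) diff(range(col)) == 0))
    if (length(const) > 0) {
      stop("constant covariate column(s): ",
           paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    }
  }

  ord <- order(time)
  xs <- x[ord, , drop = FALSE]
  ts <- time[ord]; es <- event[ord]; os <- offset[ord]
  ev_times <- unique(ts[es == 1])
  # first sorted index of each unique time value (risk-set entry point)
  first_idx <- match(ev_times, ts)

  pl_parts <- function(beta, need_deriv = TRUE) {
    eta <- drop(xs %*% beta) + os
    eta_c <- eta - max(eta)             # overflow guard; cancels in ratios
    w <- exp(eta_c)
    # suffix sums over the risk sets
    Sw <- rev(cumsum(rev(w)))
    if (need_deriv && p > 0) {
      xw <- xs * w
      Sxw <- apply(xw, 2, function(col) rev(cumsum(rev(col))))
      Sxw <- matrix(Sxw, ncol = p)
      xxw <- matrix(0, n, p * p)
      for (a in seq_len(p)) for (b in seq_len(p)) {
        xxw[, (a - 1) * p + b] <- xs[, a] * xs[, b] * w
      }
      Sxxw <- apply(xxw, 2, function(col) rev(cumsum(rev(col))))
      Sxxw <- matrix(Sxxw, ncol = p * p)
    }
    ll <- 0
    g <- numeric(p)
    H <- matrix(0, p, p)
    for (k in seq_along(ev_times)) {
      i0 <- first_idx[k]
      Dk <- which(ts == ev_times[k] & es == 1)
      d <- length(Dk)
      sR <- Sw[i0]
      sD <- sum(w[Dk])
      ll <- ll + sum(eta_c[Dk])
      if (need_deriv && p > 0) {
        xR <- Sxw[i0, ]
        xD <- colSums(xw[Dk, , drop = FALSE])   # hazard-weighted, for Efron terms
        xxR <- matrix(Sxxw[i0, ], p, p)
        xxD <- matrix(colSums(xxw[Dk, , drop = FALSE]), p, p)
        g <- g + colSums(xs[Dk, , drop = FALSE])
      }
      for (l in seq_len(d) - 1) {
        frac <- l / d
        denom <- sR - frac * sD
        ll <- ll - log(denom)
        if (need_deriv && p > 0) {
          num <- xR - frac * xD
          g <- g - num / denom
          H <- H + (xxR - frac * xxD) / denom - tcrossprod(num) / denom^2
        }
      }
    }
    list(ll = unname(ll), g = unname(g), H = unname(H))
  }

  beta <- numeric(p)
  cur <- pl_parts(beta, need_deriv = p > 0)
  ll_null <- cur$ll
  iter <- 0L
  if (p > 0) {
    repeat {
      iter <- iter + 1L
      info <- cur$H
      step <- tryCatch(solve(info, cur$g), error = function(e) {
        stop("singular information matrix (columns: ",
             paste(colnames(x), collapse = ", "),
             "); possible collinearity or separation", call. = FALSE)
      })
      # damped update: halve until the partial likelihood does not decrease
      scale <- 1
      repeat {
        cand <- beta + scale * step
        new <- pl_parts(cand, need_deriv = TRUE)
        if (is.finite(new$ll) && new$ll >= cur$ll - 1e-12) break
        scale <- scale / 2
        if (scale < 1e-10) {
          stop("Cox fit failed to make progress (iteration ", iter, ")",
               call. = FALSE)
        }
      }
      converged <- abs(new$ll - cur$ll) <= tol * (abs(cur$ll) + 1e-8) ||
        max(abs(new$g)) < 1e-9
      beta <- cand
      cur <- new
      if (converged) break
      if (iter >= max_iter) {
        stop(sprintf(
          "Cox fit did not converge in %d iterations (|grad| = %.3g, ll = %.6g)",
          max_iter, max(abs(cur$g)), cur$ll), call. = FALSE)
      }
    }
  }

  if (p > 0) {
    vc <- tryCatch(solve(cur$H), error = function(e) {
      stop("singular information matrix at optimum", call. = FALSE)
    })
    dimnames(vc) <- list(colnames(x), colnames(x))
    se <- sqrt(diag(vc))
    names(beta) <- colnames(x)
  } else {
    vc <- matrix(numeric(0), 0, 0); se <- numeric(0)
  }

  # Breslow cumulative baseline hazard at eta = 0 (published-score scale)
  eta <- drop(xs %*% beta) + os
  w <- exp(eta)
  Sw <- rev(cumsum(rev(w)))
  d_k <- vapply(ev_times, function(t) sum(ts == t & es == 1), numeric(1))
  haz_inc <- d_k / Sw[first_idx]
  baseline <- data.frame(time = ev_times, cumhaz = cumsum(haz_inc))

  structure(list(coefficients = beta, se = se, vcov = vc,
                 loglik = c(null = ll_null, optimum = cur$ll),
                 baseline = baseline,
                 iterations = iter,
                 grad_norm = if (p > 0) max(abs(cur$g)) else 0,
                 offset_used = offset_used,
                 n = n, n_event = sum(event)),
            class = "cox_fit")
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$vcov

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik[["optimum"]], df = length(object$coefficients),
            class = "logLik")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit: n = %d, events = %d%s, loglik = %.4f>\n",
              x$n, x$n_event, if (x$offset_used) ", offset" else "",
              x$loglik[["optimum"]]))
  if (length(x$coefficients) > 0) print(summary(x)$table)
  invisible(x)
}

#' @export
summary.cox_fit <- function(object, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- object$coefficients; se <- object$se
  tab <- data.frame(coef = b, se = se,
                    hr = exp(b),
                    hr_lower = exp(b - z * se), hr_upper = exp(b + z * se),
                    z = b / se,
                    p = 2 * stats::pnorm(-abs(b / se)))
  structure(list(table = tab, loglik = object$loglik, n = object$n,
                 n_event = object$n_event, offset_used = object$offset_used),
            class = "summary.cox_fit")
}

#' @export
print.summary.cox_fit <- function(x, ...) {
  print(round(x$table, 4))
  cat(sprintf("n = %d, events = %d, loglik (null -> optimum): %.4f -> %.4f\n",
              x$n, x$n_event, x$loglik[["null"]], x$loglik[["optimum"]]))
  invisible(x)
}

#' Likelihood-ratio test for nested Cox models
#'
#' @param nested the restricted fit (e.g. offset-only).
#' @param full the unrestricted fit on the same data with the same offset.
#' @param df degrees of freedom (number of additional free parameters).
#' @return List with `statistic`, `df`, `p`.
#' @export
lr_test <- function(nested, full, df = length(full$coefficients) - length(nested$coefficients)) {
  stopifnot(inherits(nested, "cox_fit"), inherits(full, "cox_fit"))
  stat <- 2 * (full$loglik[["optimum"]] - nested$loglik[["optimum"]])
  if (stat < -1e-6) {
    stop("negative LR statistic: models do not appear to be nested", call. = FALSE)
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
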