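#' Right-censored Weibull accelerated-failure-time fit
#'
#' Maximum likelihood for the log-linear model
#' `ln(T) = mu + gamma * lp + sigma * W`, with `W` following the standard
#' minimum (type 1) extreme value distribution, so `T` is Weibull given
#' the covariate. The scale is parameterised as `log(sigma)` during
#' optimisation; quasi-Newton (BFGS) with analytic gradient, deterministic
#' start (method-of-moments intercept/scale from the event log-times,
#' slope 0). Covariance of `(mu, gamma, log sigma)` comes from the
#' observed information at the optimum.
#'
#' @param lp per-record linear predictor; `NULL` for an intercept-only
#'   fit. A constant nonzero `lp` is rejected (unidentifiable slope).
#' @param time strictly positive times.
#' @param event 0/1 indicators, at least 2 events.
#' @param max_iter maximum BFGS iterations.
#' @return A `weibull_aft`: `coefficients` (`mu`, `gamma` if present,
#'   `sigma`), `se` (delta method for `sigma`), `vcov` on the
#'   `(mu, gamma, log_sigma)` scale, `loglik`, `n`, `n_event`,
#'   `iterations`.
#' @export
fit_weibull_aft <- function(lp, time, event, max_iter = 200) {
  n <- length(time)
  stopifnot(length(event) == n)
  if (any(time <= 0)) stop("all times must be strictly positive", call. = FALSE)
  if (sum(event) < 2) stop("at least 2 events are required", call. = FALSE)
  intercept_only <- is.null(lp) || all(lp == 0)
  if (!intercept_only && diff(range(lp)) == 0) {
    stop("lp is constant; slope is not identifiable (use lp = NULL)", call. = FALSE)
  }
  if (intercept_only) lp <- rep(0, n)
  stopifnot(length(lp) == n)

  y <- log(time)
  d <- as.numeric(event)
  ye <- y[d == 1]
  sigma0 <- stats::sd(ye) * sqrt(6) / pi
  if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- 1
  # E[W] = -Euler-Mascheroni for the minimum extreme value distribution
  mu0 <- mean(ye) + 0.5772156649 * sigma0
  theta0 <- if (intercept_only) c(mu0, log(sigma0)) else c(mu0, 0, log(sigma0))

  unpack <- function(theta) {
    if (intercept_only) list(mu = theta[1], gamma = 0, ls = theta[2])
    else list(mu = theta[1], gamma = theta[2], ls = theta[3])
  }
  nll <- function(theta) {
    p <- unpack(theta); sigma <- exp(p$ls)
    z <- (y - p$mu - p$gamma * lp) / sigma
    ez <- exp(z)
    sum(d * (p$ls - z) + ez)
  }
  grad <- function(theta) {
    p <- unpack(theta); sigma <- exp(p$ls)
    z <- (y - p$mu - p$gamma * lp) / sigma
    u <- exp(z) - d                  # d(nll_i)/d(z_i)
    gmu <- -sum(u) / sigma
    gls <- sum(d) - sum(u * z)
    if (intercept_only) c(gmu, gls)
    else c(gmu, -sum(u * lp) / sigma, gls)
  }
  opt <- stats::optim(theta0, nll, grad, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop("Weibull AFT fit did not converge (optim code ", opt$convergence,
         ", ", opt$counts[["function"]], " evaluations)", call. = FALSE)
  }
  theta <- opt$par
  sigma <- exp(unpack(theta)$ls)
  if (sigma < 1e-6) {
    stop("Weibull AFT scale collapsed towards zero (sigma = ", sigma, ")",
         call. = FALSE)
  }
  info <- stats::optimHess(theta, nll, grad)
  vc <- tryCatch(solve(info), error = function(e) {
    stop("singular observed information in Weibull AFT fit", call. = FALSE)
  })
  par_names <- if (intercept_only) c("mu", "log_sigma")
               else c("mu", "gamma", "log_sigma")
  dimnames(vc) <- list(par_names, par_names)
  se_raw <- sqrt(diag(vc))
  cf <- if (intercept_only) c(mu = theta[1], sigma = sigma)
        else c(mu = theta[1], gamma = theta[2], sigma = sigma)
  se <- if (intercept_only) {
    c(mu = se_raw[["mu"]], sigma = sigma * se_raw[["log_sigma"]])
  } else {
    c(mu = se_raw[["mu"]], gamma = se_raw[["gamma"]],
      sigma = sigma * se_raw[["log_sigma"]])
  }
  # report the likelihood of T itself (log-Jacobian -sum over events of y)
  structure(list(coefficients = cf, se = se, vcov = vc,
                 loglik = -opt$value - sum(d * y), n = n, n_event = sum(d),
                 iterations = opt$counts[["gradient"]],
                 intercept_only = intercept_only),
            class = "weibull_aft")
}

#' @export
coef.weibull_aft <- function(object, ...) object$coefficients

#' @export
vcov.weibull_aft <- function(object, ...) object$vcov

#' @export
logLik.weibull_aft <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
print.weibull_aft <- function(x, ...) {
  cat(sprintf("<weibull_aft: n = %d, events = %d, loglik = %.4f>\n",
              x$n, x$n_event, x$loglik))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}
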