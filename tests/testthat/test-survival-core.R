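# --- Kaplan-Meier ---------------------------------------------------------

test_that("product-limit estimate matches the hand computation on (2, 4+, 5, 7+)", {
  km <- kaplan_meier(c(2, 4, 5, 7), c(1, 0, 1, 0))
  # at t=2: 4 at risk, 1 event -> 3/4; at t=5: 2 at risk, 1 event -> 3/8
  expect_equal(km$time, c(2, 5))
  expect_equal(km$surv, c(3 / 4, 3 / 8))
  expect_equal(km_surv(km, c(0, 1.99, 2, 4.5, 5, 100)),
               c(1, 1, 0.75, 0.75, 0.375, 0.375))
})

test_that("with no censoring the KM equals the empirical survival function", {
  withr::local_seed(2)
  t <- sample(1:50, 30, replace = FALSE)
  km <- kaplan_meier(t, rep(1, 30))
  ecdf_surv <- vapply(km$time, function(tt) mean(t > tt), numeric(1))
  expect_equal(km$surv, ecdf_surv)
  expect_equal(km_surv(km, 0), 1)
})

test_that("KM curve, Greenwood band and median match the survival package", {
  skip_if_not_installed("survival")
  d <- sim_simple(150, beta = 0.8, seed = 4)
  km <- kaplan_meier(d$time, d$event)
  sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1,
                          conf.type = "log-log")
  at_events <- sf$n.event > 0
  expect_equal(km$surv, sf$surv[at_events], tolerance = 1e-12)
  expect_equal(km$lower, sf$lower[at_events], tolerance = 1e-10)
  expect_equal(km$upper, sf$upper[at_events], tolerance = 1e-10)
  med <- km_median_ci(km)
  tab <- summary(sf)$table
  expect_equal(med$median, unname(tab["median"]))
  expect_equal(med$lower, unname(tab["0.95LCL"]))
  expect_equal(med$upper, unname(tab["0.95UCL"]))
})

test_that("median is the first 0.5-crossing and NR when never reached", {
  # toy curve: S(5) = 3/4, S(17) = 3/4 * 1/2 = 0.5 -> first crossing at 17
  km <- kaplan_meier(c(5, 17, 20, 30), c(1, 1, 0, 0))
  expect_equal(km_median_ci(km)$median, 17)
  # uncensored odd-n: median equals the sample median
  t <- c(4, 9, 11, 15, 40)
  expect_equal(km_median_ci(kaplan_meier(t, rep(1, 5)))$median, 11)
  # survival never drops to 0.5 -> not reached
  km_nr <- kaplan_meier(c(5, 10, 20, 25), c(1, 0, 0, 0))
  expect_true(is.na(km_median_ci(km_nr)$median))
})

# --- Cox partial likelihood ----------------------------------------------

test_that("single-covariate fit matches brute-force partial-likelihood grid search", {
  x <- c(0, 1, 1, 0, 1, 0)
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1, 6)
  fit <- fit_cox(cbind(z = x), time, event)
  pl <- function(b) {
    eta <- b * x
    sum(vapply(seq_along(time), function(i) {
      eta[i] - log(sum(exp(eta[time >= time[i]])))
    }, numeric(1)))
  }
  grid <- seq(-3, 3, by = 1e-4)
  b_grid <- grid[which.max(vapply(grid, pl, numeric(1)))]
  expect_equal(unname(coef(fit)), b_grid, tolerance = 1e-4)
  expect_equal(fit$loglik[["optimum"]], pl(coef(fit)[[1]]), tolerance = 1e-10)
})

test_that("scaling a covariate rescales its coefficient exactly", {
  d <- sim_simple(120, beta = 0.7, seed = 6)
  f1 <- fit_cox(cbind(z = d$lp), d$time, d$event)
  f2 <- fit_cox(cbind(z = d$lp / 2.5), d$time, d$event)
  expect_equal(coef(f2)[["z"]], 2.5 * coef(f1)[["z"]], tolerance = 1e-7)
})

test_that("an offset is a covariate with its coefficient frozen at 1", {
  d <- sim_simple(100, beta = 0.9, seed = 7)
  free <- fit_cox(cbind(z = d$lp), d$time, d$event)
  # offset-only model at the fitted coefficient reproduces the optimum
  pinned <- fit_cox(NULL, d$time, d$event,
                    offset = coef(free)[["z"]] * d$lp)
  expect_equal(pinned$loglik[["optimum"]], free$loglik[["optimum"]],
               tolerance = 1e-10)
  # zero offset changes nothing
  null0 <- fit_cox(NULL, d$time, d$event, offset = rep(0, 100))
  expect_equal(null0$loglik[["optimum"]], free$loglik[["null"]],
               tolerance = 1e-12)
})

test_that("refitting the generating score against itself gives a coefficient near 1", {
  d <- sim_simple(800, beta = 1, seed = 8)
  fit <- fit_cox(cbind(lp = d$lp), d$time, d$event, offset = NULL)
  expect_lt(abs(coef(fit)[["lp"]] - 1), 3 * fit$se[["lp"]])
})

test_that("Efron-tied fit agrees with the survival package on censored tied data", {
  skip_if_not_installed("survival")
  d <- sim_simple(250, beta = 0.6, seed = 9)
  x2 <- withr::with_seed(10, stats::rbinom(250, 1, 0.4))
  t_tied <- ceiling(d$time * 8) / 8
  mine <- fit_cox(cbind(a = d$lp, b = x2), t_tied, d$event)
  ref <- survival::coxph(survival::Surv(t_tied, d$event) ~ d$lp + x2,
                         ties = "efron")
  expect_equal(unname(coef(mine)), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(mine$se), unname(sqrt(diag(stats::vcov(ref)))),
               tolerance = 1e-8)
  expect_equal(unname(mine$loglik), unname(ref$loglik), tolerance = 1e-8)
  # with an offset as well
  mine_o <- fit_cox(cbind(b = x2), t_tied, d$event, offset = 0.5 * d$lp)
  ref_o <- survival::coxph(survival::Surv(t_tied, d$event) ~ x2 +
                             offset(0.5 * d$lp), ties = "efron")
  expect_equal(coef(mine_o)[["b"]], unname(coef(ref_o)), tolerance = 1e-6)
})

test_that("Breslow baseline is nondecreasing, zero before the first event", {
  d <- sim_simple(80, beta = 0.5, seed = 11)
  fit <- fit_cox(cbind(z = d$lp), d$time, d$event)
  bl <- fit$baseline
  expect_true(all(diff(bl$cumhaz) > 0))
  expect_equal(bl$time, sort(unique(d$time[d$event == 1])))
  expect_true(all(bl$cumhaz > 0))
})

test_that("degenerate designs are rejected with informative errors", {
  d <- sim_simple(40, beta = 0, seed = 12)
  expect_error(fit_cox(cbind(c1 = rep(2, 40)), d$time, d$event), "c1")
  expect_error(fit_cox(cbind(z = d$lp), d$time, rep(0, 40)), "event")
})

# --- Likelihood-ratio test ------------------------------------------------

test_that("LR test is zero for identical fits and rejects mis-nesting", {
  d <- sim_simple(100, beta = 0.5, seed = 13)
  f <- fit_cox(cbind(z = d$lp), d$time, d$event)
  res <- lr_test(f, f, df = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  null <- fit_cox(NULL, d$time, d$event, offset = rep(0, 100))
  expect_error(lr_test(f, null, df = 1), "nested")
})

test_that("null-simulated LR statistics are approximately chi-square", {
  # data generated under the nested (null) model; df = 3
  n_rep <- 120
  pvals <- vapply(seq_len(n_rep), function(r) {
    withr::local_seed(2000 + r)
    n <- 60
    X <- matrix(stats::rnorm(3 * n), n, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    t <- stats::rexp(n); c <- stats::runif(n, 0, 2)
    time <- pmin(t, c); event <- as.numeric(t <= c)
    full <- fit_cox(X, time, event)
    null <- fit_cox(NULL, time, event, offset = rep(0, n))
    lr_test(null, full, df = 3)$p
  }, numeric(1))
  # uniform p-values: mean 1/2 within 4 binomial-ish SEs, KS not rejecting
  expect_lt(abs(mean(pvals) - 0.5), 4 * sqrt(1 / 12 / n_rep))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("LR and Wald statistics agree asymptotically for one strong covariate", {
  d <- sim_simple(500, beta = 0.8, seed = 14)
  full <- fit_cox(cbind(z = d$lp), d$time, d$event)
  null <- fit_cox(NULL, d$time, d$event, offset = rep(0, 500))
  lr <- lr_test(null, full, df = 1)$statistic
  wald <- (coef(full)[["z"]] / full$se[["z"]])^2
  expect_lt(abs(lr - wald) / wald, 0.2)
})

# --- Weibull AFT ----------------------------------------------------------

test_that("Weibull AFT recovers generating parameters on a large cohort", {
  withr::local_seed(15)
  n <- 2000
  lp <- stats::rnorm(n)
  mu <- -1.0; gamma <- -0.6; sigma <- 1.2
  W <- log(-log(stats::runif(n)))
  t <- exp(mu + gamma * lp + sigma * W)
  c <- stats::rexp(n, rate = 0.08)  # ~20% censoring
  time <- pmin(t, c); event <- as.numeric(t <= c)
  fit <- fit_weibull_aft(lp, time, event)
  cf <- coef(fit)
  expect_lt(abs(cf[["mu"]] - mu), 3 * fit$se[["mu"]])
  expect_lt(abs(cf[["gamma"]] - gamma), 3 * fit$se[["gamma"]])
  expect_lt(abs(cf[["sigma"]] - sigma), 3 * fit$se[["sigma"]])
})

test_that("shifting the linear predictor moves only the intercept", {
  d <- sim_simple(300, beta = 0.7, seed = 16)
  f1 <- fit_weibull_aft(d$lp, d$time, d$event)
  f2 <- fit_weibull_aft(d$lp + 2, d$time, d$event)
  expect_equal(coef(f2)[["gamma"]], coef(f1)[["gamma"]], tolerance = 1e-5)
  expect_equal(coef(f2)[["mu"]], coef(f1)[["mu"]] - 2 * coef(f1)[["gamma"]],
               tolerance = 1e-4)
  expect_equal(coef(f2)[["sigma"]], coef(f1)[["sigma"]], tolerance = 1e-5)
})

test_that("AFT fit agrees with survreg and the intercept-only closed form", {
  skip_if_not_installed("survival")
  d <- sim_simple(200, beta = 0.5, seed = 17)
  mine <- fit_weibull_aft(d$lp, d$time, d$event)
  ref <- survival::survreg(survival::Surv(d$time, d$event) ~ d$lp,
                           dist = "weibull")
  expect_equal(coef(mine)[["mu"]], unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(coef(mine)[["gamma"]], unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(coef(mine)[["sigma"]], ref$scale, tolerance = 1e-6)
  expect_equal(mine$loglik, ref$loglik[2], tolerance = 1e-6)
  # intercept-only on uncensored data vs 1-D profile of the Weibull MLE:
  # for fixed sigma the mu-MLE is sigma * log(mean(exp(y / sigma)))
  withr::local_seed(18)
  t <- exp(0.3 + 0.8 * log(-log(stats::runif(120))))
  io <- fit_weibull_aft(NULL, t, rep(1, 120))
  y <- log(t)
  prof <- function(s) {
    m <- s * log(mean(exp(y / s)))
    z <- (y - m) / s
    -sum(log(s) - z + exp(z))
  }
  s_grid <- seq(0.3, 2, by = 1e-4)
  s_hat <- s_grid[which.max(vapply(s_grid, prof, numeric(1)))]
  expect_equal(coef(io)[["sigma"]], s_hat, tolerance = 1e-3)
  expect_equal(coef(io)[["mu"]], s_hat * log(mean(exp(y / s_hat))),
               tolerance = 1e-3)
})

test_that("AFT preconditions are enforced", {
  d <- sim_simple(50, beta = 0.5, seed = 19)
  expect_error(fit_weibull_aft(d$lp, d$time, rep(0, 50)), "event")
  expect_error(fit_weibull_aft(rep(2, 50), d$time, d$event), "constant")
  expect_error(fit_weibull_aft(d$lp, d$time - min(d$time), d$event), "positive")
})

test_that("all fitters are deterministic given identical inputs", {
  d <- sim_simple(150, beta = 0.6, seed = 20)
  f1 <- fit_cox(cbind(z = d$lp), d$time, d$event)
  f2 <- fit_cox(cbind(z = d$lp), d$time, d$event)
  expect_identical(coef(f1), coef(f2))
  w1 <- fit_weibull_aft(d$lp, d$time, d$event)
  w2 <- fit_weibull_aft(d$lp, d$time, d$event)
  expect_identical(coef(w1), coef(w2))
})
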