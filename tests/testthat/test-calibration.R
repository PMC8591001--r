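# A small exact-Weibull baseline for oracle computations:
# H0(t) = 0.05 * (t/24)^0.8, tabulated at a few knots.
weibull_baseline <- function(knots = c(0, 1, 3, 6, 12, 24)) {
  as_baseline_survival(data.frame(time = knots,
                                  survival = exp(-0.05 * (knots / 24)^0.8)))
}

test_that("cumulative-hazard interpolation is exact for a Weibull baseline", {
  bl <- weibull_baseline()
  t <- c(0, 0.4, 2, 4.7, 9.3, 17, 24)
  expect_equal(baseline_cumhaz(bl, t), 0.05 * (t / 24)^0.8, tolerance = 1e-12)
  # inverse round-trips, including below the first positive knot
  h <- baseline_cumhaz(bl, t[-1])
  expect_equal(baseline_cumhaz_inv(bl, h), t[-1], tolerance = 1e-10)
  expect_equal(baseline_cumhaz_inv(bl, 0), 0)
  expect_true(is.infinite(baseline_cumhaz_inv(bl, 0.2)))
  # beyond the table: error by default, flat on request
  expect_error(baseline_cumhaz(bl, 25), "beyond")
  expect_equal(baseline_cumhaz(bl, 25, extend = "flat"), 0.05)
})

test_that("time transformation is the cumulative baseline hazard", {
  bl <- as_baseline_survival(data.frame(time = c(0, 6, 12, 24),
                                        survival = c(1, 0.9, 0.8, 0.6)))
  tr <- transform_time(c(12, 0, 24), c(1, 0, 1), bl)
  expect_equal(tr$tstar[1], -log(0.8), tolerance = 1e-12)
  expect_equal(tr$tstar[2], 1e-10)  # floored at epsilon
  expect_equal(tr$event, c(1, 0, 1))
  # monotone in t
  ts <- transform_time(seq(0.5, 24, length.out = 40), rep(1, 40), bl)$tstar
  expect_true(all(diff(ts) >= 0))
})

test_that("recalibrated survival reduces to the algebraic identities", {
  bl <- weibull_baseline()
  t <- seq(0.5, 24, length.out = 21)
  lps <- c(-2, -0.5, 0, 1, 2.5)
  for (lp in lps) {
    expect_equal(recalibrated_survival(t, lp, c(0, 0, 1), bl),
                 exp(-baseline_cumhaz(bl, t)), tolerance = 1e-12)
    expect_equal(recalibrated_survival(t, lp, c(0, -1, 1), bl),
                 exp(-baseline_cumhaz(bl, t))^exp(lp), tolerance = 1e-12)
  }
  # generic parameter oracle: direct evaluation of the survival formula
  s0 <- 0.8; lp <- 1
  bl2 <- as_baseline_survival(data.frame(time = c(0, 6, 12), survival = c(1, s0, 0.5)))
  inner <- (log(-log(s0)) - (-1) - (-0.6) * lp) / 1.2
  expect_equal(recalibrated_survival(6, lp, c(-1, -0.6, 1.2), bl2),
               exp(-exp(inner)), tolerance = 1e-12)
  # bounds and monotonicity for assorted parameter draws
  withr::local_seed(30)
  for (r in 1:20) {
    cal <- c(stats::rnorm(1), stats::rnorm(1), stats::rexp(1) + 0.2)
    s <- recalibrated_survival(t, stats::rnorm(1), cal, bl)
    expect_true(all(s > 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("calibration slope is near 1 for self-generated data and tracks attenuation", {
  cfg <- shipped_score_config("erasl_pre")
  co <- simulate_cohort(ship_fixture_configs()$okayama_like, seed = 33, n = 1200)
  lp <- compute_lp(co, cfg)
  sl <- calibration_slope(lp, co$rfs_months, co$event)
  expect_lt(abs(sl$slope - 1), 3 * sl$se)
  expect_true(sl$lower < 1 && 1 < sl$upper)
  # halving the generating effect halves the slope
  cfg_half <- unclass(ship_fixture_configs()$okayama_like)
  cfg_half$outcome$gamma_sim <- 0.5
  co2 <- simulate_cohort(as_sim_config(cfg_half), seed = 34, n = 1200)
  lp2 <- compute_lp(co2, cfg)
  sl2 <- calibration_slope(lp2, co2$rfs_months, co2$event)
  expect_lt(abs(sl2$slope - 0.5), 3 * sl2$se)
})

test_that("Weibull calibration recovers (0, -1, 1) on exactly calibrated data", {
  cfg <- shipped_score_config("erasl_pre")
  co <- simulate_cohort(ship_fixture_configs()$okayama_like, seed = 35, n = 2000)
  lp <- compute_lp(co, cfg)
  cal <- fit_weibull_calibration(lp, co$rfs_months, co$event,
                                 cfg$baseline_survival)
  cf <- coef(cal)
  expect_lt(abs(cf[["mu"]] - 0), 3 * cal$se[["mu"]])
  expect_lt(abs(cf[["gamma"]] + 1), 3 * cal$se[["gamma"]])
  expect_lt(abs(cf[["sigma"]] - 1), 3 * cal$se[["sigma"]])
  expect_equal(cal$tests$contrast,
               c("mu = 0", "gamma = 0", "gamma = -1", "sigma = 1"))
  # gamma = 0 should be firmly rejected when the score carries signal
  expect_lt(cal$tests$p[cal$tests$contrast == "gamma = 0"], 0.001)
})

test_that("an attenuated score effect pulls gamma into (-1, 0)", {
  cfg <- shipped_score_config("erasl_pre")
  weak <- unclass(ship_fixture_configs()$okayama_like)
  weak$outcome$gamma_sim <- 0.4
  co <- simulate_cohort(as_sim_config(weak), seed = 36, n = 2000)
  lp <- compute_lp(co, cfg)
  cal <- fit_weibull_calibration(lp, co$rfs_months, co$event,
                                 cfg$baseline_survival)
  expect_gt(coef(cal)[["gamma"]], -1)
  expect_lt(coef(cal)[["gamma"]], 0)
})

test_that("transformed times from a self-fitted baseline are unit exponential", {
  # self-consistency: S0 from the Breslow baseline of a fit on the same data
  d <- sim_simple(800, beta = 1, seed = 37)
  fit <- fit_cox(cbind(lp = d$lp), d$time, d$event)
  bl <- as_baseline_survival(data.frame(
    time = c(0, fit$baseline$time),
    survival = exp(-c(0, fit$baseline$cumhaz))))
  tr <- transform_time(d$time, d$event, bl, extend = "flat")
  io <- fit_weibull_aft(coef(fit)[["lp"]] * d$lp, tr$tstar, tr$event)
  expect_lt(abs(coef(io)[["mu"]]), 0.1)
  expect_lt(abs(coef(io)[["gamma"]] + 1), 0.1)
  expect_lt(abs(coef(io)[["sigma"]] - 1), 0.1)
})

test_that("grouped calibration table tracks the KM curves for calibrated data", {
  cfg <- shipped_score_config("erasl_pre")
  # for self-generated data the mean predicted curve should sit inside the
  # KM confidence band at 12 and 24 months in the large majority of
  # group-by-time checks across replicates
  inside <- total <- 0
  for (r in 1:5) {
    co <- simulate_cohort(ship_fixture_configs()$okayama_like,
                          seed = 380 + r, n = 1200)
    lp <- compute_lp(co, cfg)
    groups <- assign_risk_groups(lp, cfg, mode = "in_sample")
    tab <- calibration_plot_grouped(lp, co$rfs_months, co$event, groups,
                                    cfg$baseline_survival, plot = FALSE)
    expect_setequal(unique(as.character(tab$group)),
                    c("low", "intermediate", "high"))
    for (g in levels(tab$group)) {
      for (tt in c(12, 24)) {
        row <- tab[tab$group == g & abs(tab$time - tt) < 0.26, ][1, ]
        total <- total + 1
        if (row$predicted >= row$km_lower && row$predicted <= row$km_upper) {
          inside <- inside + 1
        }
      }
    }
  }
  expect_gte(inside / total, 0.9)
})

test_that("recalibration moves predictions towards the observed curves", {
  cfg <- shipped_score_config("erasl_pre")
  # miscalibrated world: events much more frequent than the score predicts
  bad <- unclass(ship_fixture_configs()$okayama_like)
  bad$outcome <- list(mode = "weibull_aft", mu = -1.5, gamma = -0.6,
                      sigma = 1.0, score = "erasl_pre")
  co <- simulate_cohort(as_sim_config(bad), seed = 39, n = 1500)
  lp <- compute_lp(co, cfg)
  groups <- assign_risk_groups(lp, cfg, mode = "in_sample")
  cal <- fit_weibull_calibration(lp, co$rfs_months, co$event,
                                 cfg$baseline_survival)
  tab <- calibration_plot_grouped(lp, co$rfs_months, co$event, groups,
                                  cfg$baseline_survival, cal = cal, plot = FALSE)
  dist_orig <- sum(abs(tab$predicted - tab$km), na.rm = TRUE)
  dist_recal <- sum(abs(tab$recalibrated - tab$km), na.rm = TRUE)
  expect_lt(dist_recal, dist_orig)
  # mu should flag the overall risk-level mismatch
  expect_lt(cal$tests$p[cal$tests$contrast == "mu = 0"], 0.001)
})

test_that("fixed-time calibration flags a uniformly optimistic model", {
  cfg <- shipped_score_config("erasl_pre")
  bad <- unclass(ship_fixture_configs()$okayama_like)
  bad$outcome <- list(mode = "weibull_aft", mu = -1.5, gamma = -1,
                      sigma = 1.0, score = "erasl_pre")
  co <- simulate_cohort(as_sim_config(bad), seed = 40, n = 1200)
  lp <- compute_lp(co, cfg)
  groups <- assign_risk_groups(lp, cfg, mode = "in_sample")
  # under this heavily accelerated outcome a group can run out of patients
  # at risk at the late horizon, which is reported as a warning
  tab <- suppressWarnings(
    calibration_plot_fixed_times(lp, co$rfs_months, co$event, groups,
                                 cfg$baseline_survival, plot = FALSE))
  # predictions systematically above what is observed: points below the line
  expect_true(all(tab$predicted > tab$observed))
  # well-calibrated cohort: points hug the identity line within the KM CI
  co2 <- simulate_cohort(ship_fixture_configs()$okayama_like, seed = 41, n = 1200)
  lp2 <- compute_lp(co2, cfg)
  groups2 <- assign_risk_groups(lp2, cfg, mode = "in_sample")
  tab2 <- calibration_plot_fixed_times(lp2, co2$rfs_months, co2$event, groups2,
                                       cfg$baseline_survival, plot = FALSE)
  expect_true(all(tab2$predicted >= tab2$observed_lower - 0.02 &
                    tab2$predicted <= tab2$observed_upper + 0.02))
})

test_that("empty risk groups are dropped with a warning", {
  cfg <- shipped_score_config("erasl_pre")
  co <- simulate_cohort(ship_fixture_configs()$okayama_like, seed = 42, n = 200)
  lp <- compute_lp(co, cfg)
  groups <- factor(rep("low", 200), levels = c("low", "intermediate", "high"))
  expect_warning(
    tab <- calibration_plot_grouped(lp, co$rfs_months, co$event, groups,
                                    cfg$baseline_survival, plot = FALSE),
    "empty")
  expect_equal(unique(as.character(tab$group)), "low")
})
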