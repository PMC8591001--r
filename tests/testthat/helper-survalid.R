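# Shared fixture builders; everything is generated in code.

# A tiny hand-written cohort data.frame (complete unless edited).
toy_cohort_df <- function(n = 5) {
  data.frame(
    id = paste0("p", seq_len(n)),
    male = rep(c(1, 0), length.out = n),
    albumin_g_l = seq(38, 46, length.out = n),
    bilirubin_umol_l = seq(8, 16, length.out = n),
    afp_ug_l = c(9, 3, 148, 25, 7)[seq_len(n)],
    tumor_size_cm = seq(2, 10, length.out = n),
    tumor_number = rep(c(1, 2), length.out = n),
    mvi = rep(c(0, 1), length.out = n),
    hep_b = rep(0, n),
    hep_c = rep(0, n),
    rfs_months = seq(5, 30, length.out = n),
    event = rep(c(1, 0), length.out = n))
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# Random censored survival data with a single linear predictor effect.
sim_simple <- function(n, beta = 1, seed = 1, cens_max = 3) {
  withr::local_seed(seed)
  lp <- stats::rnorm(n)
  t <- stats::rexp(n, rate = exp(beta * lp))
  c <- stats::runif(n, 0, cens_max)
  list(lp = lp, time = pmin(t, c), event = as.numeric(t <= c))
}

# The shipped Weibull-shaped baseline (used directly in several oracles).
shipped_baseline <- function() shipped_score_config("erasl_pre")$baseline_survival

# Brute-force concordance oracles, written as plain double loops over pairs.
harrell_oracle <- function(lp, time, event) {
  conc <- 0; usable <- 0
  n <- length(lp)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      usable <- usable + 1
      if (lp[i] > lp[j]) conc <- conc + 1
      if (lp[i] == lp[j]) conc <- conc + 0.5
    }
  }
  conc / usable
}

gh_oracle <- function(lp) {
  n <- length(lp); s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- lp[i] - lp[j]
    s <- s + if (d >= 0) 1 / (1 + exp(-d)) else 1 / (1 + exp(d))
  }
  2 * s / (n * (n - 1))
}
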