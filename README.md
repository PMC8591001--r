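# survalid

External validation and recalibration of prognostic survival risk
scores, instantiated on the preoperative and postoperative ERASL
models for early hepatocellular-carcinoma (HCC) recurrence after liver
resection.

## What it does, and for whom

A published risk score condenses a patient's covariates into a linear
predictor $LP = \sum_k \beta_k f_k(x_k)$ and predicts recurrence-free
survival through the derivation cohort's baseline survival,
$S(t\mid LP) = S_0(t)^{\exp(LP)}$. Biostatisticians and clinical
researchers who want to know whether such a score still works on
*their* cohort need three things checked:

1. **Misspecification** — the calibration slope (the Cox coefficient
   of $LP$ as the only covariate; 1 under correct relative risks) and
   offset regressions in which every score covariate is re-estimated
   alongside $LP$ pinned at coefficient 1, with a likelihood-ratio
   test of the joint deviation.
2. **Discrimination** — Harrell's C, Gönen–Heller K,
   Royston–Sauerbrei $R^2_D$ and the time-dependent AUC, each with
   bootstrap confidence intervals (B = 200).
3. **Calibration** — grouped and fixed-time calibration curves, plus
   the Weibull calibration model
   $\ln T^* = \mu + \gamma LP + \sigma W$ on baseline-transformed
   event times $T^* = -\ln S_0(T)$, where $(\mu,\gamma,\sigma) =
   (0,-1,1)$ is perfect calibration: $\mu$ captures the overall risk
   level, $\gamma$ the (possibly exaggerated) impact of the score,
   $\sigma$ the baseline shape. Recalibrated predictions follow
   $S(t\mid LP)_{cal} = \exp(-\exp(\frac{1}{\sigma}(\ln(-\ln S_0(t)) -
   \mu - \gamma LP)))$.

The survival engine (Kaplan–Meier with Greenwood/log-log intervals,
Cox partial likelihood with Efron ties and offset support, censored
Weibull AFT) is implemented from definition and cross-checked in the
tests against the `survival` package and brute-force oracles. A
synthetic cohort generator reproduces the published covariate margins
of a Western (Rotterdam-style) and an Eastern (Okayama-style)
validation cohort so the whole pipeline runs and is tested without any
patient-level data. The shipped score configurations mirror the ERASL
term structure but carry clearly labelled synthetic stand-in
constants; transcribe the published supplement into a YAML config to
validate the real scores.

## A worked example

```r
library(survalid)
cohort <- simulate_cohort(ship_fixture_configs()$rotterdam_like,
                          seed = 7, n = 400)
config <- shipped_score_config("erasl_pre")
report <- validate_score(cohort, config, bootstrap = 200, seed = 1,
                         quiet = TRUE)
report
```

```
# Validation of erasl_pre on rotterdam_like

Analyzed 336 of 400 records (64 excluded for missing covariates); 24-month horizon.

## Risk groups

| Group | n (%) | Median RFS (95% CI) | HR (95% CI) |
|---|---|---|---|
| low | 168 (50%) | NR (NR-NR) | 1 (ref) |
| intermediate | 117 (35%) | NR (NR-NR) | 2.4 (1.4-4.1) |
| high | 51 (15%) | NR (13-NR) | 3.5 (1.9-6.3) |

## Misspecification

Calibration slope 0.88 (95% CI 0.56-1.20); joint offset LR test: chi2 = 4.06 on 5 df, p = 0.541.

## Discrimination

| Statistic | Estimate (95% CI) |
|---|---|
| harrell_c | 0.67 (0.61 to 0.73) |
| gonen_heller_k | 0.68 (0.67 to 0.69) |
| royston_sauerbrei_r2d | 0.21 (0.09 to 0.33) |
| tdauc | 0.71 (0.64 to 0.78) |

## Weibull calibration

mu = -0.24 (-1.13 to 0.65), gamma = -0.82 (-1.15 to -0.48), sigma = 0.92 (0.75 to 1.13); perfect calibration is (0, -1, 1).
```

Reading it: this cohort was generated from the score itself, so the
in-sample percentile grouping splits 50/35/15, the hazard ratios rise
across risk groups, the calibration slope's interval covers 1, the
joint deviation test finds nothing (p = 0.54), discrimination is
moderate (C = 0.67), and the Weibull calibration interval covers
$(0, -1, 1)$ — the signature of a correctly specified score. "NR"
means the Kaplan–Meier median was not reached within the 24-month
horizon. On a cohort the score does *not* describe, the slope falls
below 1, $\mu$ goes negative (observed recurrence faster than
predicted) and $\gamma$ lands inside $(-1, 0)$ (prognostic differences
exaggerated); the recalibrated curves then track the observed
Kaplan–Meier curves.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/survalid simulate --config rotterdam_like --n 400 --seed 7 --out cohort.csv
Rscript inst/cli/survalid validate --cohort cohort.csv --score erasl_pre --bootstrap 200 --seed 1 --out out/
```

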