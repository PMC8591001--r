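# Synthetic cohort emulating the published covariate margins of an
# Eastern (Okayama-style) HCC resection cohort: male 79%, mean albumin
# 40 +/- 4.6 g/L, median bilirubin 12 (9-15) umol/L, median AFP
# 10 (4-78) ug/L, median largest tumour 3.5 (2.3-6.0) cm, 71% solitary,
# MVI 29%, hepatitis B 27% / C 47%, no missing values. Censoring tuned
# so ~85% of patients have >= 2 years of follow-up.
name: okayama_like
n: 500
covariates:
  male:          {p: 0.79}
  albumin:       {mean: 40, sd: 4.6}
  bilirubin:     {median: 12, q1: 9, q3: 15}
  afp:           {median: 10, q1: 4, q3: 78}
  tumor_size:    {median: 3.5, q1: 2.3, q3: 6.0}
  tumor_number:  {p_solitary: 0.71, extra_lambda: 0.7}
  mvi:           {p: 0.29}
  hep_b:         {p: 0.27}
  hep_c:         {p: 0.47}
outcome:
  mode: ph
  gamma_sim: 1
  score: erasl_pre
censoring:
  type: uniform
  max: 160
truncation: 24
missingness: {}
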