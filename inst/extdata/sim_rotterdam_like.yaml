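# Synthetic cohort emulating the published covariate margins of a
# Western (Rotterdam-style) HCC resection cohort: male 70%, mean albumin
# 42 +/- 5.8 g/L, median bilirubin 10 (7-15) umol/L, median AFP
# 9 (3-148) ug/L, median largest tumour 5.9 (3.2-9.6) cm, 79% solitary,
# MVI 58%, hepatitis B 25% / C 15%. Outcome, censoring and missingness
# parameters are documented package choices: proportional hazards on the
# preoperative score's linear predictor through the derivation baseline,
# uniform censoring tuned so ~77% of patients have >= 2 years of
# follow-up, 24-month administrative truncation, and the per-field
# missing-value rates observed in a 312-patient registry extract.
name: rotterdam_like
n: 500
covariates:
  male:          {p: 0.70}
  albumin:       {mean: 42, sd: 5.8}
  bilirubin:     {median: 10, q1: 7, q3: 15}
  afp:           {median: 9, q1: 3, q3: 148}
  tumor_size:    {median: 5.9, q1: 3.2, q3: 9.6}
  tumor_number:  {p_solitary: 0.79, extra_lambda: 0.7}
  mvi:           {p: 0.58}
  hep_b:         {p: 0.25}
  hep_c:         {p: 0.15}
outcome:
  mode: ph
  gamma_sim: 1
  score: erasl_pre
censoring:
  type: uniform
  max: 104
truncation: 24
missingness:
  albumin_g_l: 0.0801
  bilirubin_umol_l: 0.0353
  afp_ug_l: 0.0385
  tumor_size_cm: 0.0096
  tumor_number: 0.0096
  mvi: 0.0865
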