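# Preoperative ERASL-style risk score configuration.
#
# SYNTHETIC STAND-IN: the term structure (male gender, ALBI grade 2/3,
# ln AFP, ln largest tumour size, multiple tumours) mirrors the published
# preoperative ERASL score, but the coefficient values, fixed group
# cut-points and baseline survival table below are synthetic placeholders
# chosen to reproduce the published score's distributional behaviour
# (validation-cohort scores ~ 2.0 +/- 0.7, ~78% low risk under the fixed
# cuts, ~36% two-year recurrence for a median derivation patient).
# Replace them with the published constants before any clinical use.
name: erasl_pre
source: synthetic stand-in for the published preoperative ERASL specification
terms:
  - covariate: male
    transform: indicator
    coefficient: 0.70
  - covariate: albi_grade_23
    transform: indicator
    coefficient: 0.85
  - covariate: afp
    transform: log
    coefficient: 0.10
  - covariate: tumor_size
    transform: log
    coefficient: 0.45
  - covariate: multiple_tumors
    transform: indicator
    coefficient: 0.50
albi:
  bilirubin_coef: 0.66
  albumin_coef: -0.085
  cuts: [-2.60, -1.39]
grouping:
  cuts: [2.56, 3.52]        # derivation 50th / 85th percentile stand-ins
  percentiles: [50, 85]
afp_floor: 0.1
baseline_survival:          # derivation S0(t), Weibull-shaped stand-in
  time:     [0, 1, 2, 3, 6, 9, 12, 18, 24]
  survival: [1.0, 0.9960740289, 0.9931744348, 0.9905715011, 0.9836414299,
             0.9774446011, 0.9716909683, 0.9610576386, 0.9512294245]
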