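# Postoperative ERASL-style risk score configuration.
#
# SYNTHETIC STAND-IN: adds the microvascular-invasion indicator to the
# preoperative term structure, mirroring the published postoperative
# ERASL score; all constants are synthetic placeholders (see
# erasl_pre_synthetic.yaml for the rationale).
name: erasl_post
source: synthetic stand-in for the published postoperative ERASL specification
terms:
  - covariate: male
    transform: indicator
    coefficient: 0.65
  - covariate: albi_grade_23
    transform: indicator
    coefficient: 0.80
  - covariate: afp
    transform: log
    coefficient: 0.09
  - covariate: tumor_size
    transform: log
    coefficient: 0.40
  - covariate: multiple_tumors
    transform: indicator
    coefficient: 0.45
  - covariate: mvi
    transform: indicator
    coefficient: 0.80
albi:
  bilirubin_coef: 0.66
  albumin_coef: -0.085
  cuts: [-2.60, -1.39]
grouping:
  cuts: [2.33, 3.45]        # derivation 50th / 85th percentile stand-ins
  percentiles: [50, 85]
afp_floor: 0.1
baseline_survival:          # derivation S0(t), Weibull-shaped stand-in
  time:     [0, 1, 2, 3, 6, 9, 12, 18, 24]
  survival: [1.0, 0.9960740289, 0.9931744348, 0.9905715011, 0.9836414299,
             0.9774446011, 0.9716909683, 0.9610576386, 0.9512294245]
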