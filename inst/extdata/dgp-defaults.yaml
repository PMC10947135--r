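# Default structural coefficients for the longitudinal simulation model.
# Continuous baseline covariate enters all linear predictors standardized
# (analytic mean/sd of the rescaled beta distribution).
#
# Treatment-effect coefficients (y.a, y.a_lag, x.a_lag) are calibrated by
# root search on a common multiplier so that the interventional
# always-vs-never contrast in mean end-of-follow-up outcome equals
# true_ate (see calibrate_ate); with the linear outcome/confounder
# equations the contrast is exactly
#   y.a + y.a_lag + y.x * x.a_lag * (1 + x.lag + x.lag^2).
b_bin_prevalence: 0.06
b_cont:
  shape1: 5.0
  shape2: 3.0
  min: 18.0
  max: 90.0
x0:
  intercept: 0.0
  b_bin: 0.3
  b_cont: 0.3
  sd: 1.0
x:
  intercept: 0.0
  lag: 0.5
  a_lag: -0.25806452
  b_bin: 0.3
  b_cont: 0.2
  sd: 1.0
a:
  intercept: -0.8
  lag: 1.2
  x: 0.5
  y_lag: -0.3
  b_bin: 0.2
  b_cont: 0.2
"y":
  intercept: 0.5
  a: 0.03225806
  a_lag: 0.03225806
  x: -0.3
  y_lag: 0.0
  b_bin: -0.2
  b_cont: -0.2
  sd: 1.0
outcome_noise:
  skew_low_sdlog: 0.5
  skew_high_sdlog: 1.0
  # artifact thresholds for the skewness property checks
  skewness_threshold_low: 0.5
  skewness_threshold_high: 1.5
true_ate:
  normal: 0.2
  skew_low: -0.2
  skew_high: -0.2
# Interaction between the two confounders (standardized continuous
# baseline x current time-varying confounder) present in the true outcome
# and missingness mechanisms under misspecification scenarios, scaled so
# it accounts for ~5% (low) / ~15% (high) of linear-predictor variance.
misspec:
  low:
    y_x_bcont: 0.0855
    r_x_bcont: 0.1252
  high:
    y_x_bcont: 0.1566
    r_x_bcont: 0.2292
missingness:
  slopes:
    nonmonotone:
      a_lag: -0.3
      x_lag: 0.3
      y_lag: -0.3
      b_bin: 0.3
      b_cont: 0.2
    dropout:
      a_lag: -0.3
      x_lag: 0.3
      y_lag: -0.3
      b_bin: 0.3
      b_cont: 0.2
  # Calibrated intercepts (bisection against a 50k-person simulated
  # cohort; see calibrate_missingness_intercepts) keyed by
  # pattern_level_outcomedist_misspec. Recomputed on demand for
  # combinations not listed.
  intercepts:
    nm_outcome_low_normal_none: {nonmonotone: -1.968653, dropout: -3.128119}
    nm_outcome_high_normal_none: {nonmonotone: -0.468609, dropout: -2.018127}
    nm_confounder_low_normal_none: {nonmonotone: -1.993178, dropout: -3.128119}
    nm_confounder_high_normal_none: {nonmonotone: -0.465927, dropout: -2.018127}
    nm_both_low_normal_none: {nonmonotone: -1.968653, dropout: -3.128119}
    nm_both_high_normal_none: {nonmonotone: -0.468609, dropout: -2.018127}
    monotone_low_normal_none: {dropout: -3.128119}
    monotone_high_normal_none: {dropout: -2.018127}
    mixed_low_normal_none: {nonmonotone: -2.722231, dropout: -3.128119}
    mixed_high_normal_none: {nonmonotone: -1.286972, dropout: -2.018127}
    mixed_low_skew_low_none: {nonmonotone: -2.765103, dropout: -3.154727}
    mixed_high_skew_low_none: {nonmonotone: -1.331386, dropout: -2.038008}
    mixed_low_skew_high_none: {nonmonotone: -2.757597, dropout: -3.149214}
    mixed_high_skew_high_none: {nonmonotone: -1.334200, dropout: -2.029110}
    mixed_high_normal_low: {nonmonotone: -1.307826, dropout: -2.051627}
    mixed_high_normal_high: {nonmonotone: -1.327475, dropout: -2.084897}
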