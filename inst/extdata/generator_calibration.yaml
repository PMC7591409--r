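# Default calibration constants for the synthetic cohort generator.
# These are calibration values, chosen so that the generated cohorts
# reproduce the marginal statistical structure the analyses assume
# (right-skewed baseline frailty with median 0.16 and IQR 0.14, baseline
# falls incidence, frailty-dependent mortality and attrition thinning
# 1044 -> 715 -> 382). They are not person-level study parameters.
frailty_shape:
  alpha: 2.237726        # Beta distribution on [0,1]; median 0.16, IQR 0.14
  beta: 10.38683
frailty_drift: [0.065, 0.130]   # additive index shift at +5 y and +10 y
frailty_noise_sd: [0.03, 0.04]  # trajectory noise at +5 y and +10 y
mortality:
  base: 0.30             # 10-year mortality below the knee
  slope: 1.5             # additional mortality per unit index above the knee
  knee: 0.25
  first_interval_share: 0.38   # share of 10-year deaths in the first 5 years
attendance:
  target: [1.0, 0.68487, 0.36590]   # expected attendees / baseline n per visit
  slope_per_001: 0.04    # attendance log-odds decrease per 0.01 of index
falls:
  target_any: [0.284, 0.310, 0.447]        # P(>=1 fall) among attendees, per visit
  target_recurrent: [0.147, 0.176, 0.264]  # P(>=2 falls) among attendees, per visit
  log_or_any_per_001: 0.03922071315328133      # log(1.04)
  log_or_recurrent_per_001: 0.04879016416943205  # log(1.05)
  extra_falls:           # falls beyond 2 among recurrent fallers (neg. binomial)
    dispersion: 1.2
    mu_base: 0.5
    mu_slope: 2.5        # extra-falls mean increase per unit index
missingness_falls: [0.1245, 0.0056, 0.0]  # P(falls data missing) per visit
deficit_missingness: 0.01                 # per-item missingness per visit
binary_prevalence_scale: 0.7   # P(binary deficit) = 0.7 x latent index
covariates:
  bmi: {mean: 26.3, sd: 4.05, fi_slope: 5.5}
  s25ohd: {mean: 61.8, sd: 19.0, fi_slope: -30.0}
  smoking: {p_never: 0.657, p_previous: 0.202, p_current: 0.141, fi_slope: 1.5}
  prior_fracture: {p: 0.371, fi_logit_slope: 2.0}
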