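# Synthetic progression-group profiles (version 1).
#
# Four planted groups ordered slow -> fast in total monthly decline:
#   SP  (slow progressors)
#   MPb (moderate progressors, mainly bulbar; respiratory involvement)
#   MPs (moderate progressors, mainly spinal: limbs/trunk)
#   FP  (fast progressors)
# Decline rates are points/month on each ALSFRS-R functional-domain
# subscore; baselines are the domain subscores at the first visit;
# survival medians are months from the first visit. All values are this
# package's own emulation choices, calibrated so the four groups mirror
# the qualitative trajectory shapes of the clinical progression groups
# and are recoverable, but still overlap in individual features.
version: 1
visit_gap_days_mean: 90
visit_gap_gamma_shape: 36
horizon_months: 96
profiles:
  SP:
    fraction: 0.31
    rates: {bulbar: 0.12, upper_limb: 0.18, lower_limb: 0.20, trunk: 0.18, respiratory: 0.12}
    plateau_prob: 0.05
    improve_prob: 0.02
    noise_sd: 0.15
    baseline_mean: {bulbar: 10.8, upper_limb: 7.0, lower_limb: 6.6, trunk: 7.0, respiratory: 11.2}
    baseline_sd: {bulbar: 0.28, upper_limb: 0.28, lower_limb: 0.35, trunk: 0.28, respiratory: 0.18}
    survival: {median_months: 84, censor_frac: 0.20}
  MPb:
    fraction: 0.27
    rates: {bulbar: 0.85, upper_limb: 0.15, lower_limb: 0.10, trunk: 0.15, respiratory: 0.38}
    plateau_prob: 0.05
    improve_prob: 0.02
    noise_sd: 0.15
    baseline_mean: {bulbar: 6.0, upper_limb: 7.0, lower_limb: 6.6, trunk: 7.0, respiratory: 10.2}
    baseline_sd: {bulbar: 0.42, upper_limb: 0.28, lower_limb: 0.35, trunk: 0.28, respiratory: 0.28}
    survival: {median_months: 42, censor_frac: 0.20}
  MPs:
    fraction: 0.26
    rates: {bulbar: 0.06, upper_limb: 0.60, lower_limb: 0.60, trunk: 0.45, respiratory: 0.10}
    plateau_prob: 0.05
    improve_prob: 0.02
    noise_sd: 0.15
    baseline_mean: {bulbar: 11.4, upper_limb: 4.4, lower_limb: 4.0, trunk: 5.0, respiratory: 11.4}
    baseline_sd: {bulbar: 0.28, upper_limb: 0.42, lower_limb: 0.42, trunk: 0.35, respiratory: 0.28}
    survival: {median_months: 38, censor_frac: 0.20}
  FP:
    fraction: 0.16
    rates: {bulbar: 0.50, upper_limb: 0.50, lower_limb: 0.45, trunk: 0.45, respiratory: 0.40}
    plateau_prob: 0.05
    improve_prob: 0.02
    noise_sd: 0.15
    baseline_mean: {bulbar: 7.2, upper_limb: 5.2, lower_limb: 4.8, trunk: 5.2, respiratory: 9.8}
    baseline_sd: {bulbar: 0.42, upper_limb: 0.42, lower_limb: 0.42, trunk: 0.35, respiratory: 0.35}
    survival: {median_months: 16, censor_frac: 0.15}
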