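# Default monitoring scenario: 5 injured + 26 control patients over a
# 135-day span, ~8 h daily wear, noise calibrated so an uninjured patient's
# window statistic averages ~2.2 degrees F. Peak offsets of the injury
# archetypes are set in default_injury_presets().
generator:
  n_study: 5
  n_control: 26
  days: 135
  wear_minutes_per_day_mean: 480
  wear_minutes_per_day_sd: 60
  baseline_temp_mean: 85.0
  baseline_temp_sd: 1.5
  bilateral_noise_sd: 1.95
  circadian_amplitude: 1.5
  drift_sd: 0.3
  ambient_temp: 72.0
  seed: 20201201
alerts:
  threshold: 4.0
  escalation_days: 5
  min_minutes: 30
window_days: 15
minutes_budget: 900
min_wear_days: 50
min_minutes_per_day: 30
statistic_mode: minute_pooled
seed: 1
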