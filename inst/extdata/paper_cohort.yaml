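# Default cohort calibration: 13 patients (6 anterior / 7 posterior),
# 70-day follow-up, GPS 1 min on / 4 min off, accelerometer 10 s on /
# 10 s off. Week-1 / week-5 raw-scale targets per surgical arm; pooled
# across arms these give distance 3.04 / 13.89 km, home 14.63 / 14.05 h,
# count 1.33 / 2.44, entropy 0.10 / 0.26 nats, raw steps 108.83 / 250.
# These values mirror default_targets() / default_prom_targets(); pass the
# file to `mobiphen simulate --cohort-config` to tweak a copy.
n_patients: 13
n_anterior: 6
follow_up_days: 70
targets:
  anterior:
    distance_km: [3.04, 13.89]
    home_hours: [15.1317, 13.2917]
    sig_loc_count: [1.45, 2.70]
    sig_loc_entropy: [0.120, 0.300]
    steps: [160, 260]
  posterior:
    distance_km: [3.04, 13.89]
    home_hours: [14.20, 14.70]
    sig_loc_count: [1.2271, 2.2171]
    sig_loc_entropy: [0.0829, 0.2257]
    steps: [64.969, 241.429]
day_missing_prob: 0.08
vas_response_prob: 0.5
weekly_response_prob:
  mJOA: 0.71
  ODI: 0.74
  NDI: 0.69
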