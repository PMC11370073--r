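# Scaled-down demonstration configuration: same analysis constants as the
# defaults (30 Hz, 15-s windows, 13 mg / 30 min non-wear, 480-min valid
# days, 4 valid days incl. 1 weekend day, 180/60-min guideline thresholds,
# 4-knot splines), smaller simulated problem sizes.
seed: 20190501
classifier:
  n_trees: 200
corpus:
  n_subjects: 8
  session_s: 300
recordings:
  n_children: 2
  n_days: 5
  day_minutes: 600
cohort:
  n_children: 120
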