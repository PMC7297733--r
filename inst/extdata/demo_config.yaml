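# Demo configuration for the full pipeline on a synthetic cohort.
# All randomness flows from this single seed.
seed: 76
stages: [simulate, assign, detect, enrich, date, copy_number, phase, expression]
cohort:
  # omitted fields fall back to the Table-style defaults (539 tumours,
  # 19 events, 11 A1d1a donors); the demo runs a scaled-down cohort
  n_tumours: 120
  n_ht_events: 10
enrichment:
  target: A1d1a
  replicates: 10000
rate:
  mean_mutations: 9.437
  divergence_years: 469.28
  divergence_interval: [240.34, 744.31]
expression:
  n_per_group: 15
  effect_fraction: 0.39
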