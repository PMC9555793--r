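# Default synthetic-cohort configuration (registry-scale)
spec:
  n_patients: 555
  visit_range: [3, 8]
seed: 1
thresholds:
  min_support: 0.01
  min_confidence: 80
  max_antecedent_length: 3
n_pairs: 500
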