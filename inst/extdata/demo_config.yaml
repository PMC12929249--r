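# Demo pipeline configuration: a small synthetic cohort run end to end.
simulate:
  n_patients: 200
  negation_rate: 0.2
study_start: "2017-01-01"
study_end: "2020-12-31"
seed: 20170101
lca:
  c_min: 2
  c_max: 3
  n_restarts: 3
  max_iter: 200
  tol: 1.0e-6
  criterion: BIC
outcomes:
  vl_threshold: 200
  boundary_rule: exclude
reference_class: 1
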