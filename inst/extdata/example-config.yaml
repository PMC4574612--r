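# Example pipeline configuration. Any key omitted here falls back to
# the documented default (see ?default_config); unknown keys are
# rejected.
seed: 101
output_dir: lignin-run
sampler:
  n_sets: 5000
  lhs_fraction: 0.1
screening:
  configs: [1, 2, 3]
  rel_tol: 0.2
pca:
  k: 4
validate:
  run: true
  level: 0.4
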