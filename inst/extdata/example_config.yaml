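# Example pipeline configuration: compares the regulated (wild-type-like)
# and deregulated (c-di-GMP network removed) presets at reduced size.
presets:
  - regulated
  - deregulated
simulation:
  n_traps: 60
  t_total: 1500
threshold: 1000
population:
  gate: 1000
  auto_gate: false
  n_cells: 10000
  n_replicates: 3
  f_positive:
    regulated: 0.30
    deregulated: 0.46
seed: 1
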