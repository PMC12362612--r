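# Example run configuration for the fatecontrol CLI.
# Keys mirror kinetic_params() / controller_config() arguments exactly;
# unknown keys are rejected.
model: controlled_toggle
params:
  alpha1: 2.2
  alpha2: 2.2
  K: 1
  m: 3
  delta: 1
  xi: 1
  theta: 1
  k: 1
  beta: 1
  gamma: 100
controller:
  sense_species: Y1
  sense_regulation: repressing
  input_species: U1
  actuation: additive_activation
  target_species: Y1
  duplicated: single
simulation:
  n: 1000
  t_end: 200
  omega: 1
  seed: 1
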