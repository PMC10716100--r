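# Optogenetic junction contraction on a soft gel: 20-minute activation of
# the shared junction of two central cells with remodeling enabled.
scenario: optogenetic
seed: 7
target_cells: 16
stiffness:
  kind: uniform
  E_near: 1.1
  E_far: 1.1
activation:
  multiplier: 13
  t_on: 120
  t_off: 1320
  duration: 1560
out_dir: optogenetic-run
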