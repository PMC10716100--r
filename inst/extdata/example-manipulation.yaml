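# Single-cell micromanipulation on a uniform soft gel: grow a small
# epithelium, pull the center cell 30 um at 30 um/s, write displacement
# tables. Run with:  episheet manipulate --config example-manipulation.yaml
scenario: manipulate
seed: 7
target_cells: 19
stiffness:
  kind: uniform
  E_near: 1.1
  E_far: 1.1
pipette:
  distance: 30
  speed: 30
  grab_radius: 4
  hold_after: 1
out_dir: manipulation-run
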