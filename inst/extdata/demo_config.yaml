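# Demo configuration: a reduced version of the default two-species design
# that runs end-to-end in well under a minute on one CPU.
seed: 1
design:
  cells_per_branch: 120
  terminal_cells_per_class: 80
  fraction_low_quality: 0.08
cluster:
  resolution: 7
fate:
  top_n: 50
  cap: 1000
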