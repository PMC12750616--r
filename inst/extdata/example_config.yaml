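# Example run configuration: a reduced cohort for a quick end-to-end run.
# Omitted keys take the documented defaults (see default_config()).
seed: 20260921
outdir: kinlearn-example
sim:
  n_per_arm: 20
  weeks: 12
  solver: exact
de:
  generations: 80
fit:
  n_boot: 50
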