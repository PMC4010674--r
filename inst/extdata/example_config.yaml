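# Example cmcfield run configuration.
seed: 1
outdir: cmcfield-run
grid:
  fmin: 4
  fmax: 90
  n_freq: 24
  n_k: 32
conditions: [0, 5, 10, 16, 23, 32, 44, 60, 82]
n_epochs: 256
model:
  id: 7
  variant: field
inversion:
  max_iter: 64
  tol: 0.01
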