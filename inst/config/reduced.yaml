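# Desk-scale pipeline configuration: every stage runs in minutes.
seed: 1
out_dir: oblearn_reduced
design:
  n_participants: 10
  n_blocks: 2
fit:
  chains: 4
  warmup: 200
  iter: 200
recovery:
  model_reps: 2
  parameter_reps: 2
  chains: 4
  warmup: 200
  iter: 200
regress:
  nAGQ: 0
ppc:
  reps: 20
  refit_glmm: false
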