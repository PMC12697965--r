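# Full-scale pipeline configuration: 74 participants, 4 blocks,
# 4 chains x 1000 warmup + 1000 sampling iterations, 40 recovery
# replicates, 500 posterior predictive replicates.
seed: 1
out_dir: oblearn_full
design:
  n_participants: 74
  n_blocks: 4
fit:
  chains: 4
  warmup: 1000
  iter: 1000
recovery:
  model_reps: 40
  parameter_reps: 40
  chains: 4
  warmup: 200
  iter: 200
regress:
  nAGQ: 1
ppc:
  reps: 500
  refit_glmm: true
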