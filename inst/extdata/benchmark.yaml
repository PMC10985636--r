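seed: 20260101
phantom: []
cohort:
  n_train: 60
  n_test: 80
train:
  epochs: 24
  lr: 0.003
  w_ce: 1.0
  w_dice: 1.0
  folds: 5
  width: 6
  use_oracle_masks: no
  detection_threshold: 0.45
  min_candidate_size: 1
schedule:
  refresh: 5
  rho: 0.5
  warmup: 5
noise:
  eps: 0.02
  iters: 10
  lambda_style: 0.05
  lambda_content: 0.5
  lambda_adv: 1.0
  restrict_to_body: yes
eval:
  bootstrap_B: 1000
  min_overlap: 0.1
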