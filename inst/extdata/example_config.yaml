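# Example experiment configuration: a small sweep of environmental
# resource availability at high cooperation efficiency.  Any sim_params
# field may appear under `params`; `schedule` selects constant or
# sinusoidal forcing; `plan` holds the sweep axes, scenarios, replicate
# count and master seed (replicate i runs with seed `seed + i`).
params:
  bK: 5.0
  T: 60
  N_init: 40
  n_groups: 10
schedule:
  kind: constant
plan:
  sweep:
    R00: [1, 4, 8]
  scenarios: [social]
  reps: 4
  seed: 11
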