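{
  "n_participants": 4,
  "n_blocks": 2,
  "trials_per_block": 24,
  "accuracy_range": [0.65, 0.85],
  "fs_raw": 64,
  "n_channels": 16,
  "seed": 7
}
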