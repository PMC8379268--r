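# Example fixtures

Worked examples of the package's plain-text formats, generated by
`cbci::simulate_experiment()` (synthetic; seed 1):

- `trials_example.csv` — the trial-table contract of `read_trials()` /
  `write_trials()`: one row per participant x trial, columns
  `participant_id, block, trial_id, true_label, decision,
  response_timestamp_s, reported_confidence, confidence_timestamp_s,
  correctness`; empty fields are missing values (empty doors, no-response
  trials).
- `frames_trial_example.csv` — one trial's frame stream for
  `read_frames()` / `detect_onset()`: `frame_index, timestamp_s, mean_r,
  mean_g, mean_b` at the configured frame rate (4 Hz here), with the hidden
  character-onset step visible as a mean-RGB jump.
- `config_example.json` — a `--config` document for the `cbci` CLI
  (`exec/cbci simulate --config ... --out-dir ...`); keys mirror
  `sim_config()` arguments and unknown keys are rejected.

The epoch container (`write_epochs()`) is a directory format — `meta.json`
plus one `<participant>_data.csv` matrix per participant — and is exercised
end-to-end in the test suite rather than stored here.
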