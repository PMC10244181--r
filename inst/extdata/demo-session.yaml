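# Demo pipeline configuration: simulate a 10-minute NREM session and run
# the full analysis chain on it.
synth:
  duration_s: 600
  rate_hz: 200
  n_channels: 2
  seed: 9
probe_channel: ch1
score_channel: ch1
score_sleep: false
protocol:
  initial_delay_ms: 330
  block_s: 120
  pause_s: 120
seed: 9
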