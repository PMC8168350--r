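# Health-monitor pipeline configuration: 8-muscle montage, 1 kHz input.
channels: [left_bicep, right_bicep, left_tricep, right_tricep,
           left_thigh, right_thigh, left_hamstring, right_hamstring]
delta:
  start: 1.0        # most sensitive admissible confidence
  lower: 1.0e-9
  upper: 1.0
  chunk_size: 2000  # training step every 2 s of stream
planner:
  min_drifts: 2     # >= 2 muscles must drift ...
  max_drifts: 8     # ... but all 8 at once is the cold-start signature
  window_ms: 1000   # tumbling 1 s decision windows
analyser:
  scale: auto       # per-channel scale frozen after calibration
  calibration_samples: 500
  target_sd: 0.25
sink: alerts.csv
synthetic:          # used by `driftwatch simulate`
  n_samples: 9637
  base_sigma: 50
  events:
    - at_ms: 5000
      channels: [5, 7]   # left thigh + left hamstring
      kind: variance_scale
      magnitude: 4
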