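# driftwatch

Streaming **concept-drift detection** for multi-channel physiological
recordings, organised as a MAPE-K multi-agent pipeline.

Muscle-activity monitoring with surface electromyography (EMG) produces
spiky, hard-to-model time series in which genuine physiological change
(fatigue, altered movement) appears as a change in the generating
distribution — concept drift. Single-channel drift detectors are noisy:
run alone they flood the operator with false positives. driftwatch is for
researchers and engineers building such monitors: it pairs a per-channel
adaptive-windowing detector with a cross-channel voting stage that
suppresses isolated false alarms, and wraps the whole thing in a
Monitor–Analyser–Planner–Executor agent runtime over a shared, append-only
Knowledge Base, so every stage is observable, replayable and testable.

## The method

**Per-channel detector (ADWIN).** Each channel keeps a variable-length
window of recent values, split every update into an older part `W0` and a
newer part `W1`; drift is flagged when

    |mean(W0) - mean(W1)| >= sqrt( ln(4n/δ) / (2m) ),   m = 1/(1/n0 + 1/n1)

with the confidence δ ∈ (0, 1] Bonferroni-shared over the n candidate
splits (higher δ = more sensitive). On a drift the stale older part is
discarded. Inputs are standardized per channel to a reference noise scale
before reaching the detector — the bound is calibrated for unit-range
data.

**Online confidence regulation.** δ starts at 1.0 and is stepped by
decades every 2 s of stream from the cumulative drift rate: rate rising →
δ/10, rate falling → δ×10, inside [1e-9, 1]; the comparison baseline
updates only when δ actually moves. Training runs asynchronously — never
inside the prediction path — and new δ values take effect at chunk
boundaries.

**Voting planner.** Per tumbling 1-second window, `n_drift` counts the
distinct muscles with at least one positive verdict; an alert fires iff
`2 <= n_drift < 8`. At least two muscles (one body side shares two muscles
per limb pair) must agree, and all eight drifting at once — the cold-start
signature — is ignored.

## Worked example

Generate a synthetic 8-muscle recording (9,637 rows, 1 ms each; integer
microvolts, heavy-tailed noise) with a 4x variance jump at 5,000 ms on the
left thigh and left hamstring, and run it through the pipeline:

```r
library(driftwatch)

cfg <- emg_config(
  n_samples = 9637, seed = 101,
  events = list(drift_event(5000, channels = c(5, 7),
                            kind = "variance_scale", magnitude = 4))
)
x <- emg_generate(cfg)
run <- run_pipeline(x, pipeline_config(), output = "alerts.csv")
```

```
<drift run>
  rows read:          9637
  predictions written: 77096
  raw drifts per channel:
    left_bicep           0  (final delta 1)
    right_bicep          0  (final delta 1)
    left_tricep          0  (final delta 1)
    right_tricep         2  (final delta 1)
    left_thigh          36  (final delta 1)
    right_thigh          0  (final delta 1)
    left_hamstring      45  (final delta 0.01)
    right_hamstring      0  (final delta 1)
  alerts fired:        3
    [5000, 6000) ms: 2 channel(s): left_hamstring;left_thigh
    [6000, 7000) ms: 2 channel(s): left_hamstring;left_thigh
    [8000, 9000) ms: 2 channel(s): left_hamstring;left_thigh
```

Reading the output: every one of the 9,637 rows was fanned out to the 8
per-muscle Analysers (77,096 persisted verdicts). The two jumped channels
produced 81 raw detections — and a couple of isolated false positives
appeared elsewhere — but the voting planner collapsed all of that into 3
alerts, every one at or after the 5,000 ms event, naming the two muscles
responsible. A recording where only *one* channel jumps produces zero
alerts: isolated detections never fire an alert. `tidy(run)` returns the
alerts tibble, `glance(run)` the one-row run summary, `autoplot(run)` the
detections-vs-alerts picture, and `alerts.csv` holds the delivered alerts.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/driftwatch simulate --seed 1 --out recording.csv
Rscript inst/cli/driftwatch run --input recording.csv \
    --config inst/extdata/health_monitor.yaml --out alerts.csv
```

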