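---
title: "Methods: adaptive-window drift detection with a voting MAPE-K pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive-window drift detection with a voting MAPE-K pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

driftwatch detects concept drift — changes over time in the distribution
generating a data stream — on multi-channel physiological recordings such as
surface electromyography (EMG). This vignette is the package's own account
of the method: the detector and its threshold, the online confidence
regulation, how the four-agent runtime splits the work, what the voting
planner does and why, what the synthetic generator does and does not
emulate, and where the design was genuinely open.

## The detector

Each channel is watched by an ADWIN (adaptive windowing) detector. The
detector keeps a variable-length window of the most recent values. On every
update it searches all splits of the window into an older part $W_0$ and a
newer part $W_1$ and flags a drift when

$$|\bar{W_0} - \bar{W_1}| \ \ge\ \epsilon(n_0, n_1) =
\sqrt{\tfrac{1}{2m}\,\ln\tfrac{4n}{\delta}},\qquad
m = \frac{1}{1/n_0 + 1/n_1},$$

a Hoeffding-style bound with the confidence $\delta \in (0,1]$ shared
(Bonferroni) across the $n$ candidate splits. Within this package, higher
$\delta$ means a *more sensitive* detector. On a drift, every element at or
before the qualifying split is discarded and the search repeats on the
remainder until no split qualifies, so the retained window contains only
the current regime.

Three numerical choices matter here:

* **Exact windows, exhaustive search.** Elements are stored explicitly and
  every split is scanned per update via prefix sums ($O(n)$ per update).
  The bucketed exponential-histogram approximation would be faster at very
  large windows, but exactness makes the implementation testable against a
  brute-force oracle, and per-channel physiological streams (thousands to
  tens of thousands of samples) never reach scales where it matters.
* **Oldest-split tie-break with iterated re-cutting.** When several splits
  qualify, the oldest (smallest index) is cut first and the search repeats.
  A single sweep converges on the same purge a change-point localisation
  would produce: after a level shift the retained window holds only
  post-shift elements, which the test suite asserts against the oracle.
* **One drift event per update.** However many truncations one incoming
  value causes, `drifts_detected` increments once; the drift rate is a
  per-sample event rate.

$\delta = 1$ is admitted (the formula stays finite because of the $4n$
factor) and is the configured start value: the most sensitive setting,
regularised downwards by the controller below.

### The threshold is calibrated for bounded, unit-range data

The bound above is exact Hoeffding reasoning for values with range 1
(standard deviation at most $1/2$). For data on that scale it is
conservative: at $\delta = 0.002$, streams with noise s.d. 0.5 produce
essentially no false alarms over thousands of samples. Fed raw
unit-variance data, however, the threshold sits at only $\approx 2.5$–$2.9$
standard deviations of the subwindow-mean difference — and a max-over-splits
statistic crosses such a threshold routinely, producing false alarms at a
high, scale-dependent rate. Microvolt-scale data (hundreds of µV) fire on
virtually every sample at *any* admissible $\delta$. This is a property of
the fixed-normalisation bound, not a bug; the consequence is a hard design
rule:

> **inputs must be standardized before they reach the detector.**

The pipeline's Analysers therefore standardize each channel to a reference
noise scale. The target is s.d. `target_sd = 0.25` — half the Hoeffding
reference of $1/2$, i.e. a 2x guard margin. The operating point was chosen
by a calibration experiment on the generator's heavy-tailed noise:
at target 0.25, stationary Laplace channels show about 0.2 false detections
per channel per $10^4$ samples while a 4x variance step (s.d. doubling)
yields dozens of detections within the first seconds; at target 0.2 the
variance step becomes unreliable to detect, at target 0.3 stationary false
alarms multiply several-fold. The per-channel scale estimate
$\hat\sigma$ is the sample s.d. of the first `calibration_samples = 500`
values (0.5 s at 1 kHz; relative error of a few percent) and is then
frozen — deliberately, so a later variance increase shows up as a drift
rather than being absorbed by recalibration. During calibration the
Analyser persists `predicted = FALSE` verdicts and feeds nothing to the
detector. This calibration period is an explicit warm-up in the Analyser;
the alternative — no warm-up, relying solely on confidence adaptation and
the planner's all-channels guard — cannot work here, because no admissible
$\delta$ quiets unstandardized microvolt data.

## Online confidence regulation

Each stream's $\delta$ is regulated from the observed drift rate — the
accumulated number of drift detections over the number of samples analysed
(cumulative over the stream's lifetime, starting at 0). Every training step
(one per `chunk_size = 2000` samples, i.e. every 2 s at 1 kHz) compares the
current rate with `last_rate`, the rate recorded at the last confidence
change:

* rate increased and a decade down stays above `lower` → $\delta \gets \delta/10$;
* rate decreased and a decade up stays below `upper` → $\delta \gets 10\delta$;
* otherwise nothing changes — and `last_rate` is updated **only when
  $\delta$ actually changes**, which stops small rate fluctuations from
  flapping the confidence (this also fixes the comparison semantics:
  "increasing" is relative to the last change, not the previous chunk).

Boundaries default to $[10^{-9}, 1]$: the upper bound is the start value;
the lower bound spans the useful sensitivity range of the threshold (each
decade adds only $\ln 10 / 2$ inside the square root, so $10^{-9}$ already
approaches the practical floor). Decade positions are tracked as integer
exponents so long call sequences cannot accumulate floating-point drift.

A known behaviour of the *cumulative* rate: after a burst of detections the
rate can only decay slowly, so $\delta$ tends to oscillate one decade
around its operating value rather than settling exactly. The voting stage
absorbs this.

## The four-agent runtime and the Knowledge Base

The MAPE-K split assigns one concern per agent type: **Monitors** capture
samples and forward them to subscribed **Analysers** — but only while an
Analyser is available; otherwise the sample is dropped and the drop logged
(no buffering — the transport is availability-gated). Subscriptions are
reciprocal: Monitors track Analyser availability. Analysers predict and
persist one record per sample to the **Knowledge Base**; **Planners** read
the Knowledge Base and decide; **Executors** deliver alerts to a sink,
holding them in order while the sink is down (back-pressure) and flushing
on recovery. The transport is an in-process bus with per-publisher FIFO
ordering; a distributed transport could implement the same interface, and
nothing else would change.

The Knowledge Base is an append-only table
`predictions(jid, data, datetime_monitored, datetime_analysed, identifier,
predicted)` plus an auto-increment surrogate key. Payloads are canonical
JSON (recursively sorted keys, no insignificant whitespace) so round trips
are byte-stable; timestamps carry millisecond precision, which 1 kHz data
and 1 s decision windows require. Two backends — an in-memory column store
and a single-file tab-delimited store — run the same test suite through the
same interface.

**Asynchronous training contract.** The prediction path never executes
training computation. Predictions only enqueue a retraining task once
`chunk_size` new samples have accumulated; `runtime_run_tasks()` executes
queued tasks between predictions, and the new $\delta$ becomes visible to
predictions exactly at chunk boundaries. An instrumentation counter
(`train_in_predict`) counts any training work that runs inside the
prediction path; every end-to-end run asserts it is zero. Retraining
derives the cumulative drift rate *from the Knowledge Base records* the
Analyser itself persisted (samples = records, drifts = positive verdicts)
rather than re-feeding raw values through the live detector — the verdicts
are the detector's own outputs, so the resulting $\delta$ trace is
identical to batch training on the raw stream, without double-feeding.

**Clocking.** The runtime stamps samples from a deterministic stream clock
(`origin + timestamp_ms`; analysis adds a fixed 1 ms latency; decisions are
stamped at window end). Wall-clock stamps would make replays
non-reproducible; with the stream clock, rerunning an input yields a
byte-identical alert CSV.

## The voting planner

Per-channel detections are deliberately over-sensitive; the planner is the
false-positive filter. Time is partitioned into tumbling windows of
`window_ms = 1000` keyed on *monitoring* time (so decisions are independent
of processing latency). Per window, `n_drift` counts **distinct channels**
with at least one positive verdict — repeated detections on one muscle
count once. An alert fires iff

$$\texttt{min\_drifts} \le n_{\text{drift}} < \texttt{max\_drifts},
\qquad \text{default } 2 \le n_{\text{drift}} < 8 .$$

The lower bound encodes the montage's anatomy — four muscle pairs, two per
body side, so a genuine unilateral problem affects at least two muscles —
and the upper bound ignores the situation where *all* channels drift at
once, the signature of a systemic cause (cold start, montage-wide
artefact) rather than a physiological event. Tumbling (non-overlapping)
windows give at most one alert per second. The truth table over all $2^8$
drifting-subset patterns is asserted exhaustively in the tests.

## The synthetic generator

The generator emulates exactly what the detection stack consumes: 8
channels at 1 sample/ms, zero-centred heavy-tailed noise per channel
(Laplace by default — heavy tails emulate the spikiness of EMG action
potentials while keeping moments finite), integer microvolt counts
(default s.d. 50 µV), and injectable events (variance multipliers, mean
shifts in sigma units) on chosen channels at chosen times, optionally
mirrored on the paired limb channel. Events transform the *same base
draws*, so channels not named in any event are bit-identical to an
event-free run with the same seed — which is what makes localisation
properties testable. One row per millisecond is the adopted reading of the
source data's sampling (a 9,637-row recording spanning 9,637 ms); the
generator's default recording length in the acceptance run mirrors that
scale.

What it does **not** emulate: motor-unit firing structure, spectral
content, inter-channel correlation, electrode artefacts, baseline wander.
Passing the end-to-end tests therefore demonstrates the *mechanism* —
per-channel detection, confidence adaptation, vote-based suppression — on
statistically controlled inputs, not clinical performance on real EMG.

## Problem sizes and test design

The suites are sized for a single CPU: oracle-equivalence runs 50 seeded
streams of length 400 against a scalar-loop brute-force oracle;
false-alarm and detection-delay properties use 50 seeds at stream length
5,000 and 600; the end-to-end acceptance runs the full 9,637-row recording
twice (two-channel jump, single-channel jump). The acceptance script
regenerates everything from its `--seed` and recomputes all reported
quantities from scratch in under a minute.

## Known limitations

* **Scale sensitivity.** The fixed-normalisation threshold presumes
  standardized inputs; the detector alone, fed raw unit-variance or
  larger-scale data, false-alarms at a rate that grows with the input
  scale. Standardization (or a variance-aware bound, out of scope here) is
  mandatory in any deployment.
* **Frozen calibration.** A slow genuine drift *during* the 500-sample
  calibration period would inflate $\hat\sigma$ and desensitise that
  channel.
* **Cumulative drift rate.** The regulation signal never forgets; after a
  long noisy epoch, $\delta$ reacts sluggishly to genuinely new
  conditions. Windowed rates would react faster but are a different
  algorithm.
* **Univariate detectors.** Each channel is watched independently;
  correlated multi-channel drifts are only combined at the voting stage,
  not modelled jointly.
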