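---
title: "Methods: minute-block stress detection from PPG and EDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minute-block stress detection from PPG and EDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresstrace)
```

## The problem and the model

Acute psychological stress raises heart rate (sympathetic activation plus
vagal withdrawal) and skin conductance (sudomotor activity). Both signals
are cheap to record from a wrist- or finger-worn sensor, but absolute
levels vary enormously between people: one person's resting heart rate is
another's stressed one. The pipeline therefore works on *within-person
changes*: each participant contributes a 5-minute seated baseline, and all
task features are deviations from that baseline.

The unit of analysis is the **minute block**: a non-overlapping 60-s
window yielding one feature vector
\((\Delta HR, \Delta EDA)\) — baseline-subtracted mean heart rate (bpm)
and mean skin conductance (μS). A linear decision function

\[ s(\mathbf{x}) = w_1\,\widehat{\Delta HR} + w_2\,\widehat{\Delta EDA} + b \]

on standardized features classifies a block as stress when \(s > 0\).
Ground truth comes from the session protocol: baseline blocks are
non-stress; public-speech (TSST-S) blocks are stress and are what the
model trains against; mental-arithmetic (TSST-A) blocks are also stress
but reserved for evaluation; anticipation (TSST-P) blocks carry no label
at all and are excluded everywhere.

Assumptions worth making explicit: stress is treated as constant within a
phase (block-level, not event-level, detection); one baseline per session
suffices to anchor a participant; and the two mean features carry the
signal — no heart-rate variability, tonic/phasic EDA decomposition, or
respiration features are used.

## Signal processing choices

**Resampling.** Acquisition systems record at up to 1000 Hz; analysis runs
at 64 Hz (PPG) and 4 Hz (EDA). 64/1000 reduces to 8/125, a non-integer
ratio, so the package implements rational polyphase resampling: conceptual
upsampling by \(L\), a Kaiser-windowed (\(\beta = 5\)) sinc low-pass at
the narrower Nyquist frequency with \(20\max(L,M)+1\) taps, decimation by
\(M\). Two numerical choices matter. Edges are *replicated* rather than
zero-padded, and each polyphase branch is normalized to sum exactly
\(1/L\), so a constant trace is reproduced exactly — a property the
baseline-normalization identity tests rely on. The rate ratio is
approximated by continued fractions to a relative 1e-9 (exact for all
integer-rate conversions used here).

**Beat detection.** The detector marks the pulse upstroke on the first
derivative (central differences). The threshold is adaptive: half the 90th
percentile of positive derivative values in a rolling 10-s window. The
rolling percentile is evaluated on a 1-s grid and linearly interpolated —
a deliberate trade of formality for speed; at these window lengths the
threshold varies slowly and the approximation is far below the decision
margin on clean signals. Windows with no positive derivative inherit the
maximum finite threshold (an all-flat trace returns an empty beat series
before thresholding). A 0.25 s refractory period suppresses double
detections; that caps detectable rates at 240 bpm, above the 180 bpm
validity bound, so it costs nothing.

**Validity filtering.** An inter-beat interval is valid iff
\(40 \le 60/\text{IBI} \le 180\) bpm: the stated exclusions are strict
("below 40", "above 180"), so exact-boundary intervals are *kept*. Invalid
intervals are flagged, not removed: the beat after an excluded interval
still anchors the next interval. A minute block needs at least 40 valid
IBIs or its heart rate is discarded; the EDA mean of such a block is still
computed for diagnostics, but a feature vector requires both channels, so
the block contributes nothing to classification.

**Windowing conventions.** All intervals are half-open \([t_0, t_1)\) in
seconds from session start, which makes the 1-minute windows partition a
5-minute phase into exactly 5 blocks; trailing partial windows are
dropped. An IBI belongs to the minute containing its *onset*.

## The classifier

The loss is unregularized-intercept hinge with L2 weight decay
(`l2 = 1e-4`), minimized by per-sample SGD with the learning-rate schedule
\(\eta_t = 1/(\lambda(t_0 + t))\), \(t_0\) set from the typical weight
norm \(1/\lambda^{1/4}\); logistic loss is available as an option. A
linear SGD classifier needs comparable feature scales — bpm and μS are
not — so features are standardized with center/scale learned from the
training data and stored in the model; predictions are thereby invariant
to positive rescaling of either raw feature column (a tested property).
Data are reshuffled every epoch from the caller's seed, making training
bit-reproducible within a build.

Splitting (75:25) and cross-validation folds (5) are stratified/assigned
at minute-block level. Block-level splitting leaks participants across
folds — blocks from one person appear on both sides — which is the
faithful default here but inflates accuracy relative to subject-level
splits; the labeled-sample tables keep `participant_id`, so callers can
group by subject if they want the honest-generalization variant.

A score of exactly 0 classifies as non-stress: conservative alerting. The
bias term is the exposed tuning knob — `adjust_bias()` shifts the decision
boundary, and sweeping it moves hit rate and false-alarm rate together,
monotonically, from (0, 0) to (1, 1).

## Evaluation

Block-level signal detection: hits (stress classified stress), misses,
false alarms, correct rejections; accuracy \((H+CR)/N\), hit rate
\(H/(H+M)\), false-alarm rate \(FA/(FA+CR)\). A rate with an empty
denominator is reported as undefined (`NA`), never as 0 — silently
optimistic metrics are worse than missing ones. Evaluation pools blocks
across participants; a per-participant breakdown is attached to every
report.

## What the simulator emulates — and what it does not

The generator stands in for recordings that were never deposited, so its
parameters are *stated conditions*, not estimates of any study sample. Per
participant it draws a baseline heart rate (70 ± 8 bpm between subjects),
a stress response (+15 ± 5 bpm), a tonic skin conductance (4.0 ± 1.5 μS),
and a tonic stress response (+2.0 ± 0.7 μS). Stress phases (TSST-S,
TSST-A) receive the full response; the anticipation phase receives half of
it (`anticipation_fraction = 0.5`) on both channels, producing the
intermediate, unlabeled blocks a robustness check wants. PPG beats follow
the per-minute programmed rate with 4 % multiplicative IBI jitter,
rendered as a stereotyped pulse (0.12 s raised-cosine upstroke, 0.25 s
exponential decay); ground-truth beat times mark the upstroke midpoint,
which is the point a derivative detector locates. EDA is a
piecewise-linear tonic level plus skin conductance responses at Poisson
times (2/min at rest, 6/min under stress) with biexponential shape
(\(\tau_{rise} = 0.75\) s, \(\tau_{decay} = 4\) s), exponentially
distributed peak amplitudes (mean 0.3 μS — the configuration fixes only
the mean, and an exponential is the standard minimal-assumption choice for
positive event amplitudes), 0.02 μS Gaussian sensor noise, clipped at 0.

Not emulated: motion artifacts (available via an optional injector,
default off), sensor detachment, respiration and circadian modulation,
heart-rate variability structure beyond white jitter, EDA drift. A green
pipeline test on this generator establishes that the *machinery* —
resampling, detection, filtering, normalization, training, accounting — is
correct and deterministic, and that the advertised effect sizes are
recoverable; it says nothing about classifier performance on real,
artifact-laden wearable data. Conversely, the zero-effect configuration
(all deltas and the SCR-rate difference set to 0) verifies there is no
information leak: held-out accuracy is statistically indistinguishable
from chance.

## Degenerate inputs and error policy

Non-finite samples on ingestion, overlapping schedule intervals, unknown
phase labels, single-class training sets, zero-variance features, and
empty traces are all hard errors with located messages (row numbers,
participant ids) — bad data is loud, never imputed. Participants without a
single valid baseline block are excluded (skipped with a logged reason by
the pipeline driver, which flags partial failure in its exit status), and
phases shorter than one minute yield an empty block list rather than an
error.

## Known limitations

The detector is tuned for clean or mildly noisy PPG; heavy motion
contamination will produce spurious upstrokes faster than the validity
filter can discard them. Block-level splitting overstates accuracy
relative to subject-level generalization (see above). The simulator's
separability at default effect sizes means headline accuracies near 1.0
on synthetic cohorts should be read as machinery checks, not performance
claims. Threshold tuning via the bias is global; per-user adaptive
thresholds are out of scope.
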