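---
title: "Behavior-classified step counting: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavior-classified step counting: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheepstep)
```

## The problem

A pedometer on a sheep's leg sees a roughly periodic combined-acceleration
waveform while the animal walks: at 32 Hz a normal walking step spans about
`L = 29` samples, and counting peaks above a threshold counts steps well.
Two behaviors break this:

* **Running.** The stride rate exceeds the sampling budget: the waveform
  stays elevated (valleys above 20 m/s²), the fall-back between steps is
  incomplete, and peak detection misses steps.
* **Leg shaking.** Scratching while standing or lying produces peaks of
  walking-like height at a fast rate. Every one of them is a false step.

Fast (brisk) walking complicates the second case: in the acceleration
channel it looks like leg shaking (moderate peaks, small peak-valley gap),
but its steps are real. The two are separated in the gyroscope: shaking
swings the leg about the joint and drives the x-axis angular velocity,
brisk walking does not.

`sheepstep` implements the resulting pipeline: orientation-free combined
acceleration, zero-phase low-pass filtering, two-sided window peak/valley
detection, threshold-rule behavior windows, a gyro-variance discriminator,
and per-behavior aggregation

\[
\text{total} = \text{peaks} - \text{running-window peaks} + R - \text{leg-shake peaks},
\qquad R = \operatorname{round}(W \cdot K / L).
\]

## Signal conditioning

Combined acceleration is the per-sample Euclidean norm of the three axes.
The pipeline then filters the *magnitude* (not the raw axes): the
magnitude is what the detection thresholds were calibrated on, and
filtering axes first gives a slightly different magnitude (the option
exists as `prepare_magnitude(filter_axes = TRUE)`).

The filter is a second-order Butterworth low-pass at 5 Hz, applied
forward-backward. The choices, in order of importance:

* **Zero phase.** Window sizes (`W`, `L = 29`) are sample-index
  arithmetic on peak positions; a causal filter would shift every peak by
  its group delay and bias `W`.
* **Cutoff 5 Hz.** Walking cadence is ~1.1 Hz (32/29), running ~2.3 Hz,
  and the leg-shake oscillation sits near 3–4 Hz; 5 Hz passes all
  behavior content and removes sensor noise. Both cutoff and order are
  `threshold_config()` fields.
* **Edge handling.** The mean is removed and the ends are extended by odd
  reflection before filtering, so a constant (gravity-only) trace passes
  through bit-exactly and edge transients do not fabricate peaks near the
  boundaries.

Traces with timestamp gaps longer than `2/fs` are split and each segment
is processed independently; windows never span a recording gap.

## Peak and valley windows

Index \(i\) is a peak iff the signal strictly increases over its \(n\)
left neighbors, strictly decreases over its \(n\) right neighbors, and
exceeds `thr` (12 m/s²). Strictness is deliberate: plateaus (equal
neighbors) yield no peak, and indices within \(n\) of either boundary are
excluded rather than padded, because the definition requires \(n\) real
neighbors per side. The calibrated half-widths are \(n = 4\) for peaks
and \(n = 2\) for valleys (troughs are narrower than crests in this
gait). Larger \(n\) discards genuine steps, smaller \(n\) admits
pseudo-peaks.

Behavior-window detection runs on the *unthresholded* extrema stream:
the windows close on low peaks (below 20 or 12 m/s²) which would not
exist if the amplitude threshold had already been applied. The step
threshold only decides which peaks count as walking steps.

Downstream rules compare `peak[k]` with `valley[k]`, so extrema are
paired: each peak takes the nearest detected valley that follows it and
precedes the next peak; when none exists, the minimum sample between the
two peaks stands in. The pairing is isolated in `pair_extrema()` so the
rule can be swapped.

## Behavior windows

Both window types share one scanner. A running window opens at a peak
above `thr1 = 30` and a leg-shake candidate at a peak above
`thr5 = 12`. A window closes at the first subsequent peak below the
closing threshold (`thr2 = 20` running, `thr3 = 12` leg shake) *or* at
the first filtered sample below `thr3`, whichever comes first
(`close_on = "sample"`, the default). The sample clause matters in
practice: a quiet stretch after the behavior may contain no structural
peak at all for a hundred samples, and a window that cannot close leaks
into the next behavior and corrupts both its label and `W`. The
peak-only variant (`close_on = "peak"`) is retained as an option.

The qualifying rule is the peak-valley difference
\(acc_p - acc_v < acc_p - thr\), which reduces algebraically to
\(acc_v > thr\) (`thr4 = 20` running, `thr7 = 12` leg shake); the
package implements the reduced form and the tests verify both forms
agree. The rule quantifies over the valleys *between consecutive
interior peaks*: the final drop toward the closing peak is the
termination of the behavior, not part of it, and including it would
disqualify every window. By default all pairs must qualify
(`pair_rule = "all"`); `"any"` is available.

Two further design decisions:

* **Minimum of two interior peaks for leg-shake candidates.** With a
  single peak there are no adjacent peak-valley pairs, the pair rule
  would hold vacuously, and every isolated walking step would become a
  candidate. Leg shaking is an oscillation; one peak is a step.
* **Precedence.** Running is detected first and candidates overlapping a
  running window are discarded. The regional peak restriction
  (`thr8 = 39`: every candidate peak must stay below it) separates the
  two in amplitude, but peaks in the 30–39 band satisfy both rule sets
  and need the tie-break.

## The gyro-variance discriminator

A candidate window is leg shaking iff the variance of `gyro_x` over the
window strictly exceeds `var_cut = 10`; a window variance of exactly 10
is fast walking. Variance is population variance (divisor \(N\)) by
default — the cut carries no stated convention, and for the ~200-sample
windows involved the two divisors differ by well under the separation
between the classes; `var_type = "sample"` switches it.

`extract_features()` computes the mean/var/std/kurtosis/skewness feature
set whose 3-cluster structure (standing shake, lying shake, brisk walk)
motivated choosing variance as the discriminator, and
`cluster_behaviors()` runs k-means over it (Lloyd, 10 restarts, seeded).
This is exploratory tooling, not part of the runtime pipeline. Kurtosis
is reported as excess kurtosis; a constant window gets skew = kurt = 0
with a warning rather than NaN.

## Step accounting

`running_steps()` rounds \(W K / L\) half-away-from-zero; the
calibration table that fixed \(K\) reports integer prediction errors, so
predictions are integers, and `round_mode = "floor"` covers the
truncating reading. The "leg-shaking steps" subtracted by the aggregation
identity are the above-threshold peaks inside leg-shake windows — the
window's own step count in the peak-counting sense. Fast-walk windows
subtract nothing: their peaks are real steps. The identity is asserted
inside `aggregate_steps()` on every run.

`sweep_K()` reproduces the calibration: signed errors
\(\operatorname{round}(W K/L) - \text{true}\) per candidate \(K\),
summarised by MSE/RMSE/MAE. The summary divisor is \(n-1\), not \(n\):
the bundled calibration table's printed summaries (e.g. MAE 1.14 from
eight errors with \(\sum |e| = 8\), i.e. \(8/7\)) force that convention,
which the package keeps for fidelity with a `divisor = "n"` switch.
Similarly, `error_table()` rounds per-trial relative errors to 2 decimals
(half-up) *before* averaging, because the bundled validation means are
averages of the rounded rows; `round_digits = NULL` gives full precision.

## The synthetic generator

`generate_trace()` exists so every rule is testable with known ground
truth. Segment defaults encode the regimes the thresholds define, at
32 Hz with gravity baseline 9.8 m/s²:

| behavior | waveform | peaks (m/s²) | valleys | gyro-x sd |
|---|---|---|---|---|
| walk | one raised-cosine pulse / 29 samples | 14–18 | 9.8 baseline | 0.5 |
| run | oscillation, 2.1 cycles / 29 samples | 31–36 | 21–25 | 2 |
| leg_shake | oscillation, 1 cycle / 10 samples | 16–20 | 13–15.5 | √30 |
| fast_walk | same as leg_shake | 16–20 | 13–15.5 | √2 |
| stationary | baseline only | — | — | 0.1 |

Amplitudes are drawn per cycle from those ranges; i.i.d. Gaussian noise
(sd 0.2 m/s²) is added per axis before combination; the magnitude profile
rides on the z axis and only gyro-x carries behavior signal. Infeasible
specs (a run that cannot cross 30, a shake valley below 12) fail at
construction. The gyro sds put the window variance near 30 and 2 — well
clear of the cut of 10 on both sides, which is what "default variance
separation" means in the tests.

What the generator does *not* emulate: orientation drift, gravity
redistribution across axes during leg swing, irregular cadence, grazing
head-bob crosstalk, sensor saturation, or temperature bias. Passing the
recovery tests therefore shows the algorithm implements its rules
correctly on in-regime waveforms, not that the thresholds generalise to
any particular flock.

## Problem sizes and numerical notes

The test suite checks the window detector against a brute-force
inequality oracle on 1,000 random-walk signals (lengths 32–512), and
end-to-end recovery on 20 seeded mixed traces of ~67 s each (total
error ≤ 10% mean; walk-only traces must be exact). The acceptance script
uses the same sizes. Ties and degenerate cases are pinned by tests:
plateau peaks (none), variance exactly at the cut (fast walk), `W = 0`
(zero steps), constant feature windows (zero skew/kurt with warning),
empty extrema (no windows), truncated windows at end-of-trace (flagged).

Known limitations: thresholds are animal- and mount-specific and will
need recalibration for other species or sensor positions; the method is
offline (whole-trace) rather than streaming; windows that genuinely
overlap in behavior (a sheep that shakes mid-run) resolve to running by
precedence; and the `n-1` summary divisor and rounded-row averaging are
reporting conventions of the original field validation, kept for
comparability rather than statistical orthodoxy.
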