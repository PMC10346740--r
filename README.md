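# sheepstep

Step counting for grazing sheep from leg-worn six-axis inertial sensors,
with behavior classification to remove the two error sources that break
plain pedometry in the field: **running** (several steps per second at a
32 Hz sampling rate, so peak counting under-counts) and **leg shaking**
(scratching while standing or lying, which produces step-like peaks that
should not be counted at all). Fast (brisk) walking mimics leg shaking in
the acceleration channel and is recovered via the x-axis gyroscope.

The package is for researchers in livestock activity monitoring who have
time-stamped 32 Hz accelerometer + gyroscope traces (or want to prototype
against synthetic ones) and need per-behavior step counts with an audit
trail.

## Method

For a trace with per-axis accelerations `acc_x, acc_y, acc_z` (m/s²):

1. **Combined acceleration** `acc = sqrt(acc_x² + acc_y² + acc_z²)`
   removes device-orientation dependence; a zero-phase Butterworth
   low-pass (default 5 Hz, order 2) removes sensor noise without lagging
   peak positions.
2. **Window peak/valley detection**: index `i` is a peak iff the signal
   rises strictly over its `n = 4` left neighbors and falls strictly over
   its `n = 4` right neighbors (valleys mirror this with `n = 2`). A peak
   above `thr = 12` m/s² counts as one walking step.
3. **Running windows**: open at a peak above `thr1 = 30`, close when the
   signal falls back below strolling level (peak < `thr2 = 20` or sample
   < `thr3 = 12`); the window is running when every interior valley stays
   above `thr4 = 20`. Steps inside are re-estimated from the window
   length `W` (samples) as `R = round(W·K/L)` with `L = 29` samples per
   baseline step and calibrated scale factor `K = 2.1`.
4. **Leg-shake windows**: same construction with gentler thresholds
   (`thr5 = thr7 = 12`) plus a regional peak restriction (every peak
   < `thr8 = 39`). A candidate is leg shaking when the x-gyro variance
   over the window exceeds 10, otherwise fast walking.
5. **Aggregation**:
   `total = peaks − running-window peaks + running steps − leg-shake peaks`.

Every constant lives in `threshold_config()`; nothing is hard-coded.

## Worked example

Generate a labeled synthetic trace mixing all five behaviors and count it:

```r
library(sheepstep)
specs <- list(segment_spec("walk", 20), segment_spec("stationary", 3),
              segment_spec("run", 8), segment_spec("stationary", 3),
              segment_spec("leg_shake", 6), segment_spec("stationary", 3),
              segment_spec("fast_walk", 6), segment_spec("stationary", 3),
              segment_spec("walk", 15))
g <- generate_trace(specs, seed = 7)
g$truth$total_steps
#> [1] 76
count_steps(g$series)
#> <step_report>
#>   total steps:        76
#>   walking peaks:      58 (of 94 peaks above thr)
#>   running:            1 window(s), 18 peaks replaced by 18 steps
#>   leg shake:          1 window(s), 18 peaks removed
#>   fast walk:          1 window(s), peaks kept as steps
```

The raw peak count (94) would over-count: 18 of those peaks are leg
shaking, and the 18 running-window peaks are replaced by the
window-length estimate. The corrected total matches the ground truth.

The evaluation metrics run on the bundled field-trial counts:

```r
df <- field_step_counts()
tab <- error_table(df$true, peak = df$pred_peak, behavior = df$pred_behavior)
mean_relative_error(tab)
#>   peak behavior
#> 17.556    6.244
```

i.e. classifying behaviors cuts the mean relative step error from 17.556%
(plain peak detection) to 6.244% on these trials.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli/sheepstep.R", package="sheepstep"))') \
    count --input trace.csv --out report.json
```

Subcommands: `count`, `simulate`, `eval`, `sweep-k`. Input CSV columns:
`time, acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z` (time as float seconds
or `yyyy/m/d h:m:s.ms`). Exit codes: 0 ok, 2 usage, 1 runtime error.

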