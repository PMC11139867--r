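---
title: "Tip kinematics and the 1/f fluctuation index: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tip kinematics and the 1/f fluctuation index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctkin)
```

## The problem

Laparoscopic skill is usually rated by experts watching video — slow,
subjective, and unavailable during surgery. An alternative is to track the
instrument tip's pixel coordinates frame by frame (e.g. with a
segmentation network) and compute objective motion indices. This package
implements the analysis side of that idea: from a per-frame tip coordinate
file to kinematic indices, a spectral "fluctuation" skill index, and
cohort-level discrimination statistics. It does not train or run any
detector; the input contract is simply one row per video frame with
coordinates and a visibility flag.

## The trajectory model

A `tip_trajectory` has one sample per frame at a fixed frame rate
(default 30 fps), image-convention coordinates (origin top-left, y
downward, pixels), and a visibility flag. In real gastrectomy footage the
tip is off screen or undetected in roughly 40–50% of frames, in episodes
(instrument exchanges, mist, occlusion) rather than isolated frames. All
analyses therefore split the video into *maximal visible runs* and never
bridge a gap: interpolating across an exchange would synthesize a huge
fictitious displacement.

## Kinematic indices

For each visible run, the per-transition Euclidean displacement
("step length", px/frame) starts a scalar finite-difference chain:

* speed = step length × fps (px/s),
* acceleration = Δspeed × fps (px/s²),
* jerk = Δacceleration × fps (px/s³).

The chain is scalar (magnitude first, then differences) rather than
vector-valued: per-video results are reported as single scalars in
px/s, px/s², px/s³, and a scalar chain is the simplest construction that
produces them. No smoothing is applied before differencing. Per-video
means pool all defined elements across runs (runs weighted by length);
for acceleration and jerk the *magnitudes* are averaged, since the signed
differences average to ≈ 0 by construction.

`distance_per_second()` sums step lengths in non-overlapping one-second
bins (exactly `fps` transitions), binned within runs from the run start.
Trailing partial seconds are discarded: a partial bin necessarily has a
small sum and would inflate precisely the "hovering" region of the
distribution. The `hovering_ratio()` compares time below 120 px/s
(dwell/hesitation) to time in the closed working band [120, 400] px/s;
seconds above 400 belong to neither count. Both thresholds assume the
recording resolution; they are arguments, not constants, because an HD
recording may be 1280×720 or 1920×1080.

The distance-per-second distribution is displayed with `kde_curve()`: an
exact Gaussian-kernel density (Scott's-rule bandwidth, `stats::bw.nrd`)
evaluated on an explicit grid. Each cohort's curve integrates to 1, so
groups with very different total surgical time remain comparable. The
default grid is `[0, 1.2·max]` for nonnegative data, widened by 3
bandwidths wherever needed so the numerical integral stays within 1%
of 1.

## The fluctuation index β

The headline index treats the step-length series as a stochastic signal
with power spectral density S(f) ∝ 1/f^β. β = 0 is white noise
(disorderly movement), β = 1 the classical 1/f regime seen across
biological processes, and values approaching 2 indicate regular, smooth
movement; in cohort data experts score higher than novices.

The estimator is a Welch-style realization:

1. within each visible run, cut the step series into non-overlapping
   3-second windows (90 samples at 30 fps); trailing remainders dropped,
   windows never spanning a gap;
2. per window: subtract the mean, FFT, raw periodogram
   `|X_k|²/N` at frequencies `k·fps/N`, k = 1..N/2 (DC excluded,
   0.33–15 Hz at the defaults);
3. average the periodograms across windows;
4. fit ordinary least squares of log₁₀ power on log₁₀ frequency over all
   positive-power bins; β is minus the slope, with intercept and R²
   reported.

Design choices, where the procedure was genuinely open:

* **Average spectra, then fit once** (rather than fitting each window
  and averaging slopes): per-window log-periodograms are heavily skewed,
  so slope-averaging is noisier and biased; averaging power first is the
  standard Welch variance reduction.
* **Rectangular window, no taper, no bin truncation**: the simplest
  defensible convention; nothing in the 3-s-window + FFT + least-squares
  recipe calls for more.
* **Log base 10** on both axes (the slope is base-invariant).
* Zero-power bins (possible only in degenerate windows) are excluded and
  counted in the result; fewer than 3 usable bins is an error, as is a
  video without a single complete window.

### Known estimator bias near β = 2

With 3-s windows, per-window mean removal acts as a crude high-pass
filter: for very smooth series (β → 2) the lowest retained bins lose
power and the fitted slope is systematically shallow by ≈ 0.14 at β = 2
(stable across seeds; negligible for β ≤ 1.5). We do not correct it —
no taper or band truncation belongs to the stated method — but recovery
claims below account for it.

## The synthetic generator

No surgical videos ship with the package, so `synth_trajectory()`
emulates the statistical structure the analysis assumes:

* **Spectral content**: `colored_noise()` synthesizes Gaussian 1/f^β
  noise in the frequency domain (amplitudes ∝ f^(−β/2), uniform random
  phases, conjugate-symmetric spectrum, inverse FFT, standardized).
  Steps are `mean_step + sd_step · noise`, clipped at 0; the default
  mean/sd of 12/3 px keeps clipping below 10⁻⁴ and matches reported mean
  tip speeds (~350–374 px/s at 30 fps).
* **Hover episodes**: a fraction of whole seconds (default 10%) is
  rescaled so each sums below 120 px. This produces realistic dwell in
  the distance-per-second distribution, but it is amplitude modulation
  and therefore *deliberately* distorts the spectrum (block-wise
  modulation injects low-frequency power, inflating β̂ by roughly +0.2
  at the defaults). Estimator-validation work must generate with
  `hover_fraction = 0`; the hover machinery exists to exercise the
  kinematic indices, and in cohort comparisons its bias is common to
  both groups.
* **Visibility gaps**: invisible episodes with geometric lengths (10-s
  mean burst) covering `gap_fraction` (default 0.45) of frames — bursty
  like real off-screen episodes, exercising the run-splitting logic.
* **Geometry**: positions integrate the step series along a smoothly
  drifting random heading; at a frame edge the heading component is
  reflected, so every position is in frame while consecutive-position
  distances reproduce the step series *exactly* — the kinematics of a
  synthetic video are fully controlled.
* **Cohorts**: per-video β drawn from group-specific normals truncated
  to [0, 2]; defaults 1.45 (expert) vs 1.29 (novice) with within-group
  SD 0.08 and 9 videos/group. The SD is a fixture choice: published
  group data give means only, plus the fact that 7 of 9 videos per group
  fall on the correct side of the 1.4 cutoff — SD 0.08 reproduces that
  regime.

Everything is driven by explicit seeds; identical config ⇒ identical
output, and the generators restore the caller's RNG state.

What the generator does **not** emulate: camera motion and zoom, depth
(all distances are screen pixels), detector noise in the coordinates,
correlation between visibility and movement phase, and duration
differences between skill groups (all videos of a cohort share the
template duration — which is why the frames-vs-β Spearman block of a
report degenerates to `NULL` on purely synthetic cohorts). Passing tests
therefore validate the *pipeline's* arithmetic and the estimator's
statistical behavior, not the clinical claim.

## Cohort statistics

`mann_whitney_u()` is two-sided, exact when `n1·n2 ≤ 400` and tie-free,
otherwise the tie-corrected normal approximation with continuity
correction. `spearman_rho()` is rank-Pearson with the t-approximation
p-value. `roc_analysis()` fixes the conventions the published cutoff
needs to be reproducible from any per-video table: higher index ⇒
expert; candidate cutoffs are the observed values only (no midpoints);
classification is `value ≥ cutoff`; the cutoff maximizes Youden's J with
ties broken toward the smallest qualifying value; AUC by trapezoid.
`power_simulation()` draws normal parents (the Cohen's-d convention of
standard power software) and applies the same Mann-Whitney test; at
d = 1.46, n = 9/group, α = 0.05 the Monte-Carlo power of the exact test
is ≈ 0.77–0.78, a touch below analytic ARE-based approximations (~0.81),
as expected from the exact test's discreteness at n = 9.

## Validation scale

The test suite validates at desk scale, chosen so the full suite runs in
a few minutes: β recovery uses 20 seeded 300-s videos per target
β ∈ {0, 0.5, 1, 1.45, 2} (mean |β̂ − β| ≤ 0.15, strict monotonicity);
the end-to-end discrimination harness uses 100 seeded cohorts of 18
120-s videos (AUC > 0.5 in ≥ 95% of seeds); power uses 10,000
replicates. A 120-s video at the default gap structure yields ~20
spectral windows — enough that measurement noise in β̂ (SD ≈ 0.1) does
not swamp a 0.16 group separation.

## Limitations

Pixel units are not calibrated to millimeters; camera motion is
confounded with tip motion; thresholds (120/400 px/s, the 1.4 cutoff)
are resolution- and task-specific; and the fluctuation index summarizes
only the step-length magnitude series — direction changes enter only
through speed. These mirror the limitations acknowledged for the
original cohort analysis and are out of scope here.
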