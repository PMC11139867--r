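# fluctkin

Objective surgical-skill indices from instrument-tip coordinate time
series.

AI-based detectors can output the pixel coordinates of a laparoscopic
instrument tip for every video frame. `fluctkin` turns such per-frame
coordinate files into skill metrics for surgeons and surgical-education
researchers:

- **Kinematic indices** per video: total travel distance, velocity /
  acceleration / jerk (scalar finite-difference chain at the frame
  rate), tip occurrence rate, the distance-per-second distribution with
  its kernel-density curve, and the *hovering ratio* — time below
  120 px/s over time in the 120–400 px/s working band, a proxy for
  indecisive dwell.
- **The fluctuation index β**: the step-length series is treated as a
  signal with power spectral density S(f) ∝ 1/f^β. β is estimated by
  cutting each visible run into 3-s windows, averaging mean-removed FFT
  periodograms (Welch), and fitting log₁₀ S(f) = −β·log₁₀ f + c by
  least squares. β = 0 is white noise (disorderly motion), β = 1 the
  classical 1/f regime, values toward 2 regular, smooth movement —
  experts score higher than novices, and unlike operation time β can be
  computed in real time from the last few seconds.
- **Detector accuracy metrics** on binary masks: pixel TPR / FPR / Dice
  and the tip-hit rule, plus the 11-part evaluation-frame sampler.
- **Cohort statistics**: two-sided Mann-Whitney U per index, Spearman
  correlation of operating time vs β, ROC with the Youden-index cutoff
  (observed-value thresholds, `value ≥ cutoff ⇒ expert`), and
  Monte-Carlo power of the Mann-Whitney design.
- **A seeded synthetic generator** (`synth_trajectory()`,
  `synth_cohort()`): 1/f^β colored-noise step series integrated along
  smooth random headings, with hover episodes and bursty visibility
  gaps, so the full pipeline is testable without any video data.

The input format is plain CSV, one row per frame: `frame,x,y,visible`
(pixels, image convention, `x`/`y` blank when the tip is off screen);
frame rate and frame size are metadata arguments.

## Worked example

Simulate an 18-video cohort (9 expert, 9 novice; group β means
1.45 / 1.29, within-group SD 0.08; 120-s videos), analyze it, and
compare the groups:

```r
library(fluctkin)

cfg <- cohort_config(n_per_group = 9,
                     template = trajectory_config(duration_s = 120),
                     seed = 7)
manifest <- run_simulate(cfg, "cohort/")
metrics  <- run_analyze(manifest$file)
run_compare(metrics, manifest,
            power = list(effect_size_d = 1.46, n_per_group = 9,
                         reps = 10000, seed = 7))
#> <cohort_report> expert n=9, novice n=9
#>   total_travel_distance  expert  26820.391  novice  24712.084   p = 0.6665
#>   occurrence_rate        expert      0.681  novice      0.594   p = 0.6665
#>   mean_speed             expert    329.661  novice    331.550   p = 0.6048
#>   mean_acceleration      expert    565.602  novice    657.472   p = 0.005636
#>   mean_jerk              expert  25859.255  novice  30148.245   p = 0.002756
#>   hover_ratio            expert      0.081  novice      0.039   p = 0.09255
#>   beta                   expert      1.665  novice      1.563   p = 0.01061
#>   ROC on beta: AUC 0.852, cutoff 1.605 (sens 88.9%, spec 77.8%)
#>   Power: 0.779 (d = 1.46, n = 9, alpha = 0.05)
```

Reading the report: the expert group's estimated β is higher (more
regular movement) and the ROC on β̂ separates the groups well above
chance; speed and travel distance do not differ here because both groups
share the same generator kinematics apart from β. The absolute β̂ values
sit ~0.1–0.2 above the generator targets: hover episodes are amplitude
modulation and inflate the spectral slope — a deliberate property of the
simulator, common to both groups (see the vignette,
`vignettes/fluctuation-skill-analysis.Rmd`, for why and for every other
numerical convention).

Single-video use:

```r
traj <- read_trajectory("video01.csv", fps = 30,
                        frame_width = 1280, frame_height = 720)
summarize_kinematics(traj)
beta_for_trajectory(traj)
```

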