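# thermoknee

Tools for studying knee skin-temperature dynamics during repeated
sit-to-stand exercise, for researchers combining infrared thermography
with a four-load-cell balance board.

During a 10-minute paced sit-to-stand protocol the skin over the medial
collateral ligament region (superior-medial zone, SM) warms while the
patella (P) and patellar tendon (PT) cool. `thermoknee` implements the
two ways of extracting those trends from a 20 Hz thermal video and the
statistics that compare them:

* **semi-automatic extraction** — operator-style rectangular ROIs,
  repositioned per frame, yielding the ROI maximum and minimum
  temperature on one thermogram every 30 s (20 frames over 10 min);
* **automatic extraction** — sampling the thermal frames at tracked
  keypoint coordinates (DeepLabCut-style CSV input) at 1 Hz, with a
  likelihood p-cut of 0.5 and a configurable pixel neighbourhood;
* **balance-board processing** — total weight, sit/stand/transition
  segmentation, per-leg and fore/rearfoot load shares, centre of
  pressure `x = (span_x/2)·((TR+BR)−(TL+BL))/total` (and likewise for
  y), and a weight-asymmetry flag (one leg's mean standing share > 52%);
* **method agreement** — linear interpolation of the dense automatic
  series onto the sparse semi-automatic grid, OLS regression with
  R² = 1 − SSres/SStot, RMSE about each profile's own linear trend,
  Bland–Altman bias and limits of agreement (bias ± 1.96 sd), and
  AG / NAG / PAG labels for whether each method ties the heavier-loaded
  leg to the most thermally responsive leg;
* **robust lowess smoothing** (2% span, tricube weights, bisquare
  reweighting) for outlier-spike suppression in temperature profiles;
* a **synthetic-cohort generator** producing thermal video, keypoint
  tracks and load-cell records with known ground truth (zone trends,
  load shares, cycle count), so the whole pipeline is testable without
  the human dataset.

See `vignettes/thermoknee-methods.Rmd` for the full model description
and design rationale.

## Worked example

One synthetic participant with a 53% left-leg load share, analysed end
to end:

```r
library(thermoknee)

cfg  <- synth_config(duration_s = 600, seed = 42, left_share = 0.53)
part <- synth_participant(cfg)

ws <- weight_summary(part$loadcells)
ws
#> <weight_summary>
#>   static weight 67.5 kg, 172 cycles
#>   mean left share 0.530 (max per-leg 0.536), rear share 0.650
#>   asymmetric: TRUE (heavier leg: left)

auto <- sample_frames(part$thermal, 1)          # 600 frames at 1 Hz
trk  <- simulate_tracker(cfg, part$gt,
                         frame_index = attr(auto, "source_index"))
prof <- sample_at_keypoints(auto, trk, p_cut = 0.5, radius_px = 1)
sm   <- smooth_profile(prof$LSM, 0.02)
coef(lm(temp_c ~ I(t_s / 60), data = sm))[2]
#> 0.109   # degC/min
```

The recovered static weight (67.5 kg of a 70 kg configured mass — the
raised-cosine stance only dwells briefly at full load), the 172
sit-to-stand cycles (one per 3–4 s over 10 min), and the 53% left share
match the generator's ground truth. The left SM warming slope of
0.109 °C/min is the configured 0.08 °C/min base trend plus the
load-coupled extra warming of the heavier leg (gain 1 °C/min per unit
excess share × 0.03 excess).

A whole cohort, with stratified agreement tables and report files:

```r
rc <- run_config(n_participants = 20, seed = 1, out_dir = "out")
report <- run_pipeline(rc)
report
make_figures(report, "out/figures")
```

A thin CLI over the same functions is installed at
`inst/cli/thermoknee.R` (`synth`, `extract`, `wbb`, `run`, `figures`
subcommands).

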