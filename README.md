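# motilitylab

Quantifying single-cell motility from time-lapse microscopy, end to end.

A common question in cell biology is whether a treatment changes how cells
move — in wound-healing (scratch) assays, drug screens, or physical-therapy
studies. `motilitylab` implements the full analysis platform for that
question:

1. **Localization** — cells are found in every frame with a circle Hough
   transform (CHT) over a physical radius range (default 5–8 µm at
   0.66 µm/px).
2. **Tracking** — detections in consecutive frames are linked by
   minimum-cost bipartite assignment (Kuhn–Munkres / Hungarian algorithm)
   with a displacement gate; tracks lasting less than 50 min are discarded.
3. **Kinematics** — each trajectory is smoothed with cubic smoothing
   splines, then reduced to four global descriptors:
   - mean tangential speed
     `v(t_k) = |r_s(t_{k+1}) − r_s(t_k)| / Δt` (µm/min),
   - mean curvature
     `χ = |x′y″ − y′x″| / (x′² + y′²)^{3/2}` (µm⁻¹),
   - mean turning angle `ϑ = tan⁻¹(v_x / v_y)` (rad, circular mean),
   - diffusion coefficient `D = ¼·e^{y₀}` (µm²/min), where `y₀` is the
     intercept of the ordinary least-squares line fitted to the
     mean-squared displacement in log–log space
     (`MSD(τ) = 4Dτ` for 2-D Brownian motion).
4. **Separability** — for each descriptor, the two experimental groups are
   compared with normalized histograms and a single-feature ROC curve; the
   area under the curve (AUC) is the separability measure (0.5 = random
   guessing, 1.0 = perfect classification).

Because real recordings are rarely shareable, the package ships a
first-class synthetic-data module: disk-shaped cells moving under Brownian,
persistent, circular, or stationary motion models, rendered into noisy
multi-page TIFF stacks with exported ground truth — so every stage of the
pipeline is testable against known truth.

## Worked example

A two-group in-silico experiment: control cells diffuse with
D = 0.5 µm²/min, "treated" cells with D = 5 µm²/min. Thirty cells per
group are simulated for 120 min, rendered to images, re-detected, tracked,
filtered, and compared:

```r
library(motilitylab)

cfg <- pipeline_config(
  model_ctrl    = motion_model("brownian", diffusion_coefficient = 0.5),
  model_treated = motion_model("brownian", diffusion_coefficient = 5),
  seed = 99L)
man <- run_pipeline(cfg, "motility_run")
print(man$report)
```

```
<separability_report> 22 control vs 18 treated tracks
  mean_speed_um_min        AUC = 1.0000  |AUC - 0.5| = 0.5000
  mean_curvature_per_um    AUC = 0.2955  |AUC - 0.5| = 0.2045
  mean_turning_angle_rad   AUC = 0.4545  |AUC - 0.5| = 0.0455
  diffusion_um2_min        AUC = 0.9672  |AUC - 0.5| = 0.4672
```

Reading the output: of the 30 simulated cells per group, 22 and 18
recovered trajectories survive the 50-min duration filter (fast-moving
cells collide and split more often). The speed and diffusion descriptors
separate the groups almost perfectly (AUC 1.00 and 0.97) — as they must,
since the groups differ 10-fold in D. The turning angle stays near 0.5:
both groups are isotropic random walkers, so heading carries no
information. Curvature lands *below* 0.5 — faster cells trace less curly
smoothed paths — a reminder that AUC orientation follows the "greater ⇒
treated" convention and that `|AUC − 0.5|` is the orientation-free
separability index. When both groups share the same motion model, all four
AUCs sit near 0.5.

Every intermediate artifact (ground-truth CSV, detections, tracks,
descriptors, `report.json`, `manifest.json`) is written under the output
directory, and each stage can be re-run independently from those files —
from R or from the shell front end:

```sh
Rscript exec/motilitylab detect --in stack.tif --rmin-um 5 --rmax-um 8 --out det.csv
Rscript exec/motilitylab track --detections det.csv --min-duration-min 50 --out tracks.csv
```

See `vignettes/motility-pipeline.Rmd` for the model assumptions, parameter
reference, and design notes.

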