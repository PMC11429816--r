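---
title: "The motilitylab pipeline: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The motilitylab pipeline: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`motilitylab` measures how single cells move in time-lapse microscopy and
whether two experimental groups can be told apart by their motion. This
vignette is the package's account of the science: the models each stage
assumes, the parameters that matter and why their defaults are what they
are, and the design decisions that were genuinely open.

## 1. The pipeline at a glance

```
simulate (or acquire) → detect → track → filter → describe → compare
     TIFF + truth        CSV      CSV              CSV       report.json
```

Each stage is a plain function over plain tables, and every intermediate is
written to disk in an open format, so any stage can be re-run or replaced
in isolation. `run_pipeline()` orchestrates the whole chain and records a
manifest (configuration, master seed, per-stage counts).

## 2. Synthetic acquisition: what is emulated, what is not

Real motility recordings are rarely deposited, so the generator is a
first-class, tested part of the package rather than a test fixture. It
emulates a small-scale inverted-microscope acquisition: square grayscale
frames at **0.66 µm/px**, **1 frame/min**, with cells of radius **5–8 µm**
drawn as bright disks (a 1-px Gaussian stands in for the point-spread
function) over a dark background, plus additive zero-mean Gaussian pixel
noise. An `invert` flag covers dark-on-bright modalities, and an optional
vertical cell-free band at t = 0 emulates the geometry (only the geometry)
of a scratch-wound assay.

Four motion models supply trajectories:

| model | law | parameters |
|---|---|---|
| `brownian` | per-axis increments ~ N(0, 2·D·Δt) | `diffusion_coefficient` (µm²/min) |
| `persistent` | constant speed, heading diffuses with variance 2·Δt/P | `mean_speed` (µm/min), `persistence_time` (min) |
| `circular` | circle of radius R at constant angular speed | `radius` (µm), `angular_speed` (rad/min) |
| `stationary` | constant position | — |

Cells reflect off the field-of-view boundary, so trajectories never leave
the scene and track lengths are controlled by the experimenter — this
keeps the effect of the 50-min duration filter deterministic in tests.

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: cell morphology beyond a disk,
division and apoptosis, cell–cell adhesion and contact inhibition,
photobleaching, uneven illumination, shot (Poisson) noise, focus drift,
and any directed wound-closure response. Results on synthetic data
demonstrate that the *algorithms* are implemented correctly, not that the
platform is robust to every real-world artifact.

**Seed policy.** All randomness derives from one master seed through
documented substreams, `derive_seed(master, offset, counter)`
(`(master·1009 + offset + counter) mod 2³¹−1`): per-cell trajectories use
offset 0 with the cell index as counter, frame noise offset 500000, and
the two groups of a paired dataset offsets 900000/910000. Identical
configuration + seed reproduces stacks and truth byte-for-byte.

## 3. Detection: circle Hough transform

Edges are Sobel gradient magnitudes thresholded with Otsu's method (on the
max-normalized magnitude, so thresholding is intensity-scale invariant).
Each edge pixel votes for circle centers at every integer radius between
`round(r_min/res)` and `round(r_max/res)` px along its gradient direction
— on both sides by default, so polarity does not matter. Each radius
accumulator is pooled with a 3×3 box (sub-pixel vote scatter) and divided
by the perimeter 2πr so scores are comparable across radii.

Two choices here were genuinely open:

* **Peak threshold.** Peaks are kept at ≥ `rel_threshold` (default 0.5)
  times the **global** accumulator maximum across radii, not a per-radius
  maximum. A per-radius relative threshold manufactures detections at
  radii where only noise voted (every radius has *some* maximum); the
  global reference keeps the "empty frame → empty result" contract without
  an absolute-score knob.
* **Non-maximum suppression.** Greedy by descending score with minimum
  center separation `r_min` px; exact ties are broken by (y, x, r)
  lexicographic order for determinism. Surviving peaks are refined to
  sub-pixel accuracy by a 3×3 vote centroid.

Degenerate inputs: a constant (or numerically flat, range ≤ 10⁻¹² of the
intensity scale) frame returns an empty table, not an error; a radius
range collapsing below 1 px is a configuration error.

## 4. Tracking: per-pair optimal assignment

Between consecutive frames, the Euclidean distance matrix (µm) is solved
for the minimum-cost complete matching of the smaller side with an O(n³)
shortest-augmenting-path Hungarian implementation (`solve_assignment()`,
written in-package: no installed dependency provides linear-sum
assignment). This is *per-frame-pair* optimal and therefore globally
greedy in time — deliberately, matching the platform's stated
frame-by-frame distance computation.

* **Gating.** Pairs farther than `max_disp` (default 4·r_max = 32 µm per
  frame) are forbidden by a large-cost sentinel; dummy columns pad unequal
  sets. Minimizing total cost under a large sentinel first maximizes the
  number of feasible links, then minimizes their summed distance.
* **No gap closing, no merge/split.** A missed detection terminates a
  track and seeds a new one. This makes the filter's input well defined
  and is honest about what a frame-linking tracker can know.
* **Singletons.** Detections that never link (1-sample candidates) are
  dropped and counted separately; every returned track has ≥ 2 samples,
  and detections are conserved (samples + singletons).

Tracks shorter than **50 min** (duration = t_last − t_first, boundary
kept) are then discarded; with the defaults that means a track must span
≥ 51 frames.

## 5. Kinematic descriptors

Positions are smoothed with cubic smoothing splines fitted independently
to x(t) and y(t) (`stats::smooth.spline`, `all.knots = TRUE` — the default
knot subset imposes a resolution floor of its own that distorts fine-scale
motion). Three numerical decisions deserve explanation:

* **One smoothing parameter for both axes.** Per-axis parameter selection
  breaks rotation invariance (rotating a trajectory mixes the axes and
  changes each axis's chosen smoothness). The package therefore selects a
  single `spar` by minimizing the *sum* of the two axes' GCV criteria
  (default), by a discrepancy rule (`smoothing = "localization"`: the
  lightest smoothing whose RMS residual reaches `sigma_loc`, default
  0.2 µm ≈ 0.66/√12, the pixel-quantization scale), or as a fixed number.
  With a shared parameter the smoother is one linear operator applied to
  both axes, and speed, curvature, and D are exactly rotation invariant.
* **Derivative descriptors use the smoothed path.** Tangential speed is
  the forward-difference step speed of the smoothed positions; curvature
  `|x′y″ − y′x″|/(x′²+y′²)^{3/2}` uses the spline derivatives, as a
  magnitude (signed curvature averages toward zero on any symmetric
  path). Points with squared speed below 10⁻¹⁰ are reported `NA` —
  direction is undefined at rest — and excluded from means.
* **The MSD uses the raw positions.** A smoothing spline removes exactly
  the short-lag displacement content that the MSD of a diffusive path is
  made of: on simulated Brownian tracks, GCV-smoothed positions deflate
  the fitted intercept enough to bias D low by tens of percent, and *any*
  residual-matching rule still forces a distortion on noiseless input. The
  integrative MSD is already robust to zero-mean localization noise
  (which adds a small constant, not a slope), so `msd_profile()` operates
  on the measured positions while the derivative descriptors keep the
  smoothed ones. This is the package's one deliberate deviation from
  "smooth first, then every descriptor", and this paragraph is its
  rationale.

The MSD is the overlapping time average
`msd(mΔt) = mean_k |r(t_k+mΔt) − r(t_k)|²`, fitted by OLS in log–log
space over lags `1..max(3, ⌊n/4⌋)` (the short-lag regime; long lags have
few independent windows and dominate the variance). Natural logarithms are
used throughout, so `D = ¼·e^{y₀}` with `y₀` the fitted intercept; the
slope α is reported as the anomalous-scaling exponent (α = 1 for pure
diffusion). Zero-MSD lags (stationary tracks) are excluded; fewer than 3
usable lags marks the fit, and D, missing.

**Turning angle.** The platform's printed formula reads `tan⁻¹(v_x/v_y)`,
i.e. the heading measured from the +y axis. The package honors that
convention with a full-quadrant two-argument arctangent
(`atan2(v_x, v_y)`, range (−π, π]) as the default, and offers the
conventional from-+x `atan2(v_y, v_x)` via `angle_convention = "math"`.
Whether "turning angle" means heading or heading *increment* cannot be
settled from the formula alone; the package computes the heading exactly
as printed. Because headings are periodic, per-track aggregation uses the
circular mean — for an isotropic walker the mean resultant is near zero
and the circular mean is essentially an arbitrary angle, which is itself
informative: heading then carries no group information, and its AUC sits
at 0.5.

## 6. Separability

Each descriptor is compared between groups by a single-feature ROC: a
sample is called "treated" when its value exceeds the threshold, swept
over all observed values. The trapezoid AUC equals the Mann–Whitney
probability `P(X_treated > X_ctrl) + ½P(tie)` (mid-rank tie handling), a
property the test suite asserts to 10⁻¹² against pairwise counting and an
independent library implementation. Since the "greater ⇒ treated"
orientation is a convention, the report also carries the orientation-free
index `|AUC − 0.5|`. Histograms use Freedman–Diaconis bins computed on the
pooled sample so both groups share edges, normalized to sum to 1 over
in-range values (out-of-range values are counted separately). Tracks are
the unit of replication, and group sizes are always recorded alongside
every AUC. No confidence intervals are attached in the core report.

## 7. Problem sizes and defaults

Desk-scale defaults keep a full run interactive: 256×256 px, 120 frames,
30 cells/group. `full_scale = TRUE` switches to the acquisition-scale
geometry (72 h at 1 frame/min → 4320 frames). The test suite exercises,
among others: 300 tracks/group × 200 frames for the null-separability
check (both groups from the identical Brownian model, all four AUCs
required in [0.40, 0.60]); 300 tracks per D ∈ {0.5, 1, 2} µm²/min for
diffusion recovery (median within 15%); circles with R ∈ {5, 10, 20} µm
for curvature (within 5% of 1/R); 100 random ≤ 7×7 assignment instances
against an exhaustive-permutation oracle; and a full imaging run with a
10× diffusion contrast (diffusion AUC ≥ 0.9).

## 8. Known limitations

* The detector assumes roughly circular cells within a narrow radius band;
  elongated or spread morphologies will be missed or mislocalized.
* Frame-pair linking has no motion model; very fast cells (step larger
  than the gate) or dense fields with frequent contacts fragment into
  shorter tracks, which the 50-min filter then removes — group
  comparisons remain valid, but survivorship can correlate with motility.
* D estimation by log–log intercept assumes the short-lag MSD is in the
  diffusive regime; strongly persistent or confined motion bends the
  log–log line, and α ≠ 1 flags exactly that.
* The synthetic generator's simplifications (Section 2) bound what the
  green test suite can claim about real microscopy data.
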