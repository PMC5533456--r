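---
title: "Methods: quantifying an epithelial fold as a lineage boundary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying an epithelial fold as a lineage boundary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the measurement model behind `foldquant`: what
each quantity means, which numerical conventions the implementation
commits to, what the synthetic-data generator emulates, and where the
limits of both lie. It contains no empirical claims beyond what the
package's own tests and `scripts/acceptance.R` compute.

## 1. The biological model

The eye–antenna imaginal disc (EAD) of *Drosophila* larvae is a single
epithelial sheet that becomes subdivided into an eye field and an
antennal field. At the interface, Notch-dependent apical constriction
drives a fold: border cells shrink their apical surfaces, drop out of the
main plane, and form a ridge that coincides with the sharpening
expression border between *Distal-less* (Dll, antennal) and *Lim1*
(opposing side), with the Notch ligands Delta (Dl) and Serrate (Ser)
progressively aligning with it. Functionally, the fold behaves as a
lineage-restricting boundary: clones induced before fold formation
frequently straddle the interface, clones induced after it rarely do.

`foldquant` treats each facet of that model as a measurable quantity over
tabular data — the package never touches images; it starts where
segmentation and intensity extraction end.

## 2. Apical-area dynamics

A trace is a per-cell time series of apical area, `cell_trace(id, times,
areas)`, in µm² over minutes.

**Classification** (`classify_trace`) uses thresholds bundled in
`dynamics_thresholds()`:

* `fluct_delta = 10` µm² — a cell is *fluctuating* if its total excursion
  `max(A) − min(A) ≥ 10`, inclusive; below that it is *constant*.
* `decr_start_lo = 20`, `decr_start_hi = 40`, `decr_final = 10` µm² — a
  cell is *decreasing* if its initial area lies in [20, 40] and its final
  area is `< 10`. Decreasing takes precedence over fluctuating, since a
  full constriction necessarily exceeds the excursion threshold.
* `edge_window = 3` frames — initial/final areas are means of the first
  and last three frames, which damps single-frame segmentation error
  without hiding the trend.

**Proportional change** is `(A(t) − Ā)/Ā` with `Ā` the time-mean of the
trace; it is scale-free and has zero time-mean identically, so cohort
curves of different absolute size are comparable.

**Constriction onset** (`constriction_onset`) runs a Welch two-sample
t-test per common time point between fold and non-fold cohorts and
reports the earliest time from which significance (default α = 0.05) is
*sustained through the end* — transient early significance does not
count. With 6-minute frames, onset is resolved to one frame. Traces on
different clocks are aligned by linear interpolation onto a common grid
(`common_grid`, `resample_trace`); extrapolation is refused rather than
guessed.

## 3. Expression borders

Line profiles perpendicular to the border are stored as positions (µm)
plus per-channel intensities with a scalar background estimate.

* **Normalisation** (`normalize_profile`): divide by background (default)
  or subtract it; division makes profiles from different imaging sessions
  comparable as fold-over-background.
* **Segregation** (`segregation_metrics`): for two opposing markers the
  crossing point is found by linear interpolation of their difference,
  and the overlap width is the extent over which both exceed their
  half-range midpoints, summed stepwise so disjoint overlap runs
  accumulate. Flat or non-crossing pairs return `defined = FALSE` rather
  than a fabricated number.
* **Ligand alignment** (`ratio_regression`): ordinary least squares of
  the Dl/Ser ratio on the Dll/Lim1 ratio per cell, optionally on log
  ratios. Cells with non-positive denominators are excluded and counted;
  fewer than 3 usable cells is an error, not a silent NA.
* **Co-expression** (`coexpression_percent`): a cell co-expresses two
  markers when both channels exceed their thresholds; the recommended
  threshold is background mean + 2 sd per channel.
* **Staging** (`assign_stage`): discs are assigned to mid-L2, late-L2 or
  early-L3 by nearest reference mean area (4835, 6058, 7065 µm²), ties
  going to the younger stage.

## 4. Clone restriction

The fold is an open or closed polyline, `fold_line(vertices, closed)`;
self-intersecting polylines are rejected at construction.

* **Signed distance** (`signed_distance`): distance to the nearest
  segment, signed by the cross product with that segment's direction; at
  vertices, the tie breaks toward the segment with the larger |cross|,
  which is the geometrically stable choice. For closed folds, sign is
  determined by point-in-polygon (inside = A-side).
* **Side calls** (`side_of_fold`): `"A-side"`, `"B-side"`, or
  `"on-line"` within a tolerance of 0.25 µm — roughly one pixel at
  typical magnification — because a cell centroid resting exactly on the
  boundary is a segmentation ambiguity, not evidence of a side.
* **Scoring** (`score_clone`): *restricted* only if every cell is
  strictly one-sided; one cell on the other side means *crossed*; any
  on-line cell is an error that forces the analyst to re-segment rather
  than let a rounding artifact decide the call.
* **Reporting**: percentages use explicit half-up rounding
  (`round_half_up`), because base R's banker's rounding would make
  reported fractions depend on parity. Restriction fractions print with
  2 decimals, penetrance with 1 (plus a `"k/n"` string), pooled rates as
  integers — matching how such fractions are conventionally reported.

## 5. Contour-stack volumetry

A cell compartment is a stack of cross-section polygons at increasing z.

* Slice area: shoelace formula (`pracma::polyarea`); volume: trapezoidal
  integration over z (`pracma::trapz`). The trapezoid rule is exact for
  cross-sectional areas varying linearly between slices and for right
  generalized cylinders, which is the regime of closely spaced optical
  sections; package tests verify convergence against closed forms (cone,
  hemisphere) and a voxel-counting oracle.
* Slice intervals follow the acquisition settings per compartment:
  0.27 µm apical, 0.47 µm basolateral (`slice_interval`).
* Height is the z-extent plus one slice interval by default — each
  optical section represents a slab, so a one-slice stack has the
  interval as height, not zero; `height = "extent"` is available for the
  bare z-range convention.
* Maximal circumference is the largest slice perimeter.
* Cohort ratios (`volume_ratio`) are means-of-groups per compartment;
  significance testing (`group_compare`) offers Welch t-tests
  (two-sample), ANOVA + Tukey HSD (all pairwise), and Dunnett contrasts
  via `multcomp` (several treatments against one control).

## 6. Trajectories and fold crossing

Tracks are (t, x, y) per cell with group and layer labels.

* `displacement_summary`: net displacement, path length, and orientation
  in (−180°, 180°], flagged undefined for zero net movement.
* `crossing_events`: the track's side-of-fold sign sequence is run-length
  encoded; only runs of at least `persistence = 3` frames count as
  residing on a side (the first run is kept regardless), and a crossing
  is a transition between successive kept runs of opposite sign. This
  makes single-frame excursions — tracking jitter at the boundary —
  invisible, at the cost of missing genuine sub-18-minute round trips.
* `group_displacement_test`: Welch t-tests on per-track net dx, dy and
  orientation components (cos, sin) between groups.
* `crossing_window` relates crossing times to a fold-reformation time
  after ablation.

## 7. The synthetic-data generator

`synth_config()` holds every generator parameter; defaults encode the
study conditions, and all generators return ground truth with the data.
Randomness is confined to `with_seed`, which restores the caller's RNG
state; each generator uses a fixed offset from the configured seed so
adding one step never shifts another's draws.

What it emulates, and how:

* **Traces** — three archetypes with guard-banded parameter ranges so
  ground-truth labels are exactly recoverable by the classifier: constant
  cells oscillate gently (excursion strictly below 10 µm²), fluctuating
  cells pulse with period ~60 min and excursion well above threshold
  (final phase rejected if it would dip the last-3-frame mean toward the
  decreasing rule), decreasing cells start in [22, 38] µm² and ratchet
  down to below 8.3 µm² beginning at the configured onset (default
  180 min into a 300 min movie at 6 min frames). Default composition is
  17/31/17 per control movie.
* **Profiles** — opposing sigmoids with a per-stage sharpening schedule
  (widths 8/4/2 µm, amplitudes 2/3/4× background). Per-cell ligand
  intensities are built from a latent bivariate normal with per-stage
  correlation (0.3, 0.6, 0.85) mapped through `exp(z/4)`; the soft
  exponent and the default of 200 cells keep the ordering of regression
  R² across stages stable at realistic sample noise. Co-expressing cells
  are planted explicitly (defaults 4/2/0 by stage) with intensities
  guard-banded around the mean + 2 sd threshold so calls are exact.
* **Clones** — cells placed at least `clone_margin = 1` µm off the fold;
  restricted clones strictly one-sided, crossing clones guaranteed at
  least one cell per side. Counts of restricted clones can be fixed
  (reconstruction) or drawn from per-stage barrier strengths
  (0.03/0.19/0.86).
* **Contour stacks** — irregular 12-gons over per-compartment z-extents;
  fold cells are XY-scaled copies (factor √ratio) of the non-fold cohort,
  so cohort mean volume ratios are exactly the configured 20 % (apical)
  and 50 % (basolateral) and the trapezoid rule is exact for them.
* **Tracks** — bounded wandering on one side; crossing tracks make one
  jump transition (±1.5 µm across a line fold, noise bounded at
  ±0.4 µm), guaranteeing exactly one persistent crossing. Crossing
  starting sides alternate and per-axis displacement is zero-mean in both
  groups, so group displacement tests are null by construction.

What it does **not** emulate: images or segmentation itself, curvature of
real fold geometry in 3D, cell neighbour topology, division and death
within traces, stage-dependent disc growth, or intensity bleed-through
between channels. Quantities downstream of those (e.g. true penetrance of
clone induction) are inputs to the generator, not emergent.

## 8. Design decisions and limitations

* Base-R S3 data structures (lists + data frames) rather than a
  heavyweight class system: every object is inspectable with `str()` and
  serialisable to CSV/JSON interchange files (`write_*`/`read_*`), which
  is what collaborating imaging pipelines consume.
* Statistics are delegated to `stats` and `multcomp`; geometry and
  integration primitives central to the method (signed distance, polygon
  volumetry, persistence filtering) are implemented here and tested
  against independent oracles (brute-force distance loops, voxel
  counting, closed-form solids).
* Thresholds are parameters with study-condition defaults, not constants:
  `dynamics_thresholds()`, `side_of_fold(tol=)`,
  `crossing_events(persistence=)` all accept overrides.
* The trapezoid rule under-integrates convex caps (hemisphere tops)
  between coarse slices; tests document the convergence rate, and users
  with sparse z-sampling should treat sub-percent volume differences as
  below resolution.
* The on-line tolerance (0.25 µm) and persistence window (3 frames) are
  acquisition-dependent; both defaults assume the study's pixel size and
  6-minute frame interval and should be rescaled for other setups.
* `run_pipeline` orchestrates the full synthetic workflow and writes a
  JSON report; it is deterministic given a seed, and
  `scripts/acceptance.R` (in the source tree) reproduces the headline
  quantities against the installed package from any seed.
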