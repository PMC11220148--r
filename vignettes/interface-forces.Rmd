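---
title: "Computing vector contact forces at the human-mattress interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing vector contact forces at the human-mattress interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vecforce)
```

## The measurement problem

A grid pressure mat under a lying person reports one scalar per sensor:
the force acting perpendicular to the *local* surface of the deformed
mattress. On a soft support the surface tilts under the body, so the
scalar readings are not vertical forces — they hide shear (in-plane)
components that matter both for comfort research and as boundary
conditions for musculoskeletal models of sleeping postures. The sensors
themselves cannot tell which way they are pointing.

`vecforce` recovers the missing directions by fusing two measurements:

1. the 24 x 48 pressure map (cell pitch 36.25 mm), time-averaged over
   the steady middle of a trial, and
2. a 3D scan of the *deformed* mattress surface — in the motivating
   protocol a vacuum positioning mattress is hardened after the person
   rises, preserving the body's indentation for scanning.

Once the pressure grid is registered onto the scan, each cell inherits
the local surface orientation and its scalar force `F` becomes a vector

$$\vec F_s = F \, \hat n_s,$$

where `n_s` is the mean unit normal of the scan points falling inside
that cell. The vertical components `f_z` then sum to a quantity directly
comparable with body weight `G` (the force-balance validation), while
the horizontal components expose lateral (mat width, x) and axial (mat
length, y) shear.

## Pipeline stages and their assumptions

**Windowing and averaging.** `select_middle_window()` keeps the frames in
the closed interval centred on the timestamp midpoint (default 10 s of a
30 s trial); `average_frames()` takes the per-cell arithmetic mean. The
assumption is a quasi-static posture: transients at lie-down and rise
are discarded, and a single averaged grid represents the trial.

**Units.** Mats report mmHg; forces are needed in N.
`convert_to_newtons()` multiplies by 133.322 Pa/mmHg and the full cell
area (36.25 mm)^2, i.e. 1 mmHg -> 0.17519 N per cell. This treats the
sensor reading as a uniform pressure over its cell; the constant is an
argument so calibrated devices can override it.

**Expansion and registration.** The grid has no natural z; to register
it against the scan, `expand_pressure_cloud()` places one point per
loaded cell at depth `-(F / F_max)(z_max - z_min)`, using the scan's own
z extent. This makes the deepest pressure map to the deepest indentation
— a *surrogate* shape, adequate because registration mostly has to
resolve the in-plane pose. Zero cells are omitted: they carry no force
and would drag the alignment toward the undeformed plane.
`coarse_align()` is a deterministic stand-in for manual pre-alignment
(centroid translation plus in-plane principal axes, the four sign/axis
assignments disambiguated by nearest-neighbour RMSE), and `icp_refine()`
is classical point-to-point ICP with an SVD (Kabsch) rigid fit.
Point-to-point rather than point-to-plane is deliberate: the source z is
a pressure surrogate, not geometry, so plane residuals have no better
footing. Defaults (correspondence cut-off two cell pitches = 72.5 mm,
200 iterations, relative RMSE tolerance 1e-6) are exposed as arguments.
Registration is strictly rigid; the only scaling anywhere is the z
normalisation above.

**Normals and binning.** If the scan lacks normals,
`estimate_normals()` fits a plane to each point's k = 12 nearest
neighbours (smallest-spread direction of the local covariance) and
orients every normal upward (z >= 0) — out of the mattress, toward the
body, so computed forces are the support forces acting on the person.
`bin_points_to_cells()` assigns scan points (carried back into the mat
frame by the inverse registration transform) to cells by half-open
intervals from the lower-left origin, so every point lands in exactly
one cell; out-of-footprint points are counted, not silently dropped.
`cell_mean_unit_normal()` averages then renormalises; a near-cancelling
mean (norm < 1e-9) raises an error, because opposing normals inside one
36 mm cell indicate registration failure, not geometry.

**Shadow cells.** Scans shadow: some loaded cells may receive no points.
The default policy borrows the mean normal of the 8 nearest scan points
within two cell pitches (falling back to vertical beyond that);
alternatives are `"vertical"` (always flat) and `"strict"` (refuse).
The filled-cell count is reported in the pipeline log.

**Force balance.** `trial_summary()` reports total pressure (sum of
scalar forces), the component sums, and each as a percentage of body
weight. Because every cell contributes its *full* magnitude to total
pressure but only `F n_z` to the vertical sum, total pressure/weight
ratios above 100% are expected on a conforming surface — around 130% in
practice — while the vertical ratio should hover near 100%. Cohort
statistics (`cohort_summary()`) use the population SD (divide by n),
recorded in the output as `sd_mode`, and are always computed from
unrounded per-trial ratios; printed tables are matched by rounding half
away from zero to two decimals at report time only
(`round_half_away()`).

## Regional wrenches

For model input, `region_wrenches()` reduces the force field inside each
body-region rectangle (head, chest, waist, hips, legs — editable index
ranges, see `default_regions()`; the defaults are starting points to be
adjusted against the heatmap, not anatomical truth) to a resultant force
`F_A = sum F_i`, a resultant couple `M_A = sum r_i x F_i` about the mat
origin, and an application point.

The application point deserves a note. Formally one would like to invert
`r_A x F_A = M_A` for `r_A`, but the cross-product matrix of any vector
is singular (rank 2, `cross_matrix()`), so no inverse exists: the
component of `M_A` parallel to `F_A` cannot be produced by any
application point. `solve_application_point()` implements the resolution
natural for a planar contact: constrain `r_A` to the sensor plane z = 0,
split off the parallel ("free") moment as an explicit scalar residual,
and solve the in-plane equation by least squares. Whenever the resultant
has a vertical component — always true for contact forces — the two
in-plane coefficient directions span the plane perpendicular to `F_A`
exactly, so the perpendicular moment is reproduced without defect and
the reconstruction `r_A x F_A + residual * F_A/|F_A| = M_A` holds to
machine precision. This `r_A` generalises the centre of pressure.
Exports (`export_boundary_conditions()`) convert to SI (N, N·m, m) and
record the moment origin, which is always the mat's lower-left corner in
this package.

## sEMG processing

The EMG validation chain mirrors standard practice: a zero-phase
Butterworth band-pass (20–500 Hz; prototype order 4 per edge, the MATLAB
`butter(4, ...)` convention), a 50 Hz biquad notch (Q = 30 — a
conventional mains-notch width, chosen here as the quality factor is
otherwise unspecified), a centred moving-RMS envelope of 66.7 ms (100
samples at 1500 Hz, truncated at the edges), and normalisation to the
largest peak across the MVC repetition envelopes. The trial statistic
defaults to the envelope *mean* over the trial — a 30 s lying posture is
a sustained, not impulsive, effort — with `"peak"` selectable.
Zero-phase filtering is used because envelope timing matters and
one-pass filtering would delay it. `spearman_activity()` is the rank
correlation (ties mid-ranked) used to compare measured %MVC against
model-predicted activity; it requires at least 3 pairs and refuses
constant series.

## The synthetic generator: what it emulates, what it does not

`make_scenario()` builds scenes with closed-form ground truth: the
indentation is a sum of Gaussian lobes (so surface normals are analytic),
per-cell vertical loads are proportional to share-weighted lobe depth,
and a known rigid transform separates the mat frame from the scan frame.
Two presets caricature supine (five midline lobes) and lateral (four
laterally offset lobes) load patterns; a seed jitters geometry
reproducibly. Body weight defaults to 600 N.

Raw lobe loads are then *minimally redistributed* so the truth is in
static equilibrium — vertical components summing exactly to G and net
shear exactly zero, as for any resting body. The correction solves a
3 x 3 system for a multiplicative field over the per-cell shear slopes;
it only has to absorb Gaussian-tail truncation at the mat edge, so it is
tiny. This is what makes `sum(f_z) = G` an exact oracle for the
pipeline.

The generator emulates smooth indentations, scan noise (additive
Gaussian on points) and sensor noise (additive Gaussian on the grid,
truncated at zero), and arbitrary in-plane misalignment. It does *not*
emulate wrinkles or sharp folds, scan holes and occlusions, mat
creep/hysteresis, or anthropometric shape — so a passing pipeline shows
correctness of the geometry-to-force chain, not robustness to every
artefact of real scans. Scenario artifacts are written through the
package's own writers (`write_scenario_files()`), so tests exercise the
same PLY/CSV readers as real data.

## Numerical choices and problem sizes

Scan lattices of 9 mm (about 19k points) are used for the full-scale
checks and 12–15 mm for unit tests; at 9 mm the whole pipeline runs in a
few seconds. Normal estimation uses k = 12 neighbours — at 9 mm spacing
a disc of radius ~1.5 cell pitches, small against lobe widths of 70 mm
and more. ICP stops on a relative RMSE change of 1e-6. Degenerate inputs
fail loudly and early: all-zero grids cannot be expanded (no `F_max`),
empty clouds cannot be aligned, zero resultants have no application
point, zero MVC peaks cannot normalise. Under the stated noise
conditions (0.5 mm on points, 1% of peak on pressures) the vertical
recovery stays within a few tenths of a percent of body weight, well
inside the 95–105% band observed across real trials.

## Known limitations

- Registration quality is bounded by the pressure-to-depth surrogate; a
  strongly nonlinear mat response would shift the expanded cloud's shape
  and could bias the in-plane pose by a few mm. The per-cell normals are
  smooth at that scale, so force sums degrade gracefully.
- The scalar cell force is applied unchanged to the deformed cell; no
  attempt is made to re-distribute force when deformation changes the
  effective cell area.
- The mmHg-to-N conversion assumes uniform pressure over the full cell.
- Region layouts are user responsibility; the defaults are plausible
  rectangles, not a segmentation algorithm.
- The musculoskeletal model itself (scaling, inverse dynamics, muscle
  recruitment) is out of scope; this package ends at boundary-condition
  export and at the %MVC / rank-correlation machinery used to compare
  measured with predicted activity.
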