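---
title: "Displacement microscopy of cell-imparted hydrogel deformations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Displacement microscopy of cell-imparted hydrogel deformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement

Adherent cells pull on their substrate. On a soft hydrogel with fluorescent
fiduciary beads embedded near the surface, those tractions show up as bead
motion in a time-lapse recording. *Displacement microscopy* stops there: it
quantifies the substrate deformation itself — no inversion to traction
forces, and therefore no regularization choices — and summarises it as a
single per-condition statistic that can be compared across gel stiffness,
gel thickness, plating density, and culture time.

This package implements that pipeline end to end on synthetic data with
exact ground truth:

1. **`scene_config()` / `scenario()` / `render_stack()`** — a seeded
   generator of bead time-lapse stacks deformed by model cell tractions;
2. **`build_grid()` / `track_pair()` / `track_sequence()`** — a digital
   image correlation (DIC) tracker measuring the displacement of a node
   lattice between hourly frame pairs;
3. **`accumulate_displacements()` / `percentile_timecourse()` /
   `window_average()`** — the cumulative-displacement statistics;
4. **`effective_stiffness()` / `attenuation_factor()`** — an axisymmetric
   finite-element model of how finite gel thickness and lateral constraint
   change the apparent stiffness a contracting cell feels;
5. **`render_zprofile()` / `estimate_thickness()`** — gel thickness from
   confocal z intensity profiles;
6. **`run_simulate()` / `run_track()` / `run_summarize()` / `run_all()`**
   — staged runners plus a thin command line at
   `system.file("scripts", "gelsense", package = "gelsense")`.

## The synthetic generator

A scene is a 512 × 512 px field of view at 0.65 µm/px with 800
sub-resolution beads rendered as Gaussian spots (σ = 1.5 px, peak 0.5
above a 0.05 background, additive noise σ = 0.05 — spot SNR 10 — quantized
to 16 bits). Every random draw (bead positions, cell placement, per-frame
noise) comes from a seed derived deterministically from the scene seed, so
stacks are bit-reproducible; `write_stack()` produces byte-identical TIFFs
for identical scenarios.

Each cell is a radially contracting traction centre. At distance $r$ from
a cell centre, at time $t$, the surface displacement has magnitude

$$|u|(r, t) = s\,\bigl(1 - e^{-t/\tau}\bigr)\,\frac{r}{\sigma}\,
  e^{-r^2 / 2\sigma^2},$$

directed toward the centre, with strength $s$ (default 20 µm), reach
$\sigma$ (default 80 µm), and ramp time $\tau$ (default 8 h). The field is
zero at the cell centre, peaks at one reach length with value
$s(1 - e^{-t/\tau})e^{-1/2}$, decays smoothly to zero, and superposes
linearly across cells. The reach default is set once for all scenarios:
contractile stromal cells deform soft gels over $O(100\ \mu m)$, so at
20 000 cells/cm² (mean spacing ≈ 71 µm) neighbouring pulls overlap and
partially cancel, while at 1000 cells/cm² (≈ 316 µm) cells act as isolated
wells. Density-placed cells are a Poisson draw over the field of view plus
a two-reach margin, since cells just outside the frame still deform the
imaged surface.

**Realism and limits.** The generator captures what the tracker and the
statistics are sensitive to — spot photometry and noise, smooth
superposed displacement fields with a saturating ramp, finite-thickness
attenuation — and deliberately omits what they are not: bead
photobleaching, focal drift, out-of-plane motion, cell bodies occluding
beads, and any active cell dynamics (migration, divisions, force
fluctuations). Displacements move beads from their time-zero positions
(small-displacement Lagrangian approximation), which is accurate for the
few-micron fields simulated here.

### Why per-cell strength falls with plating density

With linearly superposed, randomly placed, identical cells, the typical
field magnitude *grows* like $s\sqrt{\rho}$ with density $\rho$ — random
pulls accumulate like a random walk; cancellation reduces the per-cell
budget, not the total. Observed monolayers show the opposite: crowded
cells deform the substrate far less. The standard interpretation is that
mechanically coupled neighbours hold each other in a tug-of-war and each
cell imparts less deformation. The density presets therefore scale
per-cell strength inversely with density ($s = 20\ \mu m \times
1000/\rho$: a conserved total contractile budget, anchored at the
reference strength for 1000 cells/cm²). The superposition property itself
— splitting a fixed *total* strength across more cells lowers the upper
percentile of the field — is kept as a tested invariant.

## The tracker

`track_pair()` matches a 31-px template around each node by
zero-normalized cross-correlation over integer offsets within ±6 px, then
refines the peak with a least-squares quadratic surface over a 9-px
correlation neighbourhood. Numerical choices that matter:

- **Weighted subpixel fit.** The correlation surface of a sparse bead
  template is a narrow peak on a flat ring; an unweighted quadratic fit is
  dominated by the ring and lands well off the peak (~0.3 px error in an
  identity test). The fit is therefore Gaussian-weighted toward the peak
  (σ = max(0.75, w/8) for window width w), which brings identity-test
  error below 0.12 px. An intensity-weighted centroid is the fallback when
  the fitted surface is not concave.
- **Outlier replacement.** With 800 beads in 512² px, a 31-px template
  holds ~3 beads and can lock onto the wrong one. A normalized-median test
  (each node's raw displacement against the median of its 8 nearest
  reliable neighbours, residual floor 0.2 px, threshold 2) flags such
  nodes `low_corr` and substitutes the smoothed neighbour estimate.
  Integer peaks on the search border are flagged `clamped`; a clamped
  value that is also an isolated outlier among consistent neighbours is
  treated as a false match, but when no reliable majority exists (a true
  out-of-range motion) clamping is preserved.
- **Field smoothing.** Reliable displacements are blended with their
  Gaussian-weighted (25 px) neighbour average as
  $\hat u = (u + s\,\tilde u)/(1 + s)$ with weight $s = 5$;
  $s = 0$ disables smoothing exactly.
- **Lagrangian tracking.** `track_sequence()` advects node positions by
  the measured displacement each interval so the same material point is
  followed; nodes whose template would leave the image are frozen with a
  warning.

On the seeded uniform-shift benchmark (3.30, −2.10 px at SNR 10) the
tracker recovers the shift with RMSE < 0.1 px across the 99-node lattice.

## The statistics

Frames are paired one hour apart (`hourly_pairs()`; a 5-min cadence over
24 h gives 289 frames and 24 chained hourly intervals). Per-node interval
displacements accumulate in **path mode** (sum of interval magnitudes,
nondecreasing — the default, since it measures total remodelling activity
regardless of direction reversals) or **net mode** (magnitude of the
vector sum); path dominates net pointwise. At each time point the
90th percentile of cumulative displacement is taken across nodes pooled
over replicates — linear interpolation between order statistics, so the
90th percentile of 1…10 is 9.1 — with the spread reported as the
(n − 1) standard deviation of per-replicate percentiles. The scalar
per-condition statistic is the unweighted mean of the percentile over the
8–24 h window (inclusive), after the ramp has saturated.

## Layer mechanics

How much harder is it to deform a thin gel bonded to glass? The model is
a rigid circular patch of radius $a$ (default 25 µm, a spread cell's
footprint) displaced on a linear-elastic layer of thickness $h$ bonded to
a rigid base, solved with Fourier-harmonic axisymmetric finite elements:
bilinear quadrilaterals in $(r, z)$, harmonic $n = 0$ for normal loading
and $n = 1$ for tangential, stiffness recovered from the strain energy as
$k = 2U/\delta^2$. Three numerical points:

- **Selective reduced integration.** Polyacrylamide is modelled as nearly
  incompressible (ν = 0.499; ν = 0.5 is capped with a warning). Full 2 × 2
  integration locks volumetrically (+37% stiffness error in the half-space
  limit); one-point integration of the volumetric term brings both loading
  modes within ~3% of the classical closed forms
  $k_n = 2Ea/(1-\nu^2)$ and $k_t = 8Ga/(2-\nu)$ at $h/a = 50$.
- **Truncation radius.** The laterally unconstrained domain is truncated
  traction-free at $\max(20a, 3h)$: for thick layers a radius tied only to
  $a$ leaves a slender column that flexes like a cantilever under
  tangential load (−40% at $h/a = 50$ with $R = 20a$). A finite
  `R_lateral_um` instead fixes the outer boundary, modelling crowding by
  neighbouring contracting cells; walls at $R = 3a$ stiffen the response
  by ~20%.
- **Verification.** `effective_stiffness(verify = TRUE)` re-solves on a
  1.5× refined mesh and errors if the stiffness moves by more than 2%.

`attenuation_factor()` gives the factor $k(h\!\to\!\infty)/k(h) \in
(0, 1]$ by which finite thickness shrinks the displacement a fixed
traction produces. Both numerator and denominator come from the same
solver (thick-limit reference at $h/a = 50$) so discretization bias
cancels; the factor is independent of $E$. The synthetic thick/thin arms
(200 vs 50 µm soft gel, identical cells, normal-mode attenuation) differ
by this factor, and the tracked pipeline recovers their window-mean ratio
≥ 1.5.

## Thickness from z-profiles

`estimate_thickness()` reads the full width at half maximum of a labelled
slab's z intensity profile: baseline from the median of the lowest decile,
plateau from the median of the top decile (robust to noise extremes; equal
to the max on noiseless profiles), crossings of the half-way level located
by linear interpolation. It requires a clear plateau (peak > 3× baseline),
rejects profiles with multiple plateaus (listing the candidate intervals),
and warns when the plateau touches the scan boundary. On noiseless
boxcars the estimate is exact; with blurred edges and SNR-20 noise,
averaging triplicate scans recovers 27–597 µm slabs within half a 2-µm
z-step.

## Problem sizes and runtime

All problem sizes are the package's choice, set for desk-scale runs: the
scenario presets render 512 × 512 px stacks at hourly cadence (25 frames)
rather than every 5 min, since the statistics consume hourly pairs anyway;
the FE meshes resolve the patch with 24 elements. The full synthetic
thick/thin comparison (2 conditions × 3 replicates, render + track +
summarise) takes about a minute on one CPU; a single `effective_stiffness`
solve takes a couple of seconds and repeated attenuation factors are
cached per session.

## Limitations

- The cell field is a phenomenological surrogate, not a traction-to-
  displacement Green's function solution; its strength/reach/ramp
  parameters are set to plausible magnitudes, and comparisons across
  scenarios are meaningful in *ordering*, not in absolute microns.
- Thickness attenuation is applied as a single scalar factor from the
  axisymmetric punch model rather than a per-cell boundary-value solve.
- The tracker assumes displacements within ±6 px per interval and mostly
  in-plane motion; out-of-range motion clamps rather than unwraps.
- Statistics assume uniform frame cadence and identical node sets across
  replicates.

None of the numbers quoted here are empirical results beyond what the test
suite and `scripts/acceptance.R` compute.
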