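---
title: "Surface-guided diffusion mapping: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-guided diffusion mapping: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgdm)
```

## The problem

Cortical analyses of mean diffusivity (MD) sample a volumetric MD map at
the vertices of surface meshes reconstructed from a structural (T1) scan.
Two error sources corrupt the sampled values. First, diffusion-weighted
EPI volumes are geometrically distorted by field inhomogeneity, so even
after coregistration the tissue boundaries in the MD volume do not sit
exactly under the surface meshes; a vertex nominally at mid-cortical depth
may read from CSF, whose diffusivity (~3.0e-3 mm^2/s) is nearly four
times that of cortical grey matter (~0.8e-3 mm^2/s). Second, with 1.7-2 mm
voxels and a 2-4 mm cortex, every sample is a partial-volume mixture.

The package addresses both: surface-guided diffusion mapping (SGDM)
relocates the GM/CSF boundary along each cortical column before sampling,
undoing the local component of the misalignment; a two-compartment signal
model then removes the residual CSF partial-volume contamination from the
per-vertex MD.

## Surface-guided mapping

For every vertex the pipeline:

1. builds the cortical-column frame — the pial vertex is the anchor and
   the unit vector towards the linked white vertex the inward direction
   (`column_frames()`);
2. samples the MD volume trilinearly along that line, centred on the pial
   vertex (`sample_profile()`);
3. smooths the profile with a centred moving average, since the raw
   profile is stitched from voxel values and is stepwise
   (`smooth_profile()`);
4. restricts attention to a search window stretching from the WM area to
   the CSF area: the profile's local maximum nearest the centre marks the
   CSF side, and the local minimum nearest to it on the inward side marks
   the WM bound (`find_search_window()`);
5. takes the maximum of the profile's first differential inside the
   window as the relocated GM/CSF boundary (`detect_gm_csf_boundary()`);
6. samples the volume half the cortical thickness inward of that boundary
   along the column — the point that corresponds to the mid-surface
   vertex once the local shift is undone (`map_sgdm()`).

Baselines for comparison are nearest-voxel lookup (`map_nn()`) and
trilinear interpolation (`map_linear()`) at the mid-surface vertex.

### Parameters

* `spacing` (0.5 mm): profile sample step; sub-voxel for 1.7-2 mm DWI
  voxels.
* `range_in`/`range_out` (default `max(min_range, 2 * thickness[k])`,
  with `min_range` = 8 mm): profile half-extents. The window construction
  only works if the profile contains both the WM minimum and the CSF
  maximum. The WM minimum sits roughly `thickness + wm_half_width +
  |misalignment|` below the pial vertex — about 6.5-7 mm for a 3 mm
  cortex over a 3 mm gyral WM sheet displaced by 2 mm — so the floor is
  8 mm. A 6 mm floor, plausible at first sight, loses the WM minimum for
  exactly the distortions the method exists to fix and sends most
  vertices to the fallback path.
* `smooth_width` (3 samples): moving-average width.
* `sample_method` (`"linear"`): how the final value is drawn at the
  relocated point. `"nn"` restores a literal single-voxel lookup; the
  trilinear default varies smoothly with the detected shift and, on the
  aligned phantom, makes SGDM collapse exactly onto the linear baseline.
* `eps` (1e-6 mm): columns thinner than this have no direction and go to
  the fallback.

### Numerical choices

Local extrema are strict (a sample greater/smaller than both
neighbours); plateaus are skipped. Gradient-argmax ties are collected
with a relative tolerance of 1e-9 before the nearest-to-centre tie rule
is applied: a boundary read through trilinear interpolation of two voxel
layers produces an exactly linear ramp whose sampled gradients are equal
in exact arithmetic but differ by floating-point dust, and without the
tolerance the tie rule would never fire on precisely the profiles it was
designed for. Ties equidistant from the centre resolve inward. The
boundary is a discrete sample index; no sub-sample (e.g. parabolic)
refinement is applied. Missing samples inside the search window
invalidate it (conservative). Any per-vertex failure — undefined column,
too few valid samples, no window, no finite gradient, sample off the
grid — falls back to trilinear sampling at the mid vertex, tagged
`"sgdm-fallback"` with a reason code; nothing is fatal.

## CSF partial-volume correction

The observed diffusivity at a vertex mixing GM and CSF signal obeys

    exp(-b D) = lambda_app_gm exp(-b D_gm) + lambda_app_csf exp(-b D_csf)

with apparent (signal-weighted) fractions

    lambda_app_i = lambda_i S_i(0) / sum_j lambda_j S_j(0),
    S_i(0) = rho_i exp(-TE/T2_i) (1 - exp(-TR/T1_i)).

`correct_csf()` inverts the first relation in closed form for `D_gm`.
Defaults: `b` = 600 s/mm^2, TE = 60 ms, TR = 7696 ms, `D_csf` = 3.0e-3
mm^2/s. The relaxation constants enter only through the ratio of the
`S_i(0)`; the defaults (GM: rho 0.8, T1 1300 ms, T2 80 ms; CSF: rho 1.0,
T1 4000 ms, T2 2000 ms) are common 3 T literature values and every one is
overridable. Vertices with apparent GM fraction below `lambda_min` = 0.05
are flagged CSF-dominated rather than inverted — the log inversion is
ill-conditioned as the GM fraction vanishes. The model has exactly two
compartments; a supplied WM fraction should be folded into the GM
fraction (peripheral WM diffusivity is close to GM's). Tissue fractions
are projected to vertices with nearest-voxel lookup: they derive from the
undistorted structural scan, where no mapping error is being corrected.

## Tensor fit

`fit_tensor_lls()` is the plain ordinary-least-squares fit of the
log-linearised single-tensor model, with `ln S0` as the intercept of the
same system — no weighting, no positivity constraint, no eigenvalue
clamping. MD is the tensor trace over three. Mildly negative MD can occur
under noise and is passed through. Voxels with nonpositive signal are
flagged invalid instead of aborting.

## The synthetic phantom

`make_phantom()` builds a fully synthetic, ground-truth-bearing input
set. The geometry is five-layered, inward to outward: ventricular CSF
core, WM sheet (`wm_width`, 3 mm), GM shell (`thickness`, 3 mm between
white radius 30 mm and pial radius 33 mm), subarachnoid CSF shell
(`csf_width`, 4 mm) and a low-signal background (0.3e-3 mm^2/s) standing
for skull and dura. The two CSF-adjacent layers are not decoration: they
give every cortical column the genuine CSF local maximum and WM-side
local minimum that real profiles show and that the search window is
anchored to. A three-layer phantom with semi-infinite CSF produces
monotone profiles on which the window cannot form at all.

MD levels are 0.7/0.8/3.0e-3 mm^2/s for WM/GM/CSF (CSF matching the
correction's `D_csf` constant), noise is Gaussian with sd 0.05e-3 mm^2/s
(MD is a derived map, not raw signal, so Rician noise would be wrong
here), and voxels are 2 mm isotropic, matching a typical DWI acquisition.
Fractions come from 8x8x8 sub-voxel sampling of the analytic geometry;
the CSF class-probability volume equals the CSF fraction (ventricular
plus subarachnoid), mirroring a two-class (CSF vs brain) segmentation of
the b0 volume.

Misalignment is modelled as a displacement field `d(x)` under the pull
convention (`output(x) = input(x + d(x))`): a constant vector, a
uniform-amplitude radially outward field (which makes apparent content
shift inward along every column, putting CSF under the mid-surface
vertices — the canonical contamination scenario), or a seeded low-order
cosine field emulating band-limited susceptibility distortion.
`apply_distortion()` warps an existing volume, clamping out-of-grid
sample coordinates to the grid edge so shift/unshift pairs round-trip;
`make_phantom()` itself voxelises the displaced anatomy directly, so the
distorted volume carries a single voxelisation like a real distorted
acquisition rather than the double smoothing of warp-resampling.

What the phantom does **not** emulate: gyral folding and sulcal
geometry, susceptibility physics, anisotropic diffusion, surface
reconstruction error, and spatially varying noise. Passing tests on the
phantom therefore demonstrate the mapping and correction logic under
known ground truth, not performance on clinical data.

## Evaluation tools

`project_csf_probability()` applies any of the three mapping methods to a
CSF class-probability volume; probability leaking onto the surface
measures residual mapping error. `smooth_surface_data()` smooths
per-vertex data by iterated graph-Laplacian diffusion with symmetric
uniform edge weights — every step conserves the mean exactly — with the
step count first budgeted from the flat-space variance increment and
then calibrated on a probe impulse so the realised kernel matches the
requested FWHM; the probe correction absorbs what mesh curvature and
irregularity take away from the flat-space estimate. On geodesic
icospheres the kernel at the twelve degree-5 pole vertices is genuinely
narrower than at regular vertices; per-vertex kernel width on any
irregular mesh varies with local mesh density. `paired_vertexwise_t()`
computes vertex-wise paired Student's t with two-sided p-values;
multiple comparisons are handled by Benjamini-Hochberg FDR, a deliberate
substitution for the random-field-theory correction used in the
surface-statistics literature (RFT is out of scope here). An exactly
constant nonzero difference yields `t = +-Inf`, `p = 0`, flagged
degenerate.

## Validation design and problem sizes

The package validates itself on desk-scale problems: icosphere
subdivision 3 (642 vertices) on a 45^3 grid of 2 mm voxels for the
phantom studies, 1000 random profiles for the detector-oracle
equivalence, 13 displaced-step fixtures at 0.5 mm spacing, and 1000
vertices x 10 subjects for the null calibration of the paired t. The
displaced-step sweep is run noise-free on the logistic (`smoothed_step`)
fixture: it checks the detector's localisation logic; noise robustness is
exercised by the phantom studies, which carry the full noise model.

## Known limitations

* **Boundary quantisation.** The detected boundary is a discrete sample
  index. Reading a 2 mm-voxel volume trilinearly along oblique rays
  biases the gradient argmax by up to about a quarter voxel either way,
  so on the aligned spherical phantom the boundary lands exactly at the
  profile centre at only ~69% of vertices — with or without noise — while
  landing within one 0.5 mm sample at 100% of them. Wider profile
  smoothing does not remove this (it is ray/grid geometry, not noise),
  and sub-sample refinement is deliberately out of scope. The downstream
  effect is bounded by one sample of position error, which stays well
  inside the GM band.
* **Mid-cortical partial volume.** Even a perfectly relocated sample at
  mid-cortical depth of a 3 mm cortex on a 2 mm grid is a mixture; the
  trilinear support touches CSF and biases the value upward by roughly
  +0.17e-3 mm^2/s on the phantom. This is precisely the contamination
  the two-compartment correction removes; the mapping step alone cannot.
* **Window capture under noise for outward shifts.** When the true
  boundary is displaced outward, the profile centre sits in the GM
  plateau, and spurious noise-induced local maxima near the centre can
  capture the window before the true CSF peak does. Inward shifts (the
  common contamination direction) do not suffer from this. A smoothing
  width matched to the noise correlation length mitigates it.
* **Uniform-shift method ordering.** Under a spatially uniform inward
  content shift the mid vertices all sit just outside the apparent
  boundary on the convex toe of the smeared GM-to-CSF ramp, where
  trilinear interpolation reads systematically slightly higher than
  nearest-voxel lookup (~3% here). Reports from heterogeneous real
  misalignment show the opposite ordering of the two baselines; neither
  ordering affects the headline result, which is that SGDM sits far
  below both.
* Vertex correspondence across surfaces is by index and is trusted, not
  recomputed; SGDM inherits any error in the surface reconstruction
  itself.
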