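# sgdm — surface-guided mapping of diffusion MRI onto the cortex

`sgdm` projects mean-diffusivity (MD) volumes onto cortical surface
meshes for vertex-wise analysis of cortical grey matter. It is written
for researchers who combine diffusion MRI with surface-based morphometry
and who face the two classic failure modes of that combination: EPI
geometric distortion misplaces the tissue boundaries of the MD volume
relative to the structural-space surfaces, and CSF — with a diffusivity
of about 3.0 × 10⁻³ mm²/s against ~0.8 × 10⁻³ mm²/s in cortex — inflates
any sample taken too close to the pial boundary.

## What it computes

**Surface-guided diffusion mapping (SGDM).** For each vertex *k* with
pial position **p**ₖ and linked white-surface position **w**ₖ, the MD
volume is sampled along the cortical-column line through **p**ₖ, giving a
profile centred on the pial vertex. After moving-average smoothing, a
search window is set from the profile's local minimum in the WM to its
local maximum in the CSF, and the relocated GM/CSF boundary is the
argmax of the profile's first differential within that window. The value
assigned to the mid-surface vertex is sampled half the t-link thickness
Tₖ = ‖**p**ₖ − **w**ₖ‖ inward of the detected boundary. Nearest-neighbour
and trilinear sampling at the mid vertex are provided as baselines.

**Two-compartment CSF correction.** The observed per-vertex diffusivity
D(k) is modelled as

exp(−b·D) = λ̃_gm·exp(−b·D_gm) + λ̃_csf·exp(−b·D_csf),
λ̃ᵢ = λᵢSᵢ(0) / Σⱼ λⱼSⱼ(0),
Sᵢ(0) = ρᵢ·exp(−TE/T2ᵢ)·(1 − exp(−TR/T1ᵢ)),

and inverted in closed form for the CSF-free cortical diffusivity D_gm
(defaults b = 600 s/mm², TE = 60 ms, TR = 7696 ms, D_csf = 3.0 × 10⁻³
mm²/s).

Around this core the package provides a log-linear least-squares tensor
fit (DWI + FSL bval/bvec → MD volume), linked-surface utilities (t-link
thickness, midsurface, column frames), NIfTI/GIFTI/OBJ/CSV IO, vertex-wise
paired t statistics with FWHM-calibrated surface smoothing, and a fully
synthetic five-layer phantom (ventricle/WM/GM/CSF/background) with known
ground truth and a controllable EPI-like misalignment field, which powers
the entire test suite — no clinical data are required.

## Worked example

A spherical phantom (white/pial radii 30/33 mm, 2 mm voxels, noise sd
0.05 × 10⁻³) whose MD volume is displaced 2 mm outward, as EPI distortion
would:

```r
library(sgdm)

spec <- phantom_spec(seed = 42,
                     distortion = list(type = "radial", amplitude = 2))
phantom <- make_phantom(spec)

md_sgdm   <- map_sgdm(phantom$md, phantom$surfaces)
md_nn     <- map_nn(phantom$md, phantom$surfaces$mid)
md_linear <- map_linear(phantom$md, phantom$surfaces$mid)

lam_gm  <- map_nn(phantom$fractions$gm, phantom$surfaces$mid)$value +
           map_nn(phantom$fractions$wm, phantom$surfaces$mid)$value
lam_csf <- map_nn(phantom$fractions$csf, phantom$surfaces$mid)$value
pars    <- two_compartment_params()
app     <- apparent_fractions(lam_gm, lam_csf, pars)
d_gm    <- correct_csf(md_sgdm, app$lambda_app_gm, app$lambda_app_csf, pars)
```

Output of the accompanying summary lines:

```
true GM MD: 0.80e-3 mm^2/s
mean MD   NN: 2.24e-3  Linear: 2.31e-3  SGDM: 0.98e-3
median detected boundary shift: -2.0 mm (true: -2.0)
after CSF correction: mean D_gm = 0.87e-3 mm^2/s (642 of 642 vertices valid)
```

The baselines read CSF-level diffusivity at almost every mid-surface
vertex (2.2–2.3 × 10⁻³ against a truth of 0.8 × 10⁻³), because the
apparent tissue content has moved 2 mm inward under them. SGDM detects
that shift per vertex (median −2.0 mm), samples on the corrected side of
the boundary and lands at 0.98 × 10⁻³; the two-compartment correction
then removes most of the remaining partial-volume contamination
(0.87 × 10⁻³).

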