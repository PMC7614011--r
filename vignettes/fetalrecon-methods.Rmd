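---
title: "Methods: automated reorientation and rigid SVR reconstruction of the fetal thorax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated reorientation and rigid SVR reconstruction of the fetal thorax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and the numerical and design choices
behind `fetalrecon`. The README shows the user-facing workflow; here we
explain what each stage assumes, which parameters matter, and what the
synthetic experiments do and do not demonstrate.

## The reconstruction problem

A fetal MRI examination produces several multi-slice stacks. Individual
slices are sharp (single-shot acquisition), but the fetus moves between
slices and between stacks, so the stacks disagree with each other and with
themselves. Reconstruction means finding a rigid pose per stack (and
ultimately per slice) into a common standard ("atlas") frame and solving a
super-resolution inverse problem that fuses the anisotropic slices into one
isotropic volume. The pipeline's core difficulty is initialisation: a local
intensity-based rigid registration has a capture range of a few tens of
degrees, while early-gestation fetuses rotate by far more than that between
stacks.

## Geometry conventions

All volumes are a voxel array plus a 4×4 voxel-to-world affine in mm (RAS+,
0-based voxel indices, as in NIfTI headers). Rigid transforms are proper
rotations plus translations acting on world coordinates; a simulated pose
maps atlas world to scanner world, and every estimated transform maps a
stack's current world frame to the atlas, so a perfect estimate composed
with the true pose is the identity. Reorientation updates only the header
affine; voxel data are never resampled until reconstruction.

## The digital phantom and the acquisition simulator

The phantom is a set of ellipsoids (uterus shell and fluid, trunk, thorax,
abdomen, heart, liver, brain) plus 2–4 tubular "vessels" inside the thorax,
with per-tissue intensities, a smooth seeded multiplicative texture (4% by
default) and a small Gaussian band-limiting blur (0.6 voxel). Geometry
scales with the field of view, so a 160³ grid at 0.7 mm and a 64³ grid at
1.75 mm describe the same anatomy. The trunk is centred on the world
origin, so simulated rotations about the trunk centroid are rotations about
zero, and heart/liver are laterally offset so the four landmark centroids
are never close to collinear. Containment (heart ⊂ thorax, liver ⊂ abdomen,
thorax ∪ abdomen ⊂ trunk, everything ⊂ uterus) is validated by surface
sampling at construction; violations are specification errors.

The simulator samples the phantom on an anisotropic stack grid along a
chosen scanner axis after applying the pose. Defaults follow a single-shot
TSE fetal protocol: 1.25 mm in-plane, 2.5 mm slice thickness, 1.25 mm slice
spacing (a negative gap), interleaved ordering in 4 packages (so slices of
one package are 5 mm apart). The through-plane slice profile is a Gaussian
with FWHM equal to the slice thickness, integrated with a 5-point
quadrature over ±2σ; the acquisition literature does not pin the profile
down, and the Gaussian is the standard SVR convention. Optional per-slice
rigid jitter (uniform in ±max rotation/translation), a smooth quadratic
multiplicative bias field and additive Gaussian noise model motion
corruption and acquisition artifacts. Everything is seeded: identical
(spec, seed) pairs give bit-identical arrays.

What the simulator does **not** model: MR physics (no T2 decay, no k-space,
no ghosting), maternal breathing, non-rigid fetal motion (bending,
stretching), inter-subject anatomical variability, and realistic tissue
texture. Consequently, passing phantom tests demonstrates the geometric and
statistical machinery — pose recovery, capture-range extension, robust
rejection, orderings across pipeline variants — but not clinical-grade
image quality, and the printed clinical numbers of the motivating study
(Dice against expert masks, cohort slice-rejection percentages) are not
reproducible here and are not targeted.

## Localisation (Step I)

The oracle backend derives the 4-class map from the simulator's ground
truth by nearest-neighbour sampling under the stack's mean pose; per-slice
jitter therefore remains as a realistic segmentation imperfection. The CNN
backend records the reference 3D UNet configuration (5 levels with
32/64/128/256/512 channels, instance normalisation, LeakyReLU, average
pooling for the first two down-samplings then max pooling, generalised Dice
loss, Adam at learning rate 0.002 with batch size 2, 128³ input grid) but
is optional and, without trained weights, raises an explicit "untrained
backend" error; no deep-learning runtime is required by any tested path.

Design choices where the method description is silent: connected components
use 26-connectivity; size ties are broken by the lexicographically smallest
bounding-box origin (deterministic); the trunk crop margin defaults to
15 mm. `resample_to_grid()` pads to a cube at isotropic spacing (largest
extent divided by the grid) rather than stretching, so aspect ratio and
world geometry are preserved.

## Landmark pose (Step II)

Landmarks are unweighted voxel-centre centroids of the thorax, abdomen,
heart and liver masks, with heart and liver voxels removed from thorax and
abdomen *before* the centroid (the behaviour required when separate
segmentation networks produce overlapping labels). Intensity weighting was
rejected: the landmarks are defined by the labels, not by image contrast.
An empty organ label is a hard "landmark missing" error — a silent 3-point
registration would be ill-conditioned and misleading.

`point_register()` is the closed-form least-squares rigid fit: centroid
alignment plus SVD rotation with reflection correction, no scaling.
Configurations whose centred source matrix has a second singular value
below 1e−8 of the largest are rejected as collinear. The atlas reference is
a configurable input (JSON of four named points); for phantom work it is
the landmark set of the untransformed phantom.

## Stack selection (Step III)

NCC is the Pearson correlation over a region, by default the voxels where
both images are non-zero; regions with fewer than 2 voxels or zero variance
score 0 by convention, so blank slices count as maximally dissimilar
instead of crashing. `Csim` includes the self term (the literal mean over
all stacks, so a single stack scores 1); since the self term shifts every
stack equally it cannot change any inclusion decision, and the choice is
documented rather than consequential. `Ccor` is computed on the cropped
trunk ROI slices over their non-zero overlap. Inclusion uses strict
inequalities exactly as printed (fractions 0.5, 0.5 and the 40% volume
bound are configurable); boundary cases (a metric exactly at its threshold)
are excluded. The "average" mask is the voxelwise mean of the binary masks
thresholded at 0.5 — the majority vote, which is the median of binary
values. The template grid is isotropic at the finest in-plane spacing among
the included stacks, in atlas axes.

Pairwise refinement registers each stack to the least motion-corrupted
stack over the thorax region, initialised by the landmark transforms. A
refinement is accepted only if its similarity does not decrease and ends
at ≥ 0.2; otherwise the landmark-only transform is kept and the stack is
flagged. At phantom scale a residual of up to ~1° remains between stacks
sliced along different axes: their anisotropic slice-profile blurs shift
the NCC optimum slightly, an effect that more iterations cannot remove and
that is far inside the 5° pipeline tolerance.

## Rigid registration engine

Masked NCC is maximised over the 6 rigid parameters by regular-step
gradient ascent (central differences, step halving on failure) over a
coarse-to-fine pyramid (default factors 4, 2, 1 by block-averaging).
Rotations are parameterised so one step unit moves a point at the ROI
radius by about 1 mm, balancing the search directions. Defaults: 30/20/10
iterations per level, initial steps 8/4/2 mm, convergence when the step
falls below 0.05 mm, gradient delta 0.5 mm. The optimiser is deterministic,
and accepted steps never decrease the similarity. Its capture range on the
phantom is a few tens of degrees: with identity initialisation it recovers
30° offsets to ~1° but fails beyond ~90°, while initialisation with the
landmark pose makes the whole 0–180° range convergent — the property the
rotation sweep experiment quantifies.

## Rigid SVR super-resolution (Step IV)

The acquisition model is PSF-weighted integration: a slice pixel is the
Gaussian-weighted integral of the volume along the slice normal (FWHM =
slice thickness) and, optionally, in-plane (FWHM = in-plane spacing). The
quadrature is separable with a configurable number of points per axis
(default 1×1×5: at the default output resolution the in-plane FWHM is at
the grid scale, so its single-point quadrature treats it as a delta; set
`psf_samples = c(3, 3, 5)` to integrate it). Each outer iteration (default
3) performs:

1. per-slice rigid registration to the current volume (from the second
   outer iteration, once the volume is sharper than the template), a few
   gradient steps on slice NCC over the in-mask pixels;
2. robust slice weighting: the residual score of a slice is 1 − NCC between
   its acquired pixels and the projected volume over the pixels well inside
   the reconstruction mask (projected mask fraction > 0.85, at least 64
   pixels, in-mask contrast at least 10% of the global intensity scale —
   slices failing these carry no usable information and are reported as
   non-evaluable rather than excluded). An EM fit of a Gaussian-inlier +
   uniform-outlier mixture on these scores gives posterior inlier weights;
   the uniform component spans the full score support [0, 2], the inlier
   component is initialised on the lowest decile so that it locks onto the
   best-fitting subpopulation even when most slices are misregistered, and
   its width is kept in [0.005, 0.08] — a prior encoding that slices
   consistent with the volume agree within a narrow NCC band. Slices with
   weight below 0.5 count as excluded.
3. a super-resolution update: mass-normalised backprojection of the
   weighted residuals (the adjoint of the PSF projection) minus a Huber
   edge-preserving smoothness gradient (weight `lambda`, threshold 10% of
   the intensity scale), with step backtracking so the weighted objective
   decreases monotonically within the iteration; intensities are clamped
   non-negative and the volume is masked to the thorax mask dilated by
   5 mm.

All thresholds in the robust weighting are relative (NCC-based scores,
scale-relative contrast), so the whole reconstruction is homogeneous of
degree one: scaling every input by a > 0 scales the output by a and changes
no inclusion decision.

## The two experiments

**Rotation capture range.** One stack is acquired at identity pose and used
as the template; for each angle in {0, 15, 30, 45, 60, 75, 90, 105, 120,
180}°, stacks rotated about the trunk centroid are registered back under
three scenarios: classical (intensity registration from identity),
landmark-only, and combined (intensity registration initialised by the
landmark pose). Six stacks per angle are ±θ about each of x, y, z; applying
±θ to all three axes simultaneously was rejected because three 180°
rotations compose to the identity, which would make the hardest angle
trivially easy. The masked-thorax NCC and pose error are recorded per
registration. Expected behaviour, asserted by the acceptance tests:
classical NCC collapses for θ ≥ 90° (to ~0.46 against ~0.99 when
converged), the landmark curve is flat (coefficient of variation across
angles far below 5%), and the combined method dominates everywhere with
sub-degree mean pose error.

**Pipeline ablation.** Three datasets of six stacks each are simulated with
inter-stack rotations of 95–150° and ±10 mm translations; the last two
stacks of each dataset additionally carry heavy per-slice jitter (12°,
6 mm) and noise (σ = 40), emulating severely corrupted acquisitions; each
stack is split into its 4 interleaved packages before processing. Three
scenarios are reconstructed: localisation only (I+IV), plus landmark
reorientation (I+II+IV), plus selection and median template (full). In the
non-selection scenarios the template is the least motion-corrupted stack by
`Ccor`, per the automated fallback. Across the scenarios the percentage of
excluded slices decreases strictly and the mean simulated-vs-acquired slice
NCC increases strictly (at seed 1: 86.5% → 38.1% → 2.6% excluded and 0.40 →
0.73 → 0.99 NCC); a held-out stack in the template position is also scored.
These orderings — not the magnitudes, which depend on anatomy and protocol
— are the reproducible content.

## Problem sizes

The test suite and the acceptance script use a 64³ phantom at 1.75 mm
(the same 112 mm field of view as the 160³/0.7 mm default), 2 mm in-plane /
3–4 mm slices, 3 rotated stacks per sweep angle, 3 ablation datasets, and
1.2–1.4 mm reconstruction grids; these sizes were chosen so the entire
suite completes in minutes on a single core while every asserted property
remains comfortably away from its threshold. All experiment functions take
the full-size parameters if wanted.

## Known limitations

* Motion within a slice, non-rigid motion and intensity artifacts beyond a
  smooth bias field are out of scope; the reconstruction backend is rigid,
  and deformable slice-to-volume registration would replace Step IV for
  strongly non-rigid cases.
* The CNN segmentation backend is configuration-only; all tested paths use
  the oracle backend, so segmentation robustness on clinical data is not
  evaluated here.
* Singleton pregnancy is assumed, not detected.
* The EM inlier-width prior (0.005–0.08 in 1 − NCC units) is calibrated for
  structured anatomy; for nearly featureless images the NCC-based score
  loses discrimination, which is why low-contrast slices are marked
  non-evaluable instead of scored.
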