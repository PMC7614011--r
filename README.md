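# fetalrecon

Automated atlas-space reorientation and rigid slice-to-volume reconstruction
of fetal thorax MRI.

## The problem

Fetal cardiac MRI is acquired as multiple fast 2D multi-slice stacks. Each
slice freezes motion, but the fetus moves between slices and between stacks,
so no single stack is a usable 3D volume. Slice-to-volume registration (SVR)
pipelines recover a high-resolution 3D volume by registering individual
slices to an evolving reconstruction and fusing them by super-resolution —
but the classical gradient-descent rigid registration they rely on has a
narrow capture range and fails for the large rotations that are common at
early gestational ages, and conventional pipelines need an operator to pick
masks and a template stack.

`fetalrecon` implements a fully automated pipeline:

* **Step I — localisation.** A mutually exclusive 4-class segmentation
  (background / uterus / brain / trunk) localises the fetal trunk in every
  stack, keeps the largest 26-connected component and crops each stack to
  the trunk region. Stacks without a trunk (e.g. brain-only coverage) are
  dropped with a logged reason.
* **Step II — landmark pose estimation.** The centroids of four organ
  regions (thorax, abdomen, heart, liver; heart and liver subtracted from
  their containers before the centroid) form a landmark set that is rigidly
  registered to the corresponding atlas landmarks by closed-form least
  squares (Procrustes/Kabsch). The resulting pose is applied directly to the
  NIfTI header — a pure reorientation, no resampling. Unlike intensity
  registration, the landmark pose is rotation invariant: it works equally
  well at 0° and 180° of fetal rotation.
* **Step III — stack selection and template generation.** Pairwise rigid
  refinement of the reoriented stacks, then three per-stack metrics:

  * motion corruption `Ccor(i)` = mean NCC of sequential 2D slices,
  * mutual similarity `Csim(i)` = mean 3D NCC against all stacks,
  * volume deviation `Cvol(i) = |V_i − median(V)| / median(V)`,

  with inclusion iff `Ccor(i) > 0.5·max Ccor`, `Csim(i) > 0.5·max Csim` and
  `Cvol(i) < 0.40` (strict inequalities). The reference stack maximises
  `Ccor·Csim`; the template is the voxelwise median of the included,
  reoriented stacks and the thorax mask their majority vote.
* **Step IV — reconstruction.** A rigid slice-to-volume super-resolution
  backend: per-slice rigid registration to the evolving volume, robust slice
  weights from an EM fit of a Gaussian-inlier + uniform-outlier mixture on
  per-slice residuals, and a monotone super-resolution update of the
  PSF-projection least squares with Huber edge-preserving smoothness, on an
  isotropic (default 0.7 mm) grid in atlas space.

Because clinical data cannot ship with a package, `fetalrecon` includes a
deterministic **digital fetal-trunk phantom** (ellipsoidal uterus, trunk,
thorax, abdomen, heart, liver, brain plus tubular vessels) and a **stack
acquisition simulator** (anisotropic slices with a Gaussian slice profile,
interleaved packages, per-slice motion jitter, bias field, noise). Every
stage of the pipeline — and the two headline experiments, the rotation
capture-range sweep and the pipeline ablation — runs end-to-end on
simulations with known ground truth.

## Worked example

```r
library(fetalrecon)

# digital phantom: ground truth volume + organ labels (desk-scale grid)
ph <- make_phantom(phantom_spec(grid_size = 64, voxel_mm = 1.75))

# six motion-corrupted acquisitions: random rotations up to 120 degrees
# and translations up to 20 mm, in alternating slice orientations
acq <- acquisition_spec(in_plane_mm = 2, slice_thickness_mm = 3,
                        slice_spacing_mm = 1.5, slice_order = "ascending")
set.seed(11)
stacks <- lapply(1:6, function(s) {
  axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
  pose <- rt_about_center(rotation_about_axis(axis, runif(1, 0, 120)),
                          runif(3, -20, 20), ph$trunk_centroid)
  simulate_stack(ph, pose, acq, seed = s, slice_axis = ((s - 1) %% 3) + 1)
})

cfg <- pipeline_config(recon = recon_config(output_resolution_mm = 1.2,
                                            n_outer = 2, sr_iter = 8))
bundle <- run_pipeline(stacks, cfg)
bundle
#> <fetal_recon> 6 stacks processed, 6 included, reference 2
#>   output 42 x 35 x 33 voxels at 1.2 mm; 0.0% slices excluded
glance(bundle)
#> # A tibble: 1 × 5
#>   n_stacks n_included reference pct_excluded_slices mean_slice_ncc
#>      <int>      <int>     <int>               <dbl>          <dbl>
#> 1        6          6         2                   0          0.998
pipeline_pose_errors(bundle)
#> # A tibble: 6 × 4
#>   stack rot_err_deg trans_err_mm included
#>   <int>       <dbl>        <dbl> <lgl>
#> 1     1       2.11        0.0477 TRUE
#> 2     2       2.29        0.0619 TRUE
#> 3     3       0.798       0.109  TRUE
#> 4     4       2.17        0.0542 TRUE
#> 5     5       1.89        0.119  TRUE
#> 6     6       2.06        0.0551 TRUE
```

All six stacks — rotated by up to 120° — are reoriented to the atlas within
about 2° and 0.12 mm, every slice is retained by the robust weighting, and
the per-slice NCC between the reconstruction's simulated slices and the
acquired slices is 0.998. `tidy(bundle)` returns the per-stack
`Ccor`/`Csim`/`Cvol` selection table, `autoplot()` methods plot sweep,
ablation and slice-weight results, and `write_volume()` writes any volume
as NIfTI-1. A command-line wrapper with `simulate`, `run`, `sweep` and
`ablation` subcommands is installed at `inst/cli/fetalrecon.R`.

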