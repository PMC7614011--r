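#' Specification of the digital fetal-trunk phantom
#'
#' Defines a deterministic phantom: an intensity volume plus global
#' (background/uterus/brain/trunk) and organ (thorax/abdomen/heart/liver)
#' label maps built from ellipsoids, with tubular "vessel" structures inside
#' the thorax that give the super-resolution stage fine structure to recover.
#' All geometry is stored in world mm; defaults scale with the field of view
#' `grid_size * voxel_mm`. The trunk is centred on the world origin, so
#' simulated rotations about the trunk centroid are rotations about 0.
#'
#' @param grid_size voxels per axis (isotropic grid).
#' @param voxel_mm isotropic voxel spacing in mm.
#' @param seed integer seed for the (deterministic) intensity texture.
#' @param texture_amp amplitude of the smooth multiplicative intra-tissue
#'   texture (fraction of tissue intensity).
#' @param smooth_vox Gaussian smoothing of the final intensity volume, in
#'   voxels (band-limits the piecewise-constant geometry).
#' @param organs optional named list overriding organ geometry; each entry is
#'   `list(center = mm triple, semi = mm triple)` for `trunk`, `thorax`,
#'   `abdomen`, `heart`, `liver`, `brain`, `uterus`.
#' @param intensities optional named numeric vector of tissue intensities.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 160L, voxel_mm = 0.7, seed = 1L,
                         texture_amp = 0.04, smooth_vox = 0.6,
                         organs = NULL, intensities = NULL) {
  if (grid_size < 16) abort("grid_size must be >= 16")
  u <- grid_size * voxel_mm / 2   # half field of view, mm
  geom <- list(
    uterus  = list(center = c(0, 0, 0) * u,            semi = c(0.95, 0.90, 0.95) * u),
    trunk   = list(center = c(0, 0, 0) * u,            semi = c(0.42, 0.36, 0.55) * u),
    thorax  = list(center = c(0, 0, 0.22) * u,         semi = c(0.30, 0.26, 0.21) * u),
    abdomen = list(center = c(0, 0, -0.22) * u,        semi = c(0.30, 0.26, 0.21) * u),
    heart   = list(center = c(0.09, 0.06, 0.20) * u,   semi = c(0.11, 0.10, 0.09) * u),
    liver   = list(center = c(-0.10, 0.05, -0.20) * u, semi = c(0.12, 0.11, 0.09) * u),
    brain   = list(center = c(0, 0.02, 0.78) * u,      semi = c(0.12, 0.12, 0.12) * u)
  )
  if (!is.null(organs)) geom[names(organs)] <- organs
  vessels <- list(
    list(p = c(-0.07, -0.06, 0.22) * u, d = c(0, 0, 1),               r = 0.030 * u),
    list(p = c(0.00, -0.12, 0.21) * u,  d = c(0, 0, 1),               r = 0.025 * u),
    list(p = c(0.02, 0.10, 0.22) * u,   d = c(0.4, 0.3, 1) / sqrt(1.25), r = 0.022 * u)
  )
  inten <- c(background = 0, shell = 60, fluid = 130, trunk = 95,
             thorax = 70, abdomen = 100, heart = 150, liver = 115,
             brain = 120, vessel = 190)
  if (!is.null(intensities)) inten[names(intensities)] <- intensities
  spec <- structure(list(
    grid_size = as.integer(grid_size), voxel_mm = voxel_mm,
    seed = as.integer(seed), texture_amp = texture_amp,
    smooth_vox = smooth_vox, geom = geom, vessels = vessels,
    intensities = inten, shell_frac = 0.06
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# surface-sampling containment check: every point on the surface of `inner`
# must satisfy the implicit equation of `outer` (<= 1)
ellipsoid_inside <- function(inner, outer, n = 24L) {
  th <- seq(0, pi, length.out = n)
  ph <- seq(0, 2 * pi, length.out = 2 * n)
  g <- expand.grid(th = th, ph = ph)
  pts <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  surf <- sweep(sweep(pts, 2, inner$semi, "*"), 2, inner$center, "+")
  q <- sweep(sweep(surf, 2, outer$center, "-"), 2, outer$semi, "/")
  all(rowSums(q^2) <= 1 + 1e-9)
}

validate_phantom_spec <- function(spec) {
  g <- spec$geom
  checks <- list(
    c("heart", "thorax"), c("liver", "abdomen"),
    c("thorax", "trunk"), c("abdomen", "trunk"),
    c("trunk", "uterus"), c("brain", "uterus")
  )
  for (p in checks) {
    if (!ellipsoid_inside(g[[p[1]]], g[[p[2]]])) {
      abort(sprintf("phantom geometry violates containment: %s not inside %s",
                    p[1], p[2]),
            class = "fetalrecon_spec_error")
    }
  }
  # brain must not intersect the trunk (landmark configuration sanity)
  bt <- sum(((g$brain$center - g$trunk$center) /
               (g$brain$semi + g$trunk$semi))^2)
  if (bt <= 1) {
    abort("phantom geometry: brain overlaps trunk",
          class = "fetalrecon_spec_error")
  }
  invisible(spec)
}

# logical vector: world points inside an ellipsoid
inside_ellipsoid <- function(X, Y, Z, e) {
  ((X - e$center[1]) / e$semi[1])^2 +
    ((Y - e$center[2]) / e$semi[2])^2 +
    ((Z - e$center[3]) / e$semi[3])^2 <= 1
}

inside_tube <- function(X, Y, Z, v) {
  dx <- X - v$p[1]; dy <- Y - v$p[2]; dz <- Z - v$p[3]
  proj <- dx * v$d[1] + dy * v$d[2] + dz * v$d[3]
  r2 <- (dx - proj * v$d[1])^2 + (dy - proj * v$d[2])^2 + (dz - proj * v$d[3])^2
  r2 <= v$r^2
}

#' Generate the digital fetal-trunk phantom
#'
#' Builds the ground-truth high-resolution intensity volume, the global
#' 4-class label map (background/uterus/brain/trunk) and the organ label map
#' (thorax/abdomen/heart/liver, mutually exclusive with heart and liver taking
#' precedence over the containing regions). Identical specs produce
#' bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `fetal_phantom`: a list with elements
#'   `intensity` ([image_volume()]), `global_labels`, `organ_labels`
#'   ([label_map()]s), `landmarks` (organ mask centroids, world mm),
#'   `trunk_centroid`, and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  n <- spec$grid_size
  v <- spec$voxel_mm
  A <- diag(c(v, v, v, 1))
  A[1:3, 4] <- -v * (n - 1) / 2
  coord <- (seq_len(n) - 1) * v - v * (n - 1) / 2
  X <- array(rep(coord, times = n * n), c(n, n, n))
  Y <- array(rep(rep(coord, each = n), times = n), c(n, n, n))
  Z <- array(rep(coord, each = n * n), c(n, n, n))
  g <- spec$geom

  ut_out <- inside_ellipsoid(X, Y, Z, g$uterus)
  inner <- g$uterus
  inner$semi <- inner$semi * (1 - spec$shell_frac)
  ut_in <- inside_ellipsoid(X, Y, Z, inner)
  trunk <- inside_ellipsoid(X, Y, Z, g$trunk)
  brain <- inside_ellipsoid(X, Y, Z, g$brain)
  thorax <- inside_ellipsoid(X, Y, Z, g$thorax) & trunk
  abdomen <- inside_ellipsoid(X, Y, Z, g$abdomen) & trunk & !thorax
  heart <- inside_ellipsoid(X, Y, Z, g$heart) & thorax
  liver <- inside_ellipsoid(X, Y, Z, g$liver) & abdomen
  vessel <- array(FALSE, dim(X))
  for (tube in spec$vessels) vessel <- vessel | inside_tube(X, Y, Z, tube)
  vessel <- vessel & thorax & !heart

  ints <- spec$intensities
  img <- array(0, c(n, n, n))
  img[ut_out] <- ints[["shell"]]
  img[ut_in] <- ints[["fluid"]]
  img[trunk] <- ints[["trunk"]]
  img[thorax] <- ints[["thorax"]]
  img[abdomen] <- ints[["abdomen"]]
  img[heart] <- ints[["heart"]]
  img[liver] <- ints[["liver"]]
  img[vessel] <- ints[["vessel"]]
  img[brain] <- ints[["brain"]]

  if (spec$texture_amp > 0) {
    # smooth deterministic texture: coarse seeded noise, upsampled by smoothing
    set.seed(spec$seed)
    tex <- array(stats::rnorm(n^3), c(n, n, n))
    tex <- c_separable_conv(tex, c(n, n, n), tex_kernel())
    tex <- tex / stats::sd(tex)
    img <- img * (1 + spec$texture_amp * tex)
  }
  vol <- image_volume(img, A)
  if (spec$smooth_vox > 0) vol <- smooth_volume(vol, spec$smooth_vox)

  glab <- array(0L, c(n, n, n))
  glab[ut_out | ut_in] <- 1L
  glab[brain] <- 2L
  glab[trunk] <- 3L
  global_labels <- label_map(glab, A, c(uterus = 1L, brain = 2L, trunk = 3L))

  olab <- array(0L, c(n, n, n))
  olab[thorax] <- 1L
  olab[abdomen] <- 2L
  olab[heart] <- 3L
  olab[liver] <- 4L
  organ_labels <- label_map(olab, A, c(thorax = 1L, abdomen = 2L,
                                       heart = 3L, liver = 4L))

  structure(list(
    intensity = vol,
    global_labels = global_labels,
    organ_labels = organ_labels,
    landmarks = extract_landmarks(organ_labels),
    trunk_centroid = mask_centroid(label_mask(global_labels, "trunk")),
    spec = spec
  ), class = "fetal_phantom")
}

tex_kernel <- function() {
  k <- stats::dnorm(seq(-6, 6), sd = 2.5)
  k / sum(k)
}

#' @export
print.fetal_phantom <- function(x, ...) {
  cat(sprintf("<fetal_phantom> %d^3 voxels at %.3g mm\n",
              x$spec$grid_size, x$spec$voxel_mm))
  invisible(x)
}

#' Acquisition parameters for simulated stacks
#'
#' Mirrors a single-shot TSE fetal protocol: anisotropic slices with a
#' through-plane Gaussian slice profile, interleaved slice order split into
#' acquisition packages, and optional per-slice motion jitter, smooth bias
#' field and Gaussian noise. A negative gap (slice spacing below slice
#' thickness) is permitted and increases through-plane oversampling.
#'
#' @param in_plane_mm in-plane pixel spacing, mm.
#' @param slice_thickness_mm slice thickness (Gaussian profile FWHM), mm.
#' @param slice_spacing_mm distance between consecutive slice centres, mm.
#' @param n_packages number of interleaved acquisition packages (>= 1).
#' @param package_spacing_mm within-package slice spacing; by convention
#'   `n_packages * slice_spacing_mm`.
#' @param slice_order `"interleaved"` or `"ascending"`.
#' @param noise_sigma additive Gaussian noise standard deviation (intensity
#'   units).
#' @param bias_amplitude amplitude of the smooth multiplicative polynomial
#'   bias field (fraction; 0 disables).
#' @param jitter_rot_deg maximum per-slice rotation jitter, degrees.
#' @param jitter_trans_mm maximum per-slice translation jitter, mm.
#' @return an object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(in_plane_mm = 1.25, slice_thickness_mm = 2.5,
                             slice_spacing_mm = 1.25, n_packages = 4L,
                             package_spacing_mm = n_packages * slice_spacing_mm,
                             slice_order = c("interleaved", "ascending"),
                             noise_sigma = 0, bias_amplitude = 0,
                             jitter_rot_deg = 0, jitter_trans_mm = 0) {
  slice_order <- match.arg(slice_order)
  if (n_packages < 1L) abort("n_packages must be >= 1")
  if (in_plane_mm <= 0 || slice_thickness_mm <= 0 || slice_spacing_mm <= 0) {
    abort("spacings must be positive")
  }
  structure(list(
    in_plane_mm = in_plane_mm, slice_thickness_mm = slice_thickness_mm,
    slice_spacing_mm = slice_spacing_mm, n_packages = as.integer(n_packages),
    package_spacing_mm = package_spacing_mm, slice_order = slice_order,
    noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
    jitter_rot_deg = jitter_rot_deg, jitter_trans_mm = jitter_trans_mm
  ), class = "acquisition_spec")
}

new_stack <- function(data, affine, thickness, spacing, packages,
                      truth = NULL) {
  v <- image_volume(data, affine)
  v$slice_thickness_mm <- thickness
  v$slice_spacing_mm <- spacing
  v$packages <- as.integer(packages)
  class(v) <- c("stack", class(v))
  attr(v, "truth") <- truth
  v
}

stack_truth <- function(stack) attr(stack, "truth")

# Gaussian slice-profile quadrature: offsets (mm along the slice normal) and
# weights for FWHM = slice thickness
psf_quadrature <- function(fwhm_mm, k = 5L) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  off <- sigma * seq(-2, 2, length.out = k)
  w <- stats::dnorm(off, sd = sigma)
  list(offsets = off, weights = w / sum(w))
}

#' Simulate a motion-corrupted anisotropic stack acquisition
#'
#' Samples the phantom along a chosen scanner slice axis after placing the
#' fetus at `pose` (a rigid transform applied about the trunk centroid, which
#' is the world origin). The through-plane slice profile is Gaussian with
#' FWHM equal to the slice thickness. Per-slice rigid jitter, a smooth
#' multiplicative bias field and Gaussian noise are applied when nonzero.
#' The stack's affine encodes the scanner geometry, so resampling the stack
#' back to the phantom grid under `pose^-1` overlays the phantom.
#'
#' @param phantom a `fetal_phantom`.
#' @param pose a [rigid_transform()] placing the fetus in scanner space
#'   (atlas world -> scanner world).
#' @param acq an [acquisition_spec()].
#' @param seed integer seed for jitter, bias and noise.
#' @param slice_axis scanner axis along which slices are stacked (1, 2 or 3).
#' @param fov_mm field of view of the stack (defaults to the phantom FOV).
#' @param center_mm scanner-space centre of the stack FOV.
#' @return a `stack` (an [image_volume()] with slice metadata, slices along
#'   the third array dimension, and a ground-truth attribute used by the
#'   oracle segmentation backend).
#' @export
simulate_stack <- function(phantom, pose = rt_identity(),
                           acq = acquisition_spec(), seed = 1L,
                           slice_axis = 3L, fov_mm = NULL,
                           center_mm = c(0, 0, 0)) {
  stopifnot(inherits(phantom, "fetal_phantom"))
  if (!inherits(pose, "rigid_transform")) {
    abort("pose must be a rigid_transform", class = "fetalrecon_invalid_transform")
  }
  if (min(voxel_spacing(phantom$intensity)) >= acq$slice_thickness_mm) {
    abort("phantom spacing must be finer than the slice thickness")
  }
  if (is.null(fov_mm)) fov_mm <- phantom$spec$grid_size * phantom$spec$voxel_mm
  ip <- acq$in_plane_mm
  ss <- acq$slice_spacing_mm
  inplane_axes <- switch(slice_axis, c(2L, 3L), c(1L, 3L), c(1L, 2L))
  nx <- max(4L, round(fov_mm / ip))
  ny <- nx
  nz <- max(2L, round(fov_mm / ss))

  A <- matrix(0, 4, 4); A[4, 4] <- 1
  A[inplane_axes[1], 1] <- ip
  A[inplane_axes[2], 2] <- ip
  A[slice_axis, 3] <- ss
  A[1:3, 4] <- center_mm - A[1:3, 1:3] %*% ((c(nx, ny, nz) - 1) / 2)

  set.seed(seed)
  fetus_center <- drop(rt_apply(pose, phantom$trunk_centroid))
  jitters <- vector("list", nz)
  for (k in seq_len(nz)) {
    if (acq$jitter_rot_deg > 0 || acq$jitter_trans_mm > 0) {
      jr <- stats::runif(3, -acq$jitter_rot_deg, acq$jitter_rot_deg)
      jt <- stats::runif(3, -acq$jitter_trans_mm, acq$jitter_trans_mm)
      jitters[[k]] <- rt_about_center(euler_deg(jr), jt, fetus_center)
    } else {
      jitters[[k]] <- rt_identity()
    }
  }

  psf <- psf_quadrature(acq$slice_thickness_mm)
  nhat <- c(0, 0, 0); nhat[slice_axis] <- 1
  Aph_inv <- solve(phantom$intensity$affine)
  maps <- vector("list", nz)
  offs <- vector("list", nz)
  for (k in seq_len(nz)) {
    Pk <- rt_compose(jitters[[k]], pose)
    shift <- diag(4); shift[3, 4] <- k - 1
    maps[[k]] <- Aph_inv %*% rt_as_affine(rt_invert(Pk)) %*% A %*% shift
    dirv <- Aph_inv[1:3, 1:3] %*% (t(Pk$R) %*% nhat)
    offs[[k]] <- outer(drop(dirv), psf$offsets)
  }
  slices <- c_project_slices(as.numeric(phantom$intensity$data),
                             dim(phantom$intensity$data),
                             maps, offs, psf$weights, nx, ny, 0)
  arr <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) arr[, , k] <- slices[[k]]

  if (acq$bias_amplitude > 0) {
    cx <- seq(-1, 1, length.out = nx)
    cy <- seq(-1, 1, length.out = ny)
    cz <- seq(-1, 1, length.out = nz)
    co <- stats::rnorm(9, sd = 1)
    fld <- outer(outer(co[1] * cx + co[4] * cx^2, co[2] * cy + co[5] * cy^2, "+"),
                 co[3] * cz + co[6] * cz^2, "+") +
      co[7] * outer(outer(cx, cy), rep(1, nz)) +
      co[8] * outer(outer(cx, rep(1, ny)), cz) +
      co[9] * outer(outer(rep(1, nx), cy), cz)
    fld <- fld / max(abs(fld))
    arr <- arr * (1 + acq$bias_amplitude * fld)
  }
  if (acq$noise_sigma > 0) {
    arr <- arr + array(stats::rnorm(length(arr), sd = acq$noise_sigma), dim(arr))
  }

  packages <- if (acq$slice_order == "interleaved" && acq$n_packages > 1L) {
    ((seq_len(nz) - 1L) %% acq$n_packages) + 1L
  } else {
    rep(1L, nz)
  }

  truth <- list(
    pose = pose, jitters = jitters, acq = acq, seed = seed,
    slice_axis = slice_axis,
    global_labels = phantom$global_labels,
    organ_labels = phantom$organ_labels,
    trunk_centroid = phantom$trunk_centroid,
    atlas_landmarks = phantom$landmarks
  )
  new_stack(arr, A, acq$slice_thickness_mm, ss, packages, truth)
}

#' Split a stack into its acquisition packages
#'
#' Groups slices by their package index into one stack per package. The union
#' of the output slices equals the input slices and each output affine
#' reflects its own slice positions (within-package spacing =
#' `n_packages * slice_spacing` for interleaved ordering).
#'
#' @param stack a `stack` with per-slice package indices.
#' @return a list of `stack`s (a singleton list for a single package).
#' @export
split_packages <- function(stack) {
  pk <- stack$packages
  ids <- sort(unique(pk))
  if (length(ids) == 1L) return(list(stack))
  lapply(ids, function(p) subset_slices(stack, which(pk == p)))
}

# take a subset of slices (indices into dim 3), updating affine and metadata
subset_slices <- function(stack, idx) {
  idx <- sort(idx)
  arr <- stack$data[, , idx, drop = FALSE]
  A <- stack$affine
  Anew <- A
  Anew[1:3, 4] <- A[1:3, 4] + A[1:3, 3] * (idx[1] - 1)
  step <- if (length(idx) > 1L) idx[2] - idx[1] else 1L
  Anew[1:3, 3] <- A[1:3, 3] * step
  truth <- stack_truth(stack)
  if (!is.null(truth)) truth$jitters <- truth$jitters[idx]
  new_stack(arr, Anew, stack$slice_thickness_mm,
            stack$slice_spacing_mm * step, rep(1L, length(arr[1, 1, ])),
            truth)
}

#' Re-merge package stacks by slice position
#'
#' Inverse of [split_packages()]: interleaves the slices of several package
#' stacks back into a single stack ordered by through-plane position.
#'
#' @param packages list of `stack`s produced by [split_packages()].
#' @return a single `stack` with slices sorted by world position.
#' @export
merge_packages <- function(packages) {
  if (length(packages) == 1L) return(packages[[1]])
  A1 <- packages[[1]]$affine
  dir3 <- A1[1:3, 3] / sqrt(sum(A1[1:3, 3]^2))
  slices <- list()
  origins <- list()
  pos <- numeric(0)
  for (st in packages) {
    nz <- dim(st$data)[3]
    for (k in seq_len(nz)) {
      o <- st$affine[1:3, 4] + st$affine[1:3, 3] * (k - 1)
      slices[[length(slices) + 1L]] <- st$data[, , k]
      origins[[length(origins) + 1L]] <- o
      pos <- c(pos, sum(o * dir3))
    }
  }
  ord <- order(pos)
  nz <- length(ord)
  d <- dim(packages[[1]]$data)
  arr <- array(0, c(d[1], d[2], nz))
  for (k in seq_len(nz)) arr[, , k] <- slices[[ord[k]]]
  spacing <- if (nz > 1) stats::median(diff(pos[ord])) else
    packages[[1]]$slice_spacing_mm
  Anew <- A1
  Anew[1:3, 3] <- dir3 * spacing
  Anew[1:3, 4] <- origins[[ord[1]]]
  new_stack(arr, Anew, packages[[1]]$slice_thickness_mm, spacing,
            rep(1L, nz), stack_truth(packages[[1]]))
}
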