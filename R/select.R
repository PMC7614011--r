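#' Normalised cross-correlation over a region
#'
#' Pearson correlation of two images' intensities over a region. The region
#' defaults to the voxels where both images are nonzero (and both are
#' non-missing). By convention the result is 0 when the region has fewer than
#' 2 voxels or either side has zero variance, so blank slices count as
#' maximally dissimilar rather than producing NaN.
#'
#' @param a,b [image_volume()]s or arrays on a common grid (no implicit
#'   resampling; mismatched grids are an error).
#' @param region optional logical array selecting the voxels to use.
#' @return NCC in `[-1, 1]` (or 0 for degenerate regions).
#' @export
ncc <- function(a, b, region = NULL) {
  av <- if (inherits(a, "image_volume")) a$data else a
  bv <- if (inherits(b, "image_volume")) b$data else b
  if (!all(dim(av) == dim(bv))) abort("ncc: images are on different grids")
  ok <- !is.na(av) & !is.na(bv)
  if (is.null(region)) {
    ok <- ok & av != 0 & bv != 0
  } else {
    ok <- ok & (region != 0)
  }
  x <- av[ok]
  y <- bv[ok]
  if (length(x) < 2L) return(0)
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  mean((x - mean(x)) * (y - mean(y))) * length(x) / (length(x) - 1) / (sx * sy)
}

#' Within-stack motion corruption score (sequential-slice NCC)
#'
#' The mean 2D NCC between each pair of sequential slices, each pair computed
#' over its non-zero overlap; pairs with an empty overlap (or degenerate
#' intensities) contribute 0. Low values indicate inter-slice motion
#' corruption.
#'
#' @param stack a `stack` (slices along the third array dimension).
#' @return the motion score, in `[-1, 1]`.
#' @export
motion_score <- function(stack) {
  arr <- if (inherits(stack, "image_volume")) stack$data else stack
  nz <- dim(arr)[3]
  if (nz < 2L) abort("motion score needs at least 2 slices")
  vals <- vapply(seq_len(nz - 1L), function(j) {
    ncc(arr[, , j, drop = TRUE], arr[, , j + 1L, drop = TRUE])
  }, numeric(1))
  mean(vals)
}

#' Mutual stack similarity scores (mean pairwise 3D NCC)
#'
#' For stacks resampled to a common reference grid, the similarity of stack i
#' is the mean 3D NCC of stack i against every stack n = 1..N including
#' n = i (the self term contributes 1 for non-degenerate stacks, following
#' the literal mean-over-all-stacks formulation; since it shifts every score
#' equally it cannot change inclusion orderings).
#'
#' @param volumes list of [image_volume()]s (or arrays) on a common grid.
#' @param region optional logical array (e.g. the thorax region) over which
#'   NCC is computed; within it, each pair still uses its non-zero overlap.
#' @return numeric vector of similarity scores, one per stack.
#' @export
stack_similarity <- function(volumes, region = NULL) {
  n <- length(volumes)
  if (n == 0L) abort("no stacks")
  arrs <- lapply(volumes, function(v) if (inherits(v, "image_volume")) v$data else v)
  pair <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      r <- if (is.null(region)) {
        ncc_pair_nonzero(arrs[[i]], arrs[[j]])
      } else {
        ncc_pair_nonzero(arrs[[i]], arrs[[j]], region)
      }
      pair[i, j] <- r
      pair[j, i] <- r
    }
  }
  rowMeans(pair)
}

ncc_pair_nonzero <- function(a, b, region = NULL) {
  ok <- !is.na(a) & !is.na(b) & a != 0 & b != 0
  if (!is.null(region)) ok <- ok & (region != 0)
  x <- a[ok]; y <- b[ok]
  if (length(x) < 2L) return(0)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  mean((x - mean(x)) * (y - mean(y))) * length(x) / (length(x) - 1) / (sx * sy)
}

#' Relative thorax-mask volume deviation
#'
#' Per-stack `|V_i - median(V)| / median(V)` with volumes in mm^3. Used to
#' flag stacks whose thorax mask is abnormally small or large (including the
#' absence of the thorax from the stack coverage).
#'
#' @param mask_volumes_mm3 numeric vector of per-stack mask volumes (mm^3).
#' @return numeric vector of deviations (>= 0).
#' @export
volume_deviation <- function(mask_volumes_mm3) {
  v <- as.numeric(mask_volumes_mm3)
  if (length(v) < 1L) abort("need at least one volume")
  med <- stats::median(v)
  if (med == 0) abort("median mask volume is zero")
  abs(v - med) / med
}

#' Compute per-stack selection metrics
#'
#' Builds the metric table used for stack selection: motion corruption
#' (sequential-slice NCC), mutual similarity (mean pairwise 3D NCC over the
#' thorax region) and relative thorax-volume deviation.
#'
#' @param stacks list of native-grid `stack`s (for the motion score).
#' @param resampled list of the same stacks resampled to a common reference
#'   grid (for the similarity score).
#' @param mask_volumes_mm3 per-stack thorax mask volumes in mm^3.
#' @param region optional logical array on the reference grid restricting the
#'   similarity computation.
#' @return a tibble with columns `stack`, `Ccor`, `Csim`, `Cvol`,
#'   `V_thorax_mm3`, `product`.
#' @export
compute_stack_metrics <- function(stacks, resampled, mask_volumes_mm3,
                                  region = NULL) {
  ccor <- vapply(stacks, motion_score, numeric(1))
  csim <- stack_similarity(resampled, region)
  cvol <- volume_deviation(mask_volumes_mm3)
  tibble::tibble(
    stack = seq_along(stacks),
    Ccor = ccor, Csim = csim, Cvol = cvol,
    V_thorax_mm3 = as.numeric(mask_volumes_mm3),
    product = ccor * csim
  )
}

#' Apply the stack inclusion criteria
#'
#' A stack is included iff all three strict inequalities hold:
#' `Ccor > ccor_frac * max(Ccor)`, `Csim > csim_frac * max(Csim)` and
#' `Cvol < cvol_max` (defaults 0.5, 0.5 and 0.40). Boundary values are
#' excluded (strict inequalities). If every stack fails, an explicit
#' "no usable stacks" error is raised listing the per-stack metrics.
#'
#' @param metrics tibble from [compute_stack_metrics()] (or with columns
#'   `Ccor`, `Csim`, `Cvol`).
#' @param ccor_frac,csim_frac fractions of the per-metric maximum (default 0.5).
#' @param cvol_max maximum allowed relative volume deviation (default 0.40).
#' @return the metrics tibble with logical `included` and character `reason`
#'   columns added.
#' @export
apply_inclusion <- function(metrics, ccor_frac = 0.5, csim_frac = 0.5,
                            cvol_max = 0.40) {
  ok_cor <- metrics$Ccor > ccor_frac * max(metrics$Ccor)
  ok_sim <- metrics$Csim > csim_frac * max(metrics$Csim)
  ok_vol <- metrics$Cvol < cvol_max
  reason <- rep("", nrow(metrics))
  reason[!ok_cor] <- paste0(reason[!ok_cor], "motion_corrupted;")
  reason[!ok_sim] <- paste0(reason[!ok_sim], "dissimilar;")
  reason[!ok_vol] <- paste0(reason[!ok_vol], "volume_outlier;")
  out <- metrics
  out$included <- ok_cor & ok_sim & ok_vol
  out$reason <- sub(";$", "", reason)
  if (!any(out$included)) {
    abort(paste0(
      "no usable stacks: all stacks excluded\n",
      paste(utils::capture.output(print(as.data.frame(out))), collapse = "\n")
    ), class = "fetalrecon_no_usable_stacks")
  }
  out
}

#' Select the reference stack
#'
#' The included stack with the highest `Ccor * Csim` product; ties are broken
#' deterministically by the lowest stack index.
#'
#' @param metrics tibble from [apply_inclusion()] (must have an `included`
#'   column).
#' @return the selected stack index (into the original stack list).
#' @export
select_reference <- function(metrics) {
  if (!"included" %in% names(metrics)) {
    abort("metrics must have been passed through apply_inclusion()")
  }
  cand <- which(metrics$included)
  prod <- metrics$Ccor[cand] * metrics$Csim[cand]
  cand[which.max(prod)]   # which.max takes the first maximum: lowest index
}

#' Refine stack alignments by pairwise rigid registration
#'
#' Refines each stack's landmark-estimated pose by intensity-based rigid
#' registration to an initial reference (the least motion-corrupted stack)
#' over the thorax region. If the registration diverges for a stack (its
#' similarity drops below the value at initialisation, or it errors), the
#' landmark-only transform is kept for that stack and the event is recorded.
#'
#' @param stacks list of native-grid `stack`s.
#' @param init list of [rigid_transform()]s (landmark poses, stack world ->
#'   atlas world).
#' @param masks list of binary thorax masks on the stack grids (used for the
#'   registration region after mapping to the reference grid).
#' @param cfg a [registration_config()].
#' @return list with `transforms` (refined transforms), `refined` (logical:
#'   was the registration result accepted) and `reference` (index of the
#'   registration target stack).
#' @export
refine_pairwise <- function(stacks, init, masks, cfg = registration_config()) {
  n <- length(stacks)
  ref <- which.max(vapply(stacks, motion_score, numeric(1)))
  # reference stack resampled to an isotropic grid in atlas axes
  iso <- min(vapply(stacks, function(s) min(voxel_spacing(s)[1:2]), numeric(1)))
  fixed <- resample_iso(stacks[[ref]], init[[ref]], iso)
  fmask <- resample_volume(masks[[ref]], dim(fixed$data), fixed$affine,
                           transform = init[[ref]], method = "nearest",
                           fill = 0)
  out <- init
  refined <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (i == ref) { refined[i] <- TRUE; next }
    res <- tryCatch(
      rigid_register(stacks[[i]], fixed, init = init[[i]], cfg = cfg,
                     mask = fmask$data),
      error = function(e) NULL
    )
    # divergence guard: keep the landmark transform when the refined
    # similarity is not an improvement or is too low to indicate overlap
    if (!is.null(res) && is.finite(res$similarity) &&
        res$similarity >= res$init_similarity - 1e-6 &&
        res$similarity >= 0.2) {
      out[[i]] <- res$transform
      refined[i] <- TRUE
    }
  }
  list(transforms = out, refined = refined, reference = ref)
}

# resample a stack under a transform to an isotropic grid covering it
resample_iso <- function(stack, transform, spacing, margin_mm = 2) {
  d <- dim(stack$data)
  corners <- as.matrix(expand.grid(c(1, d[1]), c(1, d[2]), c(1, d[3])))
  w <- rt_apply(transform, voxel_to_world(stack, corners))
  lo <- apply(w, 2, min) - margin_mm
  hi <- apply(w, 2, max) + margin_mm
  dims <- pmax(4L, ceiling((hi - lo) / spacing))
  A <- diag(c(spacing, spacing, spacing, 1))
  A[1:3, 4] <- lo
  resample_volume(stack, dims, A, transform = transform, fill = NA_real_)
}

#' Build the median template and average thorax mask
#'
#' Resamples all included stacks (linear interpolation) under their transforms
#' to an isotropic template grid in atlas orientation and takes the voxelwise
#' median over stacks with valid samples at each voxel. The thorax mask is
#' the voxelwise mean of the resampled binary masks thresholded at 0.5
#' (majority vote, i.e. the median of binary values).
#'
#' @param stacks list of included `stack`s (native grids).
#' @param transforms list of [rigid_transform()]s (stack world -> atlas).
#' @param masks list of binary thorax masks on the stack grids.
#' @param spacing template grid spacing in mm; defaults to the finest
#'   in-plane spacing among the stacks.
#' @return list with `template` (an [image_volume()], invalid voxels 0) and
#'   `mask` (a binary [label_map()]).
#' @export
build_template <- function(stacks, transforms, masks, spacing = NULL) {
  if (length(stacks) < 1L) abort("need at least one included stack")
  if (is.null(spacing)) {
    spacing <- min(vapply(stacks, function(s) min(voxel_spacing(s)[1:2]),
                          numeric(1)))
  }
  # common grid: union of transformed stack bounding boxes
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (i in seq_along(stacks)) {
    d <- dim(masks[[i]]$data)
    idx <- which(masks[[i]]$data != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    corners <- as.matrix(expand.grid(range(idx[, 1]), range(idx[, 2]),
                                     range(idx[, 3])))
    w <- rt_apply(transforms[[i]], voxel_to_world(masks[[i]], corners))
    lo <- pmin(lo, apply(w, 2, min) - 5)
    hi <- pmax(hi, apply(w, 2, max) + 5)
  }
  if (any(!is.finite(lo))) abort("all masks are empty")
  dims <- pmax(4L, ceiling((hi - lo) / spacing))
  A <- diag(c(spacing, spacing, spacing, 1))
  A[1:3, 4] <- lo

  n <- length(stacks)
  nvox <- prod(dims)
  mat <- matrix(NA_real_, nvox, n)
  msum <- numeric(nvox)
  for (i in seq_len(n)) {
    r <- resample_volume(stacks[[i]], dims, A, transform = transforms[[i]],
                         fill = NA_real_)
    mat[, i] <- as.numeric(r$data)
    mk <- resample_volume(masks[[i]], dims, A, transform = transforms[[i]],
                          method = "nearest", fill = 0)
    msum <- msum + as.numeric(mk$data != 0)
  }
  med <- c_row_median(mat)
  med[is.na(med)] <- 0
  template <- image_volume(array(med, dims), A)
  avg <- array(as.integer(msum / n >= 0.5), dims)
  list(template = template,
       mask = label_map(avg, A, c(thorax = 1L)))
}
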