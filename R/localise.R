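#' Segmentation backend configuration
#'
#' The pipeline's segmentation steps (global trunk localisation and organ
#' landmark segmentation) are defined against an abstract backend. The
#' `oracle` backend derives labels from the simulator's ground truth and makes
#' the whole pipeline deterministic and CNN-free; it is the backend exercised
#' by the test suite. The `cnn` backend records the reference 3D UNet
#' configuration (5 encoder/decoder levels with 32/64/128/256/512 channels,
#' instance normalisation, LeakyReLU, average pooling for the first two
#' down-samplings then max pooling, generalised Dice loss, Adam with learning
#' rate 0.002 and batch size 2, 128^3 input grid) but requires trained
#' weights; without them it raises an explicit "untrained backend" error
#' rather than producing silent garbage.
#'
#' @param mode `"oracle"` or `"cnn"`.
#' @param weights for `cnn` mode, a path to trained weights.
#' @param channels,input_grid,normalisation,activation,pooling,loss,optimiser
#'   CNN architecture/training configuration (documentation defaults).
#' @return an object of class `segmenter_backend`.
#' @export
segmenter_backend <- function(mode = c("oracle", "cnn"), weights = NULL,
                              channels = c(32L, 64L, 128L, 256L, 512L),
                              input_grid = 128L,
                              normalisation = "instance",
                              activation = "leaky_relu",
                              pooling = c("avg", "avg", "max", "max"),
                              loss = "generalised_dice",
                              optimiser = list(name = "adam", lr = 0.002,
                                               batch_size = 2L)) {
  mode <- match.arg(mode)
  structure(list(mode = mode, weights = weights, channels = channels,
                 input_grid = as.integer(input_grid),
                 normalisation = normalisation, activation = activation,
                 pooling = pooling, loss = loss, optimiser = optimiser),
            class = "segmenter_backend")
}

#' Resample a volume to an isotropic cubic grid
#'
#' Resamples to a `grid^3` voxel cube, preserving the aspect ratio by padding
#' (isotropic target spacing equal to the largest physical extent divided by
#' `grid`) rather than stretching. The affine is updated so world geometry is
#' unchanged; the world position of the volume centre is preserved.
#'
#' @param vol an [image_volume()].
#' @param grid target grid size per axis (>= 8).
#' @param method interpolation, `"linear"` or `"nearest"`.
#' @return an `image_volume` of size `grid^3`.
#' @export
resample_to_grid <- function(vol, grid, method = c("linear", "nearest")) {
  method <- match.arg(method)
  grid <- as.integer(grid)
  if (is.na(grid) || grid < 8L) abort("grid must be >= 8")
  d <- dim(vol$data)
  sp <- voxel_spacing(vol)
  extent <- d * sp
  target_sp <- max(extent) / grid
  # axis directions of the input, scaled to the target spacing
  dirs <- sweep(vol$affine[1:3, 1:3], 2, sp, "/")
  A <- diag(4)
  A[1:3, 1:3] <- dirs * target_sp
  center <- volume_center(vol)
  A[1:3, 4] <- center - A[1:3, 1:3] %*% rep((grid - 1) / 2, 3)
  resample_volume(vol, rep(grid, 3), A, method = method, fill = 0)
}

#' Global 4-class localisation of a stack
#'
#' Step I: produce the mutually exclusive background/uterus/brain/trunk label
#' map for a stack in its native grid. In `oracle` mode the labels are
#' obtained by sampling the simulator's ground-truth global label map under
#' the true fetal pose (nearest neighbour); organs absent from the stack's
#' field of view yield empty labels, so brain-only stacks produce an empty
#' trunk label and are flagged upstream rather than failing.
#'
#' @param stack a `stack` (for `oracle` mode it must carry simulator ground
#'   truth).
#' @param backend a [segmenter_backend()].
#' @return a [label_map()] on the stack's grid with labels
#'   `uterus`, `brain`, `trunk`.
#' @export
segment_global <- function(stack, backend = segmenter_backend("oracle")) {
  if (backend$mode == "cnn") {
    if (is.null(backend$weights)) {
      abort("untrained backend: cnn mode requires trained weights",
            class = "fetalrecon_untrained_backend")
    }
    abort("cnn inference is not available in this build; use the oracle backend",
          class = "fetalrecon_untrained_backend")
  }
  truth <- stack_truth(stack)
  if (is.null(truth)) {
    abort("oracle mode requires ground-truth labels alongside the stack")
  }
  oracle_sample_labels(stack, truth$global_labels, truth$pose)
}

# nearest-neighbour sampling of a phantom-space label map into the stack grid
oracle_sample_labels <- function(stack, labels, pose) {
  out <- resample_volume(labels, dim(stack$data), stack$affine,
                         transform = pose, method = "nearest", fill = 0)
  label_map(array(as.integer(out$data), dim(out$data)), stack$affine,
            labels$labels)
}

#' Keep the largest 26-connected component of a binary mask
#'
#' Components are found with 26-connectivity. Ties in component size are
#' broken deterministically by the lexicographically smallest bounding-box
#' origin. An empty mask returns an empty mask.
#'
#' @param mask a binary [label_map()] or [image_volume()] (nonzero = in mask).
#' @return a binary mask of the same class and grid.
#' @export
largest_component <- function(mask) {
  m <- mask$data != 0
  if (!any(m)) return(mask)
  lab <- c_label_components(m, dim(m))
  counts <- tabulate(lab[lab > 0L])
  best <- which(counts == max(counts))
  if (length(best) > 1L) {
    origins <- t(vapply(best, function(b) {
      idx <- which(lab == b, arr.ind = TRUE)
      c(min(idx[, 1]), min(idx[, 2]), min(idx[, 3]))
    }, numeric(3)))
    best <- best[order(origins[, 1], origins[, 2], origins[, 3])[1]]
  }
  out <- mask
  out$data <- array(as.integer(lab == best), dim(m))
  out
}

#' Crop a stack to a mask's region of interest
#'
#' Crops to the bounding box of the (nonzero) mask dilated by `margin_mm`,
#' clipped at the stack edges; the affine is updated so world geometry is
#' preserved exactly.
#'
#' @param stack a `stack` (or plain [image_volume()]).
#' @param mask a binary mask on the same grid.
#' @param margin_mm dilation margin in mm (default 15).
#' @return the cropped stack.
#' @export
crop_to_roi <- function(stack, mask, margin_mm = 15) {
  if (!all(dim(mask$data) == dim(stack$data))) {
    abort("mask and stack grids differ")
  }
  idx <- which(mask$data != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    abort("trunk absent: mask is empty", class = "fetalrecon_trunk_absent")
  }
  sp <- voxel_spacing(stack)
  grow <- ceiling(margin_mm / sp)
  lo <- pmax(1, apply(idx, 2, min) - grow)
  hi <- pmin(dim(stack$data), apply(idx, 2, max) + grow)
  crop_indices(stack, lo, hi)
}

# crop any image_volume/stack to inclusive voxel index ranges
crop_indices <- function(vol, lo, hi) {
  arr <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  A <- vol$affine
  Anew <- A
  Anew[1:3, 4] <- A[1:3, 4] + A[1:3, 1:3] %*% (lo - 1)
  out <- vol
  out$data <- arr
  out$affine <- Anew
  if (inherits(vol, "stack")) {
    out$packages <- vol$packages[lo[3]:hi[3]]
    truth <- stack_truth(vol)
    if (!is.null(truth)) {
      truth$jitters <- truth$jitters[lo[3]:hi[3]]
      attr(out, "truth") <- truth
    }
  }
  out
}
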