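#' @useDynLib fetalrecon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang abort warn .data
NULL

#' 3D image volume with world geometry
#'
#' A minimal container for a 3D scalar voxel grid together with a 4x4
#' voxel-to-world affine in mm (RAS+ convention, 0-based voxel indices, as in
#' NIfTI headers). Orientation and position live entirely in the affine.
#'
#' @param data numeric 3D array of voxel values.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices (homogeneous)
#'   to world coordinates in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, affine) {
  if (length(dim(data)) != 3L) abort("`data` must be a 3D array")
  affine <- unclass(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L))) abort("`affine` must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps) {
    abort("affine is not invertible")
  }
  structure(list(data = data, affine = affine), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  sp <- signif(voxel_spacing(x), 4)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %s mm\n",
              class(x)[1], d[1], d[2], d[3], paste(sp, collapse = " x ")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Voxel spacing of a volume in mm
#' @param vol an `image_volume`.
#' @return numeric length-3 vector of per-axis spacings (mm).
#' @export
voxel_spacing <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Map voxel indices to world coordinates
#'
#' @param vol an `image_volume`.
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  h <- cbind(ijk - 1, 1)
  out <- h %*% t(vol$affine)
  out[, 1:3, drop = FALSE]
}

#' Map world coordinates to (continuous, 1-based) voxel indices
#' @param vol an `image_volume`.
#' @param xyz n x 3 matrix (or length-3 vector) of world mm coordinates.
#' @return n x 3 matrix of continuous 1-based voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  h <- cbind(xyz, 1) %*% t(solve(vol$affine))
  h[, 1:3, drop = FALSE] + 1
}

#' World coordinates of the volume centre
#' @param vol an `image_volume`.
#' @return length-3 world mm coordinates of the grid centre.
#' @export
volume_center <- function(vol) {
  drop(voxel_to_world(vol, (dim(vol$data) + 1) / 2))
}

#' Resample a volume onto an arbitrary destination grid
#'
#' Samples `src` at the world positions of a destination grid, optionally
#' through a world-to-world rigid transform `transform` (interpreted as
#' mapping source world coordinates to destination world coordinates, i.e.
#' `out(w) = src(transform^-1 w)`).
#'
#' @param src an `image_volume`.
#' @param dims destination grid size (length-3 integer).
#' @param affine destination 4x4 voxel-to-world affine.
#' @param transform optional `rigid_transform` from source world to destination
#'   world; identity if `NULL`.
#' @param method `"linear"` or `"nearest"`.
#' @param fill value for samples outside the source grid (`NA` marks them
#'   invalid; `0` treats outside as background).
#' @return an `image_volume` on the destination grid.
#' @export
resample_volume <- function(src, dims, affine, transform = NULL,
                            method = c("linear", "nearest"), fill = NA_real_) {
  method <- match.arg(method)
  t4 <- if (is.null(transform)) diag(4) else rt_as_affine(rt_invert(transform))
  M <- solve(src$affine) %*% t4 %*% affine
  arr <- c_resample_affine(as.numeric(src$data), dim(src$data), M,
                           as.integer(dims), if (method == "nearest") 1L else 0L,
                           fill)
  image_volume(arr, affine)
}

#' Resample one volume onto the grid of another
#' @param src an `image_volume` to sample from.
#' @param target an `image_volume` whose grid defines the output.
#' @inheritParams resample_volume
#' @return an `image_volume` on `target`'s grid.
#' @export
resample_onto <- function(src, target, transform = NULL,
                          method = c("linear", "nearest"), fill = NA_real_) {
  resample_volume(src, dim(target$data), target$affine, transform,
                  match.arg(method), fill)
}

#' Gaussian-smooth a volume (separable, sigma in voxels)
#' @param vol an `image_volume`.
#' @param sigma_vox standard deviation of the kernel in voxel units.
#' @return smoothed `image_volume`.
#' @keywords internal
smooth_volume <- function(vol, sigma_vox) {
  if (sigma_vox <= 0) return(vol)
  h <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-h, h), sd = sigma_vox)
  k <- k / sum(k)
  arr <- c_separable_conv(as.numeric(vol$data), dim(vol$data), k)
  image_volume(arr, vol$affine)
}

#' Block-average downsample a volume by an integer factor
#' @param vol an `image_volume`.
#' @param f integer factor >= 1.
#' @return downsampled `image_volume` with updated affine.
#' @keywords internal
downsample_volume <- function(vol, f) {
  f <- as.integer(f)
  if (f <= 1L) return(vol)
  arr <- c_block_mean(as.numeric(vol$data), dim(vol$data), f)
  A <- vol$affine
  Anew <- A
  Anew[1:3, 1:3] <- A[1:3, 1:3] * f
  # new voxel 0 centre sits at the mean of the first f input voxel centres
  Anew[1:3, 4] <- A[1:3, 4] + A[1:3, 1:3] %*% rep((f - 1) / 2, 3)
  image_volume(arr, Anew)
}

#' Read a NIfTI file as an image volume
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return an `image_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  image_volume(as.array(img), unclass(RNifti::xform(img)))
}

#' Write an image volume as NIfTI-1
#' @param vol an `image_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Integer label map with a label dictionary
#'
#' An [image_volume()] whose voxels are integer class codes; `labels` maps
#' class names to codes. Classes are mutually exclusive by construction (one
#' integer per voxel).
#'
#' @param data integer 3D array of class codes (0 = background).
#' @param affine 4x4 voxel-to-world affine.
#' @param labels named integer vector, e.g. `c(uterus = 1, brain = 2, trunk = 3)`.
#' @return an object of classes `label_map`, `image_volume`.
#' @export
label_map <- function(data, affine, labels) {
  v <- image_volume(data, affine)
  if (is.null(names(labels))) abort("`labels` must be a named integer vector")
  v$labels <- as.integer(labels)
  names(v$labels) <- names(labels)
  class(v) <- c("label_map", class(v))
  v
}

#' Extract one label as a binary mask
#' @param lm a `label_map`.
#' @param name label name present in `lm$labels`.
#' @return a binary (0/1) `label_map` with a single label `name = 1`.
#' @export
label_mask <- function(lm, name) {
  if (!name %in% names(lm$labels)) abort(sprintf("unknown label '%s'", name))
  code <- lm$labels[[name]]
  arr <- array(as.integer(lm$data == code), dim(lm$data))
  label_map(arr, lm$affine, stats::setNames(1L, name))
}

#' Mask volume in mm^3 (voxel count times voxel volume)
#' @param mask a binary `label_map` or `image_volume` (nonzero = in mask).
#' @return volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  sum(mask$data != 0) * prod(voxel_spacing(mask))
}

#' Centroid of a binary mask in world mm
#' @param mask binary `image_volume` (nonzero = in mask).
#' @return length-3 world mm coordinates, or error if the mask is empty.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask$data != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("mask is empty", class = "fetalrecon_empty_mask")
  drop(colMeans(voxel_to_world(mask, idx)))
}

#' Dilate a binary mask by a physical radius
#' @param mask binary `image_volume`.
#' @param radius_mm dilation radius in mm (box structuring element).
#' @return dilated binary `label_map`-compatible volume.
#' @keywords internal
dilate_mask <- function(mask, radius_mm) {
  if (radius_mm <= 0) return(mask)
  sp <- voxel_spacing(mask)
  r <- pmax(0L, ceiling(radius_mm / sp))
  arr <- as.numeric(mask$data != 0)
  dim(arr) <- dim(mask$data)
  # separable box dilation: convolution with a box then threshold
  for (ax in 1:3) {
    if (r[ax] == 0L) next
    arr <- conv_axis(arr, rep(1, 2 * r[ax] + 1), ax)
  }
  out <- mask
  out$data <- array(as.integer(arr > 0), dim(mask$data))
  out
}

# convolve along a single axis with zero padding (used by dilate_mask)
conv_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  h <- (length(kern) - 1) / 2
  padded <- rbind(matrix(0, h, ncol(m)), m, matrix(0, h, ncol(m)))
  out <- matrix(0, nrow(m), ncol(m))
  for (s in seq_along(kern)) {
    out <- out + kern[s] * padded[s:(s + nrow(m) - 1), , drop = FALSE]
  }
  a <- array(out, da)
  aperm(a, order(perm))
}
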