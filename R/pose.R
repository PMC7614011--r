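#' Organ landmark segmentation for a stack
#'
#' Step II's segmentation stage: the thorax/abdomen/heart/liver label map in
#' the stack's native grid. In `oracle` mode the simulator's ground-truth
#' organ label map is sampled under the true pose (nearest neighbour),
#' emulating a perfect segmenter; residual per-slice motion jitter remains as
#' a realistic imperfection.
#'
#' @param stack a `stack` carrying simulator ground truth (oracle mode).
#' @param backend a [segmenter_backend()].
#' @return a [label_map()] with labels `thorax`, `abdomen`, `heart`, `liver`.
#' @export
segment_organs <- function(stack, backend = segmenter_backend("oracle")) {
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
  oracle_sample_labels(stack, truth$organ_labels, truth$pose)
}

#' Ordered 4-landmark set (thorax, abdomen, heart, liver centroids)
#'
#' @param points 4 x 3 numeric matrix of world mm coordinates, ordered
#'   thorax, abdomen, heart, liver.
#' @param provenance `"oracle"` or `"segmented"`.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points, provenance = "segmented") {
  points <- as.matrix(points)
  if (!all(dim(points) == c(4L, 3L)) || any(!is.finite(points))) {
    abort("landmark_set needs a finite 4 x 3 matrix")
  }
  rownames(points) <- c("thorax", "abdomen", "heart", "liver")
  check_nondegenerate(points)
  structure(list(points = points, provenance = provenance),
            class = "landmark_set")
}

check_nondegenerate <- function(points) {
  centred <- sweep(points, 2, colMeans(points))
  sv <- svd(centred)$d
  if (sv[2] < 1e-8 * max(sv[1], .Machine$double.eps)) {
    abort("degenerate landmark configuration (points are collinear)",
          class = "fetalrecon_degenerate_landmarks")
  }
  invisible(points)
}

#' Extract the four organ-centroid landmarks from an organ label map
#'
#' Heart (resp. liver) voxels are removed from the thorax (resp. abdomen)
#' region before centroid computation, matching the behaviour of overlapping
#' segmentation outputs. Centroids are unweighted voxel-centre means returned
#' in world mm. Any empty organ label raises a "landmark missing" condition
#' so the stack can be excluded from pose estimation rather than silently
#' registered on fewer points.
#'
#' @param organ_labels a [label_map()] with labels `thorax`, `abdomen`,
#'   `heart`, `liver` (integer map, or overlapping binary masks passed as a
#'   named list of masks).
#' @param provenance recorded provenance of the landmarks.
#' @return a [landmark_set()].
#' @export
extract_landmarks <- function(organ_labels, provenance = "segmented") {
  if (inherits(organ_labels, "label_map")) {
    masks <- lapply(c("thorax", "abdomen", "heart", "liver"), function(nm) {
      organ_labels$data == organ_labels$labels[[nm]]
    })
    names(masks) <- c("thorax", "abdomen", "heart", "liver")
    affine <- organ_labels$affine
  } else {
    masks <- lapply(organ_labels, function(m) m$data != 0)
    affine <- organ_labels[[1]]$affine
  }
  # subtract the contained organs before computing the container centroids
  masks$thorax <- masks$thorax & !masks$heart
  masks$abdomen <- masks$abdomen & !masks$liver
  ref <- image_volume(array(0, dim(masks$thorax)), affine)
  pts <- t(vapply(c("thorax", "abdomen", "heart", "liver"), function(nm) {
    idx <- which(masks[[nm]], arr.ind = TRUE)
    if (nrow(idx) == 0L) {
      abort(sprintf("landmark missing: empty '%s' label", nm),
            class = "fetalrecon_landmark_missing")
    }
    colMeans(voxel_to_world(ref, idx))
  }, numeric(3)))
  landmark_set(pts, provenance)
}

#' Atlas reference landmark configuration
#'
#' The four landmark points in the standard radiological space, in the same
#' thorax/abdomen/heart/liver ordering as [landmark_set()]. For phantom
#' worlds the reference is the landmark set of the untransformed phantom; for
#' real data it is a packaged JSON of reference coordinates.
#'
#' @param points 4 x 3 matrix of world mm coordinates (ordered thorax,
#'   abdomen, heart, liver), or a `landmark_set`.
#' @return an object of class `atlas_reference`.
#' @export
atlas_reference <- function(points) {
  if (inherits(points, "landmark_set")) points <- points$points
  ls <- landmark_set(points, provenance = "oracle")
  structure(list(points = ls$points), class = "atlas_reference")
}

#' Read / write an atlas reference as JSON
#'
#' The JSON format is a named object `{landmark: [x, y, z], ...}` in mm.
#' A synthetic example (the landmark coordinates of the default digital
#' phantom) ships at
#' `system.file("extdata", "atlas_phantom_synthetic.json", package = "fetalrecon")`.
#'
#' @param path JSON file path.
#' @return an `atlas_reference` (for `read_atlas`); `path` invisibly (for
#'   `write_atlas`).
#' @export
read_atlas <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- do.call(rbind, obj[c("thorax", "abdomen", "heart", "liver")])
  atlas_reference(pts)
}

#' @rdname read_atlas
#' @param atlas an `atlas_reference` to write.
#' @export
write_atlas <- function(atlas, path) {
  obj <- stats::setNames(
    lapply(seq_len(4), function(i) unname(atlas$points[i, ])),
    rownames(atlas$points)
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Least-squares rigid point registration (Procrustes/Kabsch)
#'
#' Computes the rigid transform minimising `sum ||R s_i + t - t_i||^2` between
#' two ordered point sets by centroid alignment and SVD rotation with
#' reflection correction; no scaling. Collinear configurations raise a
#' degenerate-configuration error.
#'
#' @param source,target [landmark_set()]s (or n x 3 matrices) in the same
#'   ordering.
#' @return a [rigid_transform()] mapping source points onto target points.
#' @export
point_register <- function(source, target) {
  s <- if (inherits(source, "landmark_set")) source$points else as.matrix(source)
  t_ <- if (inherits(target, "landmark_set")) target$points else
    if (inherits(target, "atlas_reference")) target$points else as.matrix(target)
  if (!all(dim(s) == dim(t_))) abort("point sets differ in size")
  check_nondegenerate(s)
  check_nondegenerate(t_)
  cs <- colMeans(s)
  ct <- colMeans(t_)
  H <- crossprod(sweep(s, 2, cs), sweep(t_, 2, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  rigid_transform(R, ct - drop(R %*% cs))
}

#' Reorient a stack to the atlas by landmark registration
#'
#' Computes the pose transform `point_register(landmarks, atlas)` and applies
#' it directly to the stack's header affine (a pure header update: the voxel
#' data are untouched, no resampling happens).
#'
#' @param stack a `stack` or [image_volume()].
#' @param landmarks the stack's [landmark_set()] in its current world frame.
#' @param atlas an [atlas_reference()].
#' @return a list with elements `stack` (header-updated) and `transform`
#'   (the estimated pose, current world -> atlas world).
#' @export
reorient_to_atlas <- function(stack, landmarks, atlas) {
  tr <- point_register(landmarks, atlas$points)
  out <- stack
  out$affine <- rt_as_affine(tr) %*% stack$affine
  list(stack = out, transform = tr)
}
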