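#' Pipeline configuration
#'
#' Orchestration settings for the four-step automated reconstruction:
#' (I) global trunk localisation and cropping, (II) landmark-based
#' reorientation to the atlas, (III) metric-driven stack selection and median
#' template generation, (IV) rigid slice-to-volume super-resolution.
#'
#' @param backend a [segmenter_backend()].
#' @param atlas an [atlas_reference()]; `NULL` uses the simulator's phantom
#'   landmarks carried by the stacks.
#' @param margin_mm trunk ROI crop margin (mm).
#' @param ccor_frac,csim_frac,cvol_max stack inclusion thresholds (see
#'   [apply_inclusion()]).
#' @param split_packages `TRUE`/`FALSE`, or `NULL` to split exactly when the
#'   slice-order metadata indicates interleaving.
#' @param min_stacks minimum recommended number of stacks (default 6); fewer
#'   produces a warning, not a failure.
#' @param recon a [recon_config()].
#' @param reg a [registration_config()] for the pairwise refinement.
#' @param seed integer seed recorded with the run.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(backend = segmenter_backend("oracle"),
                            atlas = NULL, margin_mm = 15,
                            ccor_frac = 0.5, csim_frac = 0.5, cvol_max = 0.40,
                            split_packages = NULL, min_stacks = 6L,
                            recon = recon_config(), reg = registration_config(),
                            seed = 1L) {
  if (min_stacks < 1L) abort("min_stacks must be >= 1")
  if (cvol_max <= 0 || ccor_frac < 0 || csim_frac < 0) {
    abort("thresholds out of range")
  }
  structure(list(backend = backend, atlas = atlas, margin_mm = margin_mm,
                 ccor_frac = ccor_frac, csim_frac = csim_frac,
                 cvol_max = cvol_max, split_packages = split_packages,
                 min_stacks = as.integer(min_stacks), recon = recon,
                 reg = reg, seed = as.integer(seed)),
            class = "pipeline_config")
}

# thorax region mask (thorax + heart labels) from an organ label map
thorax_mask <- function(organs) {
  codes <- organs$labels[c("thorax", "heart")]
  arr <- array(as.integer(organs$data %in% codes), dim(organs$data))
  label_map(arr, organs$affine, c(thorax = 1L))
}

# bounding box of a nonzero mask dilated by a margin, clipped to the grid
roi_bounds <- function(mask, margin_mm) {
  idx <- which(mask$data != 0, arr.ind = TRUE)
  sp <- voxel_spacing(mask)
  grow <- ceiling(margin_mm / sp)
  list(lo = pmax(1, apply(idx, 2, min) - grow),
       hi = pmin(dim(mask$data), apply(idx, 2, max) + grow))
}

# Step I on a list of stacks: localisation, largest component, crop.
# Returns kept stacks, their trunk masks (cropped) and a log tibble.
step_localise <- function(stacks, cfg) {
  kept <- list(); masks <- list(); keep_idx <- integer(0)
  log <- list()
  for (i in seq_along(stacks)) {
    seg <- segment_global(stacks[[i]], cfg$backend)
    trunk <- largest_component(label_mask(seg, "trunk"))
    if (!any(trunk$data != 0)) {
      log[[length(log) + 1L]] <- tibble::tibble(
        step = "I", stack = i, event = "dropped", reason = "trunk_absent")
      next
    }
    b <- roi_bounds(trunk, cfg$margin_mm)
    kept[[length(kept) + 1L]] <- crop_indices(stacks[[i]], b$lo, b$hi)
    masks[[length(masks) + 1L]] <- crop_indices(trunk, b$lo, b$hi)
    keep_idx <- c(keep_idx, i)
    log[[length(log) + 1L]] <- tibble::tibble(
      step = "I", stack = i, event = "kept", reason = "")
  }
  list(stacks = kept, trunk_masks = masks, index = keep_idx,
       log = dplyr::bind_rows(log))
}

# Step II on cropped stacks: organ landmarks + header reorientation.
step_pose <- function(stacks, cfg) {
  n <- length(stacks)
  transforms <- vector("list", n)
  organs <- vector("list", n)
  keep <- logical(n)
  log <- list()
  for (i in seq_len(n)) {
    res <- tryCatch({
      org <- segment_organs(stacks[[i]], cfg$backend)
      lm <- extract_landmarks(org, provenance = "segmented")
      atlas <- cfg$atlas
      if (is.null(atlas)) {
        truth <- stack_truth(stacks[[i]])
        if (is.null(truth)) abort("no atlas provided and no simulator truth")
        atlas <- atlas_reference(truth$atlas_landmarks)
      }
      list(org = org, reor = reorient_to_atlas(stacks[[i]], lm, atlas))
    }, fetalrecon_landmark_missing = function(e) e)
    if (rlang::is_condition(res)) {
      log[[length(log) + 1L]] <- tibble::tibble(
        step = "II", stack = i, event = "dropped",
        reason = "landmark_missing")
      next
    }
    keep[i] <- TRUE
    organs[[i]] <- res$org
    transforms[[i]] <- res$reor$transform
    log[[length(log) + 1L]] <- tibble::tibble(
      step = "II", stack = i, event = "posed", reason = "")
  }
  list(transforms = transforms, organs = organs, keep = keep,
       log = dplyr::bind_rows(log))
}

# Step III: refinement, metrics, inclusion, reference, template.
step_select <- function(stacks, transforms, organ_labels, cfg) {
  masks <- lapply(organ_labels, thorax_mask)
  ref <- refine_pairwise(stacks, transforms, masks, cfg$reg)
  transforms <- ref$transforms
  # resample everything to a common isotropic grid for the similarity metric
  tmpl0 <- build_template(stacks, transforms, masks)
  resampled <- lapply(seq_along(stacks), function(i) {
    resample_onto(stacks[[i]], tmpl0$template, transform = transforms[[i]],
                  fill = NA_real_)
  })
  vols <- vapply(masks, mask_volume_mm3, numeric(1))
  metrics <- compute_stack_metrics(stacks, resampled, vols,
                                   region = tmpl0$mask$data)
  metrics <- apply_inclusion(metrics, cfg$ccor_frac, cfg$csim_frac,
                             cfg$cvol_max)
  reference <- select_reference(metrics)
  inc <- which(metrics$included)
  tmpl <- build_template(stacks[inc], transforms[inc], masks[inc])
  list(transforms = transforms, refined = ref$refined, metrics = metrics,
       reference = reference, included = inc,
       template = tmpl$template, mask = tmpl$mask, thorax_masks = masks)
}

#' Run the automated reconstruction pipeline end to end
#'
#' Executes localisation, landmark reorientation, stack selection and rigid
#' SVR reconstruction on a set of stacks (simulated `stack` objects, or NIfTI
#' paths read with [read_volume()]). Stacks whose trunk is absent are dropped
#' with a logged reason; fewer than `min_stacks` usable stacks produces a
#' warning but not a failure.
#'
#' @param stacks list of `stack`s or character paths to NIfTI files.
#' @param cfg a [pipeline_config()].
#' @return an object of class `fetal_recon`: list with the reconstructed
#'   `volume`, the `svr` result, the selection `metrics` tibble, per-stack
#'   `transforms`, the `template` and `mask`, a structured `log` tibble and
#'   the indices of `included` stacks.
#' @export
run_pipeline <- function(stacks, cfg = pipeline_config()) {
  if (is.character(stacks)) {
    paths <- stacks
    stacks <- lapply(paths, function(p) {
      tryCatch(read_volume(p), error = function(e) {
        abort(sprintf("unreadable stack file '%s': %s", p, conditionMessage(e)))
      })
    })
  }
  if (length(stacks) < 1L) abort("need at least one readable stack")
  logs <- list()

  # package splitting (before Step I) when the slice order is interleaved
  split <- cfg$split_packages
  units <- list(); unit_src <- integer(0)
  for (i in seq_along(stacks)) {
    st <- stacks[[i]]
    interleaved <- inherits(st, "stack") && length(unique(st$packages)) > 1L
    do_split <- isTRUE(split) || (is.null(split) && interleaved)
    if (do_split && inherits(st, "stack")) {
      pk <- split_packages(st)
      units <- c(units, pk)
      unit_src <- c(unit_src, rep(i, length(pk)))
    } else {
      units <- c(units, list(st))
      unit_src <- c(unit_src, i)
    }
  }
  if (length(stacks) < cfg$min_stacks) {
    warn(sprintf("only %d stacks provided; below the recommended minimum of %d",
                 length(stacks), cfg$min_stacks))
  }

  s1 <- step_localise(units, cfg)
  logs[[length(logs) + 1L]] <- s1$log
  if (length(s1$stacks) == 0L) {
    abort("no usable stacks: trunk absent from every stack",
          class = "fetalrecon_no_usable_stacks")
  }
  s2 <- step_pose(s1$stacks, cfg)
  logs[[length(logs) + 1L]] <- s2$log
  keep <- which(s2$keep)
  if (length(keep) == 0L) {
    abort("no usable stacks: landmarks missing in every stack",
          class = "fetalrecon_no_usable_stacks")
  }
  stacks2 <- s1$stacks[keep]
  transforms2 <- s2$transforms[keep]
  organs2 <- s2$organs[keep]

  s3 <- step_select(stacks2, transforms2, organs2, cfg)
  logs[[length(logs) + 1L]] <- tibble::tibble(
    step = "III", stack = seq_along(stacks2),
    event = ifelse(seq_along(stacks2) %in% s3$included, "included", "excluded"),
    reason = s3$metrics$reason)

  svr <- svr_reconstruct(stacks2[s3$included],
                         s3$transforms[s3$included],
                         s3$template, s3$mask, cfg$recon)
  logs[[length(logs) + 1L]] <- tibble::tibble(
    step = "IV", stack = NA_integer_, event = "reconstructed",
    reason = sprintf("%.1f%% slices excluded", svr$excluded_pct))

  structure(list(
    volume = svr$volume, svr = svr, metrics = s3$metrics,
    transforms = s3$transforms, refined = s3$refined,
    reference = s3$reference, included = s3$included,
    template = s3$template, mask = s3$mask,
    stacks = stacks2, unit_source = unit_src[s1$index][keep],
    log = dplyr::bind_rows(logs), config = cfg
  ), class = "fetal_recon")
}

#' @export
print.fetal_recon <- function(x, ...) {
  cat(sprintf(paste0(
    "<fetal_recon> %d stacks processed, %d included, reference %d\n",
    "  output %s voxels at %.3g mm; %.1f%% slices excluded\n"),
    nrow(x$metrics), length(x$included), x$reference,
    paste(dim(x$volume$data), collapse = " x "),
    voxel_spacing(x$volume)[1], x$svr$excluded_pct))
  invisible(x)
}

#' Tidy the per-stack selection metrics of a pipeline run
#' @param x a `fetal_recon` bundle.
#' @param ... unused.
#' @return the selection metrics tibble (one row per processed stack).
#' @importFrom generics tidy
#' @export
tidy.fetal_recon <- function(x, ...) x$metrics

#' One-row summary of a pipeline run
#' @param x a `fetal_recon` bundle.
#' @param ... unused.
#' @return a one-row tibble with stack counts, the reference stack index and
#'   the percentage of excluded slices.
#' @importFrom generics glance
#' @export
glance.fetal_recon <- function(x, ...) {
  tibble::tibble(
    n_stacks = nrow(x$metrics),
    n_included = length(x$included),
    reference = x$reference,
    pct_excluded_slices = x$svr$excluded_pct,
    mean_slice_ncc = mean(x$svr$report$ncc, na.rm = TRUE)
  )
}

#' Recovered-pose errors of a pipeline run against simulator ground truth
#'
#' For each processed (simulated) stack, compares the pipeline's final
#' stack-to-atlas transform with the inverse of the simulated pose.
#'
#' @param bundle a `fetal_recon` from [run_pipeline()] on simulated stacks.
#' @return tibble with `stack`, `rot_err_deg`, `trans_err_mm`, `included`.
#' @export
pipeline_pose_errors <- function(bundle) {
  purrr::map_dfr(seq_along(bundle$stacks), function(i) {
    truth <- stack_truth(bundle$stacks[[i]])
    if (is.null(truth)) {
      return(tibble::tibble(stack = i, rot_err_deg = NA_real_,
                            trans_err_mm = NA_real_,
                            included = i %in% bundle$included))
    }
    pe <- pose_error(bundle$transforms[[i]], truth$pose,
                     point = truth$trunk_centroid)
    tibble::tibble(stack = i, rot_err_deg = pe$rot_err_deg,
                   trans_err_mm = pe$trans_err_mm,
                   included = i %in% bundle$included)
  })
}
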