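#' Rotation capture-range experiment on the phantom
#'
#' Simulates stacks rotated about the trunk centroid by each angle in
#' `angles` (six stacks per angle: positive and negative rotations about each
#' of the x, y and z axes) and registers them to a template stack acquired at
#' identity pose, under three scenarios: `classical` (intensity registration
#' from identity), `landmark` (organ-centroid pose estimation only) and
#' `combined` (intensity registration initialised with the landmark pose).
#' For each registration the masked-thorax NCC against the template and the
#' residual pose error are recorded.
#'
#' @param phantom a `fetal_phantom`.
#' @param angles rotation magnitudes in degrees (default the standard sweep
#'   set `{0, 15, 30, 45, 60, 75, 90, 105, 120, 180}`).
#' @param n_stacks rotated stacks per angle (default 6 = 3 axes x 2 signs).
#' @param acq an [acquisition_spec()] for the simulated stacks.
#' @param reg_cfg a [registration_config()].
#' @param seed base seed for the stack simulations.
#' @return a tibble of class `sweep_result` with one row per
#'   (angle, stack, method): columns `angle`, `stack`, `axis`, `sign`,
#'   `method`, `ncc`, `rot_err_deg`, `trans_err_mm`.
#' @export
rotation_sweep <- function(phantom,
                           angles = c(0, 15, 30, 45, 60, 75, 90, 105, 120, 180),
                           n_stacks = 6L,
                           acq = acquisition_spec(),
                           reg_cfg = registration_config(
                             max_iter = c(40L, 30L, 15L),
                             step_min_mm = 0.02),
                           seed = 1L) {
  backend <- segmenter_backend("oracle")
  atlas <- atlas_reference(phantom$landmarks)
  tm <- sweep_template(phantom, acq, seed)
  rows <- list()
  for (th in angles) {
    for (s in seq_len(n_stacks)) {
      axis <- ((s - 1L) %% 3L) + 1L
      sgn <- if (s > 3L) -1 else 1
      pose <- rt_about_center(axis_rotation_deg(axis, sgn * th),
                              center = phantom$trunk_centroid)
      st <- simulate_stack(phantom, pose, acq, seed = seed + s,
                           slice_axis = axis)
      st <- crop_stack_to_trunk(st, backend)

      lm <- extract_landmarks(segment_organs(st, backend))
      tr_lm <- point_register(lm, atlas$points)

      res_cl <- rigid_register(st, tm$fixed, init = rt_identity(),
                               cfg = reg_cfg, mask = tm$mask)
      res_cb <- rigid_register(st, tm$fixed, init = tr_lm,
                               cfg = reg_cfg, mask = tm$mask)
      for (m in c("classical", "landmark", "combined")) {
        tr <- switch(m, classical = res_cl$transform, landmark = tr_lm,
                     combined = res_cb$transform)
        pe <- pose_error(tr, pose, point = phantom$trunk_centroid)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          angle = th, stack = s, axis = axis, sign = sgn, method = m,
          ncc = sweep_ncc(st, tr, tm),
          rot_err_deg = pe$rot_err_deg, trans_err_mm = pe$trans_err_mm)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}

# template stack at identity pose, resampled isotropically, plus thorax mask
sweep_template <- function(phantom, acq, seed) {
  backend <- segmenter_backend("oracle")
  st <- simulate_stack(phantom, rt_identity(), acq, seed = seed,
                       slice_axis = 3L)
  st <- crop_stack_to_trunk(st, backend)
  fixed <- resample_iso(st, rt_identity(), min(voxel_spacing(st)[1:2]))
  fixed$data[is.na(fixed$data)] <- 0
  tmask <- thorax_mask(phantom$organ_labels)
  mask <- resample_onto(tmask, fixed, method = "nearest", fill = 0)$data != 0
  list(fixed = fixed, mask = mask, stack = st)
}

crop_stack_to_trunk <- function(stack, backend, margin_mm = 15) {
  seg <- segment_global(stack, backend)
  trunk <- largest_component(label_mask(seg, "trunk"))
  crop_to_roi(stack, trunk, margin_mm)
}

# masked NCC of a stack resampled under its transform onto the template grid
sweep_ncc <- function(stack, transform, tm) {
  r <- resample_onto(stack, tm$fixed, transform = transform, fill = NA_real_)
  ncc(r$data, tm$fixed$data, region = tm$mask & !is.na(r$data))
}

#' Summarise a rotation sweep per angle and method
#' @param sweep a `sweep_result` from [rotation_sweep()].
#' @return tibble with per (angle, method) mean/sd NCC and mean pose errors.
#' @export
sweep_summary <- function(sweep) {
  dplyr::summarise(
    dplyr::group_by(sweep, .data$angle, .data$method),
    ncc_mean = mean(.data$ncc), ncc_sd = stats::sd(.data$ncc),
    rot_err_mean = mean(.data$rot_err_deg),
    trans_err_mean = mean(.data$trans_err_mm),
    .groups = "drop")
}

#' @export
autoplot.sweep_result <- function(object, ...) {
  sm <- sweep_summary(object)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$angle, y = .data$ncc_mean,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ncc_mean - .data$ncc_sd,
                                      ymax = .data$ncc_mean + .data$ncc_sd,
                                      fill = .data$method),
                         alpha = 0.2, colour = NA) +
    ggplot2::labs(x = "simulated rotation (degrees)",
                  y = "masked thorax NCC vs template",
                  title = "Rotation capture range") +
    ggplot2::theme_minimal()
}

#' Pipeline ablation experiment on severe-motion phantom datasets
#'
#' Builds `n_datasets` synthetic datasets of `n_stacks` stacks each with
#' large (> 90 degree) inter-stack rotations, splits each stack into
#' interleaved acquisition packages, and reconstructs each dataset under
#' three scenarios: localisation only (`I+IV`), localisation plus atlas
#' reorientation (`I+II+IV`), and the full pipeline with stack selection and
#' median template (`I+II+III+IV`). In the non-selection scenarios the
#' template is the least motion-corrupted stack (highest sequential-slice
#' NCC). Two stacks per dataset carry heavy per-slice jitter and noise,
#' emulating severely corrupted acquisitions.
#'
#' @param phantom a `fetal_phantom`.
#' @param n_datasets number of simulated datasets (default 3).
#' @param n_stacks stacks per dataset (default 6).
#' @param acq base [acquisition_spec()] (interleaved; its package count is
#'   used for splitting).
#' @param recon a [recon_config()].
#' @param reg a [registration_config()].
#' @param seed base seed.
#' @return a tibble of class `ablation_result` with one row per
#'   (dataset, scenario): `pct_excluded`, `ncc_all` (mean simulated-vs-
#'   original slice NCC) and `ncc_heldout` (mean slice NCC of a held-out
#'   stack in the template position).
#' @export
run_ablation <- function(phantom, n_datasets = 3L, n_stacks = 6L,
                         acq = acquisition_spec(),
                         recon = recon_config(),
                         reg = registration_config(),
                         seed = 1L) {
  rows <- list()
  for (d in seq_len(n_datasets)) {
    ds <- simulate_ablation_dataset(phantom, n_stacks, acq, seed * 1000 + d)
    for (sc in c("I+IV", "I+II+IV", "I+II+III+IV")) {
      res <- scenario_recon(ds, sc, phantom, recon, reg)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        dataset = d, scenario = sc,
        pct_excluded = res$pct_excluded,
        ncc_all = res$ncc_all,
        ncc_heldout = res$ncc_heldout)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$scenario <- factor(out$scenario,
                         levels = c("I+IV", "I+II+IV", "I+II+III+IV"))
  class(out) <- c("ablation_result", class(out))
  out
}

# severe-motion dataset: first stack near identity, others rotated > 90 deg,
# the last two heavily corrupted by per-slice jitter and noise
simulate_ablation_dataset <- function(phantom, n_stacks, acq, seed) {
  set.seed(seed)
  stacks <- vector("list", n_stacks)
  poses <- vector("list", n_stacks)
  for (s in seq_len(n_stacks)) {
    poses[[s]] <- if (s == 1L) {
      rt_identity()
    } else {
      ang <- stats::runif(1, 95, 150)
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      tr <- stats::runif(3, -10, 10)
      rt_about_center(rotation_about_axis(ax, ang), tr,
                      phantom$trunk_centroid)
    }
  }
  for (s in seq_len(n_stacks)) {
    acq_s <- acq
    if (s > n_stacks - 2L) {
      acq_s$jitter_rot_deg <- 12
      acq_s$jitter_trans_mm <- 6
      acq_s$noise_sigma <- 40
    } else {
      acq_s$noise_sigma <- 2
    }
    stacks[[s]] <- simulate_stack(phantom, poses[[s]], acq_s,
                                  seed = seed + s,
                                  slice_axis = ((s - 1L) %% 3L) + 1L)
  }
  list(stacks = stacks, poses = poses, acq = acq, seed = seed)
}

#' Rotation matrix about an arbitrary unit axis
#' @param axis unit length-3 vector.
#' @param deg angle in degrees.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
rotation_about_axis <- function(axis, deg) {
  th <- deg * pi / 180
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# one ablation scenario: returns excluded %, all-slice NCC and held-out NCC
scenario_recon <- function(ds, scenario, phantom, recon, reg) {
  backend <- segmenter_backend("oracle")
  cfg <- pipeline_config(backend = backend, recon = recon, reg = reg,
                         split_packages = TRUE)
  atlas <- atlas_reference(phantom$landmarks)

  # package splitting + Step I for all scenarios
  units <- list(); srcs <- integer(0)
  for (i in seq_along(ds$stacks)) {
    pk <- split_packages(ds$stacks[[i]])
    units <- c(units, pk)
    srcs <- c(srcs, rep(i, length(pk)))
  }
  s1 <- step_localise(units, cfg)
  stacks <- s1$stacks
  srcs <- srcs[s1$index]
  trunk_masks <- s1$trunk_masks

  if (scenario == "I+IV") {
    transforms <- replicate(length(stacks), rt_identity(), simplify = FALSE)
    ccor <- vapply(stacks, motion_score, numeric(1))
    tpl_i <- which.max(ccor)
    tpl <- resample_iso(stacks[[tpl_i]], rt_identity(),
                        min(voxel_spacing(stacks[[tpl_i]])[1:2]))
    tpl$data[is.na(tpl$data)] <- 0
    mask <- resample_onto(trunk_masks[[tpl_i]], tpl, method = "nearest",
                          fill = 0)
    mask <- label_map(array(as.integer(mask$data != 0), dim(mask$data)),
                      mask$affine, c(thorax = 1L))
    svr <- svr_reconstruct(stacks, transforms, tpl, mask, recon)
    held_tr <- rt_identity()
    held_pose <- ds$poses[[srcs[tpl_i]]]
  } else {
    s2 <- step_pose(stacks, cfg)
    keep <- which(s2$keep)
    stacks <- stacks[keep]; srcs <- srcs[keep]
    transforms <- s2$transforms[keep]
    organs <- s2$organs[keep]
    if (scenario == "I+II+IV") {
      ccor <- vapply(stacks, motion_score, numeric(1))
      tpl_i <- which.max(ccor)
      tpl <- resample_iso(stacks[[tpl_i]], transforms[[tpl_i]],
                          min(voxel_spacing(stacks[[tpl_i]])[1:2]))
      tpl$data[is.na(tpl$data)] <- 0
      mask <- resample_onto(thorax_mask(organs[[tpl_i]]), tpl,
                            transform = transforms[[tpl_i]],
                            method = "nearest", fill = 0)
      mask <- label_map(array(as.integer(mask$data != 0), dim(mask$data)),
                        mask$affine, c(thorax = 1L))
      svr <- svr_reconstruct(stacks, transforms, tpl, mask, recon)
      held_tr <- rt_invert(ds$poses[[srcs[tpl_i]]])
      held_pose <- ds$poses[[srcs[tpl_i]]]
    } else {
      s3 <- step_select(stacks, transforms, organs, cfg)
      svr <- svr_reconstruct(stacks[s3$included],
                             s3$transforms[s3$included],
                             s3$template, s3$mask, recon)
      ref_src <- srcs[s3$included[1]]
      held_tr <- rt_invert(ds$poses[[ref_src]])
      held_pose <- ds$poses[[ref_src]]
    }
  }

  # held-out stack: acquired in (approximately) the template position and
  # never fed to the reconstruction
  held <- simulate_stack(phantom, held_pose, ds$acq, seed = ds$seed + 99L,
                         slice_axis = 3L)
  held <- crop_stack_to_trunk(held, backend)
  ncc_held <- heldout_slice_ncc(svr, held, held_tr)

  list(pct_excluded = svr$excluded_pct,
       ncc_all = mean(svr$report$ncc, na.rm = TRUE),
       ncc_heldout = ncc_held)
}

# mean per-slice NCC between a held-out stack and its projection through the
# reconstructed volume, over the pixels well inside the reconstruction mask
heldout_slice_ncc <- function(svr, held, transform) {
  cfg <- svr$config
  dims <- dim(svr$volume$data)
  model <- build_slice_model(list(held), list(transform), svr$volume, cfg)
  m <- model[[1]]
  proj <- project_model(svr$volume$data, dims, model)[[1]]
  mnum <- as.numeric(svr$mask$data != 0)
  dim(mnum) <- dims
  mproj <- c_project_slices(mnum, dims, m$maps, m$offsets, m$weights,
                            m$nx, m$ny, 0)
  vals <- vapply(seq_len(m$n_slices), function(k) {
    px <- mproj[[k]] > 0.85
    if (sum(px) < 64L) return(NA_real_)
    y <- m$data[[k]][px]
    p <- proj[[k]][px]
    if (stats::sd(y) == 0 || stats::sd(p) == 0) return(NA_real_)
    stats::cor(y, p)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' @export
autoplot.ablation_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$scenario,
                                       y = .data$pct_excluded)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$dataset))) +
    ggplot2::labs(x = "pipeline scenario", y = "% slices excluded",
                  colour = "dataset",
                  title = "Slice rejection across pipeline ablations") +
    ggplot2::theme_minimal()
}
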