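#' Configuration of the intensity-based rigid registration engine
#'
#' Multiresolution (coarse-to-fine pyramid) maximisation of masked NCC over
#' the 6 rigid parameters by regular-step gradient ascent. Rotation
#' parameters are internally scaled so that one step unit moves a point at
#' the ROI radius by about 1 mm, which balances the rotation and translation
#' search directions.
#'
#' @param levels integer pyramid downsampling factors, coarse to fine.
#' @param max_iter gradient iterations per level (recycled to match levels).
#' @param step_mm initial step length per level, in mm-equivalent units.
#' @param step_min_mm step length below which a level is converged.
#' @param grad_delta_mm finite-difference step for the gradient.
#' @param rot_scale_mm ROI radius used to scale rotations (NULL = derive from
#'   the fixed image / mask extent).
#' @return an object of class `registration_config`.
#' @export
registration_config <- function(levels = c(4L, 2L, 1L),
                                max_iter = c(30L, 20L, 10L),
                                step_mm = c(8, 4, 2),
                                step_min_mm = 0.05,
                                grad_delta_mm = 0.5,
                                rot_scale_mm = NULL) {
  if (length(levels) < 1L) abort("need at least one pyramid level")
  if (step_min_mm <= 0 || grad_delta_mm <= 0) abort("tolerances must be > 0")
  structure(list(
    levels = as.integer(levels),
    max_iter = rep_len(as.integer(max_iter), length(levels)),
    step_mm = rep_len(as.numeric(step_mm), length(levels)),
    step_min_mm = step_min_mm, grad_delta_mm = grad_delta_mm,
    rot_scale_mm = rot_scale_mm
  ), class = "registration_config")
}

#' Intensity-based rigid registration of two volumes
#'
#' Locally maximises masked NCC over the 6 rigid parameters, starting from
#' `init`, with a multiresolution pyramid and regular-step gradient ascent.
#' Deterministic given its inputs: the similarity never decreases across
#' accepted steps, and the recovered transform maps moving-image world
#' coordinates into fixed-image world coordinates.
#'
#' @param moving,fixed [image_volume()]s.
#' @param init initial [rigid_transform()] (moving world -> fixed world).
#' @param cfg a [registration_config()].
#' @param mask optional region (logical/numeric array on the fixed grid)
#'   over which the similarity is evaluated.
#' @param center rotation centre in fixed-world mm (default: mask centroid,
#'   or the fixed volume centre).
#' @return list with `transform` (the refined [rigid_transform()]),
#'   `similarity` (final NCC), `init_similarity` (NCC at `init`), `history`
#'   (accepted similarity values) and `converged`.
#' @export
rigid_register <- function(moving, fixed, init = rt_identity(),
                           cfg = registration_config(), mask = NULL,
                           center = NULL) {
  if (is.null(center)) {
    center <- if (!is.null(mask) && any(mask != 0)) {
      idx <- which(mask != 0, arr.ind = TRUE)
      drop(colMeans(voxel_to_world(fixed, idx)))
    } else {
      volume_center(fixed)
    }
  }
  rot_scale <- cfg$rot_scale_mm
  if (is.null(rot_scale)) {
    ext <- dim(fixed$data) * voxel_spacing(fixed)
    rot_scale <- max(ext) / 4
  }
  deg_per_unit <- 180 / (pi * rot_scale)

  param_rt <- function(q) {
    rt_about_center(euler_deg(q[1:3] * deg_per_unit), q[4:6], center)
  }

  q <- rep(0, 6)
  init_sim <- NULL
  history <- numeric(0)
  for (lev in seq_along(cfg$levels)) {
    f <- cfg$levels[lev]
    fx <- if (f > 1L) downsample_volume(fixed, f) else fixed
    mk <- NULL
    if (!is.null(mask)) {
      m <- image_volume(array(as.numeric(mask != 0), dim(fixed$data)),
                        fixed$affine)
      mk <- if (f > 1L) downsample_volume(m, f)$data > 0.25 else m$data > 0
    }
    fdat <- fx$data
    obj <- function(q) {
      tr <- rt_compose(param_rt(q), init)
      res <- resample_onto(moving, fx, transform = tr, fill = NA_real_)
      region <- !is.na(res$data)
      region <- if (is.null(mk)) region & res$data != 0 & fdat != 0 else region & mk
      if (sum(region) < 16L) return(-Inf)
      x <- res$data[region]; y <- fdat[region]
      sx <- stats::sd(x); sy <- stats::sd(y)
      if (sx == 0 || sy == 0) return(0)
      v <- mean((x - mean(x)) * (y - mean(y))) * length(x) / (length(x) - 1) / (sx * sy)
      if (!is.finite(v)) return(-Inf)
      v
    }

    cur <- obj(q)
    if (lev == 1L) {
      init_sim <- cur
      if (!is.finite(cur)) {
        abort("empty overlap between moving and fixed at initialisation",
              class = "fetalrecon_empty_overlap")
      }
    }
    step <- cfg$step_mm[lev]
    delta <- cfg$grad_delta_mm
    for (it in seq_len(cfg$max_iter[lev])) {
      g <- numeric(6)
      for (p in 1:6) {
        e <- numeric(6); e[p] <- delta
        g[p] <- (obj(q + e) - obj(q - e)) / (2 * delta)
      }
      gn <- sqrt(sum(g^2))
      if (!is.finite(gn) || gn == 0) break
      d <- g / gn
      accepted <- FALSE
      while (step >= cfg$step_min_mm) {
        cand <- q + step * d
        val <- obj(cand)
        if (is.finite(val) && val > cur) {
          q <- cand; cur <- val; accepted <- TRUE
          history <- c(history, cur)
          break
        }
        step <- step / 2
      }
      if (!accepted) break
    }
  }
  final <- rt_compose(param_rt(q), init)
  list(transform = final, similarity = cur, init_similarity = init_sim,
       history = history, converged = is.finite(cur))
}
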