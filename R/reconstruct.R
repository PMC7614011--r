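#' Configuration of the rigid SVR super-resolution backend
#'
#' A simplified rigid slice-to-volume super-resolution reconstruction: outer
#' iterations alternate (i) rigid per-slice registration to the evolving
#' volume, (ii) EM re-estimation of robust slice weights from a
#' Gaussian-inlier + uniform-outlier mixture on slice residuals, and (iii) a
#' super-resolution update minimising the robust PSF-projection least squares
#' with an edge-preserving (Huber) smoothness penalty.
#'
#' @param output_resolution_mm isotropic output voxel size (default 0.7).
#' @param n_outer number of outer iterations (>= 1).
#' @param lambda edge-preserving regularisation weight (relative units).
#' @param huber_delta Huber threshold as a fraction of the robust intensity
#'   scale.
#' @param weight_threshold robust weight below which a slice counts as
#'   excluded (default 0.5).
#' @param sr_iter super-resolution gradient iterations per outer iteration.
#' @param sr_step initial relative step of the super-resolution update.
#' @param slice_reg logical: run per-slice rigid registration refinement.
#' @param slice_reg_iter gradient iterations of the per-slice registration.
#' @param psf_samples quadrature points of the separable Gaussian PSF along
#'   (in-plane u, in-plane v, through-plane); the through-plane FWHM is the
#'   slice thickness and the in-plane FWHM the in-plane spacing.
#' @param mask_dilate_mm dilation of the thorax mask defining the
#'   reconstruction region.
#' @return an object of class `recon_config`.
#' @export
recon_config <- function(output_resolution_mm = 0.7, n_outer = 3L,
                         lambda = 0.02, huber_delta = 0.1,
                         weight_threshold = 0.5, sr_iter = 8L, sr_step = 1,
                         slice_reg = TRUE, slice_reg_iter = 4L,
                         psf_samples = c(1L, 1L, 5L), mask_dilate_mm = 5) {
  if (output_resolution_mm <= 0) abort("resolution must be > 0")
  if (n_outer < 1L) abort("need at least one outer iteration")
  structure(list(
    output_resolution_mm = output_resolution_mm, n_outer = as.integer(n_outer),
    lambda = lambda, huber_delta = huber_delta,
    weight_threshold = weight_threshold, sr_iter = as.integer(sr_iter),
    sr_step = sr_step, slice_reg = slice_reg,
    slice_reg_iter = as.integer(slice_reg_iter),
    psf_samples = as.integer(psf_samples), mask_dilate_mm = mask_dilate_mm
  ), class = "recon_config")
}

# Gaussian quadrature nodes/weights for one PSF axis
psf_axis_quad <- function(fwhm_mm, n) {
  if (n <= 1L) return(list(off = 0, w = 1))
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  off <- sigma * seq(-2, 2, length.out = n)
  w <- stats::dnorm(off, sd = sigma)
  list(off = off, w = w / sum(w))
}

# Build per-slice projection geometry for a set of stacks in atlas space.
# Returns a list per stack: maps/offsets lists (one per slice), shared
# quadrature weights, slice data, in-slice mask, and a metadata tibble.
build_slice_model <- function(stacks, transforms, out, cfg) {
  Aout_inv <- solve(out$affine)
  model <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    st <- stacks[[i]]
    tr <- transforms[[i]]
    A <- st$affine
    nz <- dim(st$data)[3]
    qu <- psf_axis_quad(voxel_spacing(st)[1], cfg$psf_samples[1])
    qv <- psf_axis_quad(voxel_spacing(st)[2], cfg$psf_samples[2])
    qt <- psf_axis_quad(st$slice_thickness_mm, cfg$psf_samples[3])
    grid <- expand.grid(u = seq_along(qu$off), v = seq_along(qv$off),
                        t = seq_along(qt$off))
    weights <- qu$w[grid$u] * qv$w[grid$v] * qt$w[grid$t]
    # unit slice directions in stack world
    dirs <- sweep(A[1:3, 1:3], 2, sqrt(colSums(A[1:3, 1:3]^2)), "/")
    maps <- vector("list", nz)
    offs <- vector("list", nz)
    W <- rt_as_affine(tr)
    Rw <- tr$R
    lin <- Aout_inv[1:3, 1:3] %*% Rw %*% dirs   # world dirs -> out voxel units
    offmat <- lin[, 1, drop = FALSE] %*% t(qu$off[grid$u]) +
      lin[, 2, drop = FALSE] %*% t(qv$off[grid$v]) +
      lin[, 3, drop = FALSE] %*% t(qt$off[grid$t])
    for (k in seq_len(nz)) {
      shift <- diag(4); shift[3, 4] <- k - 1
      maps[[k]] <- Aout_inv %*% W %*% A %*% shift
      offs[[k]] <- offmat
    }
    model[[i]] <- list(
      stack = i, maps = maps, offsets = offs, weights = weights,
      data = lapply(seq_len(nz), function(k) st$data[, , k]),
      packages = st$packages,
      nx = dim(st$data)[1], ny = dim(st$data)[2], n_slices = nz
    )
  }
  model
}

# forward-project the current volume through every slice of the model
project_model <- function(x, vdim, model) {
  lapply(model, function(m) {
    c_project_slices(x, vdim, m$maps, m$offsets, m$weights, m$nx, m$ny, 0)
  })
}

huber_energy <- function(x, delta) {
  e <- 0
  for (ax in 1:3) {
    d <- axis_diff(x, ax)
    a <- abs(d)
    e <- e + sum(ifelse(a <= delta, 0.5 * d^2, delta * a - 0.5 * delta^2))
  }
  e
}

# gradient of the Huber energy: for forward differences d_i = x_{i+1} - x_i
# with psi = rho', dE/dx_j = psi(d_{j-1}) - psi(d_j)
huber_gradient <- function(x, delta) {
  g <- array(0, dim(x))
  for (ax in 1:3) {
    d <- axis_diff(x, ax)
    w <- pmin(1, delta / pmax(abs(d), 1e-12))
    fl <- w * d
    g <- g + (axis_shift_back(fl, ax) - fl)
  }
  g
}

# forward difference along an axis (last plane zero)
axis_diff <- function(x, ax) {
  d <- array(0, dim(x))
  n <- dim(x)[ax]
  idx1 <- slice_index(dim(x), ax, 1:(n - 1))
  idx2 <- slice_index(dim(x), ax, 2:n)
  d[idx1$i, idx1$j, idx1$k] <- x[idx2$i, idx2$j, idx2$k] - x[idx1$i, idx1$j, idx1$k]
  d
}

slice_index <- function(d, ax, r) {
  i <- seq_len(d[1]); j <- seq_len(d[2]); k <- seq_len(d[3])
  if (ax == 1) i <- r else if (ax == 2) j <- r else k <- r
  list(i = i, j = j, k = k)
}

# divergence helper terms: flow shifted back along axis
axis_shift_back <- function(fl, ax) {
  out <- array(0, dim(fl))
  n <- dim(fl)[ax]
  dst <- slice_index(dim(fl), ax, 2:n)
  src <- slice_index(dim(fl), ax, 1:(n - 1))
  out[dst$i, dst$j, dst$k] <- fl[src$i, src$j, src$k]
  out
}

#' Rigid slice-to-volume super-resolution reconstruction
#'
#' Reconstructs an isotropic high-resolution volume of the thorax region from
#' the included, reoriented stacks. Each outer iteration performs per-slice
#' rigid registration to the current volume (initialised from the stack
#' transforms), robust EM slice weighting (Gaussian inliers + uniform
#' outliers on normalised slice residuals) and a monotone super-resolution
#' update of the PSF-projection least squares with Huber edge-preserving
#' smoothness. The output is masked to the dilated thorax mask.
#'
#' @param stacks list of `stack`s (native grids).
#' @param transforms list of [rigid_transform()]s (stack world -> atlas).
#' @param template an [image_volume()] used to initialise the volume.
#' @param mask binary thorax [label_map()] in atlas space.
#' @param cfg a [recon_config()].
#' @return an object of class `svr_result`: list with `volume`
#'   (the reconstruction), `report` (per-slice tibble: `stack`, `slice`,
#'   `package`, `score`, `weight`, `excluded`, `ncc`), `excluded_pct`,
#'   `history` (per-outer-iteration objective values) and `config`.
#' @export
svr_reconstruct <- function(stacks, transforms, template, mask,
                            cfg = recon_config()) {
  if (length(stacks) < 1L) abort("need at least one stack")
  res <- cfg$output_resolution_mm
  dm <- dilate_mask(mask, cfg$mask_dilate_mm)
  idx <- which(dm$data != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("empty reconstruction mask")
  w <- voxel_to_world(dm, idx)
  lo <- apply(w, 2, min) - res
  hi <- apply(w, 2, max) + res
  dims <- pmax(4L, as.integer(ceiling((hi - lo) / res)) + 1L)
  A <- diag(c(res, res, res, 1))
  A[1:3, 4] <- lo
  out_geom <- image_volume(array(0, dims), A)
  mvol <- resample_onto(dm, out_geom, method = "nearest", fill = 0)
  inmask <- mvol$data != 0
  x <- resample_onto(template, out_geom, fill = 0)$data
  x[!inmask] <- 0
  x[x < 0] <- 0

  model <- build_slice_model(stacks, transforms, out_geom, cfg)
  # per-slice pixel masks: pixels whose projection hits the recon mask
  mnum <- as.numeric(inmask)
  dim(mnum) <- dims
  mask_px <- lapply(model, function(m) {
    pr <- c_project_slices(mnum, dims, m$maps, m$offsets, m$weights,
                           m$nx, m$ny, 0)
    lapply(pr, function(p) p > 0.85)
  })
  n_slices <- sum(vapply(model, function(m) m$n_slices, integer(1)))
  scale <- stats::median(unlist(lapply(seq_along(model), function(i) {
    vapply(seq_len(model[[i]]$n_slices), function(k) {
      v <- model[[i]]$data[[k]][mask_px[[i]][[k]]]
      if (length(v) < 2) NA_real_ else sqrt(mean(v^2))
    }, numeric(1))
  })), na.rm = TRUE)
  if (!is.finite(scale) || scale == 0) scale <- 1

  weights <- rep(1, n_slices)
  history <- tibble::tibble(outer = integer(), obj_before = numeric(),
                            obj_after = numeric(), n_excluded = integer())
  hub_delta <- cfg$huber_delta * scale

  # slice residual score: 1 - NCC between the PSF-projected volume and the
  # observed slice over the in-mask pixels (scale-free and content-adaptive,
  # so heterogeneous slice content does not masquerade as an outlier)
  slice_scores <- function(proj) {
    s <- numeric(n_slices); idx0 <- 0L
    for (i in seq_along(model)) {
      for (k in seq_len(model[[i]]$n_slices)) {
        idx0 <- idx0 + 1L
        px <- mask_px[[i]][[k]]
        if (sum(px) < 64L) { s[idx0] <- NA_real_; next }
        y <- model[[i]]$data[[k]][px]
        p <- proj[[i]][[k]][px]
        sy <- stats::sd(y); sp <- stats::sd(p)
        # slices with almost no in-mask contrast carry no usable structure;
        # they are reported as non-evaluable rather than scored
        if (sy < 0.1 * scale) { s[idx0] <- NA_real_; next }
        if (sy == 0 || sp == 0) { s[idx0] <- 1; next }
        r <- mean((y - mean(y)) * (p - mean(p))) * length(y) /
          (length(y) - 1) / (sy * sp)
        s[idx0] <- 1 - r
      }
    }
    s
  }
  data_objective <- function(proj, w_s) {
    e <- 0; idx0 <- 0L
    for (i in seq_along(model)) {
      for (k in seq_len(model[[i]]$n_slices)) {
        idx0 <- idx0 + 1L
        px <- mask_px[[i]][[k]]
        if (sum(px) < 8L) next
        r <- model[[i]]$data[[k]][px] - proj[[i]][[k]][px]
        e <- e + w_s[idx0] * sum(r^2)
      }
    }
    e
  }
  total_objective <- function(proj, w_s, xcur) {
    data_objective(proj, w_s) + cfg$lambda * huber_energy(xcur, hub_delta)
  }

  for (outer in seq_len(cfg$n_outer)) {
    # (i) per-slice rigid registration refinement
    if (cfg$slice_reg && outer > 1L) {
      model <- refine_slice_transforms(model, x, dims, cfg, mask_px)
    }
    proj <- project_model(x, dims, model)
    scores <- slice_scores(proj)
    weights <- em_slice_weights(scores)
    excluded <- weights < cfg$weight_threshold
    obj_before <- total_objective(proj, weights, x)

    # (iii) super-resolution update (monotone in the weighted objective)
    step <- cfg$sr_step
    obj_cur <- obj_before
    for (it in seq_len(cfg$sr_iter)) {
      step <- min(step * 2, cfg$sr_step)
      resid <- make_residuals(model, proj, mask_px)
      bp <- backproject_model(resid, model, weights, dims)
      corr <- bp$num / pmax(bp$mass, 1e-6)
      corr[bp$mass < 1e-6] <- 0
      upd <- corr - cfg$lambda * huber_gradient(x, hub_delta) /
        pmax(max(bp$mass), 1e-6)
      accepted <- FALSE
      while (step > 1e-3) {
        xc <- x + step * upd
        xc[xc < 0] <- 0
        xc[!inmask] <- 0
        pc <- project_model(xc, dims, model)
        oc <- total_objective(pc, weights, xc)
        if (oc < obj_cur) {
          x <- xc; proj <- pc; obj_cur <- oc; accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) break
    }
    history <- dplyr::bind_rows(history, tibble::tibble(
      outer = outer, obj_before = obj_before, obj_after = obj_cur,
      n_excluded = sum(excluded, na.rm = TRUE)
    ))
  }

  # final report
  proj <- project_model(x, dims, model)
  scores <- slice_scores(proj)
  weights <- em_slice_weights(scores)
  report <- slice_report(model, proj, mask_px, scores, weights,
                         cfg$weight_threshold)
  if (all(report$excluded, na.rm = TRUE) && !all(is.na(report$excluded))) {
    cnd <- rlang::error_cnd("fetalrecon_all_slices_excluded",
                            message = "all slices rejected by robust weighting",
                            report = report)
    rlang::cnd_signal(cnd)
  }
  vol <- image_volume(x, A)
  structure(list(
    volume = vol, report = report,
    excluded_pct = 100 * mean(report$excluded, na.rm = TRUE),
    history = history, mask = mvol, config = cfg
  ), class = "svr_result")
}

make_residuals <- function(model, proj, mask_px) {
  lapply(seq_along(model), function(i) {
    lapply(seq_len(model[[i]]$n_slices), function(k) {
      r <- model[[i]]$data[[k]] - proj[[i]][[k]]
      r[!mask_px[[i]][[k]]] <- NA_real_
      r
    })
  })
}

backproject_model <- function(resid, model, weights, dims) {
  num <- array(0, dims)
  mass <- array(0, dims)
  idx0 <- 0L
  for (i in seq_along(model)) {
    ns <- model[[i]]$n_slices
    sw <- weights[idx0 + seq_len(ns)]
    idx0 <- idx0 + ns
    bp <- c_backproject_slices(resid[[i]], model[[i]]$maps,
                               model[[i]]$offsets, model[[i]]$weights,
                               sw, dims)
    num <- num + bp$num
    mass <- mass + bp$mass
  }
  list(num = num, mass = mass)
}

# EM fit of a Gaussian(inlier) + uniform(outlier) mixture on slice residual
# scores; returns posterior inlier probabilities. Scores are scale-free
# (already normalised), so decisions are invariant to intensity scaling.
em_slice_weights <- function(scores, n_iter = 20L) {
  w <- rep(0, length(scores))
  ok <- which(is.finite(scores))
  if (length(ok) == 0L) return(w)
  e <- scores[ok]
  if (length(ok) < 3L || stats::sd(e) < 1e-9) {
    w[ok] <- 1
    return(w)
  }
  # outlier component: uniform over the full support of the score 1 - NCC.
  # The inlier Gaussian is initialised on the low-residual quantile so that,
  # when most slices disagree with the volume, the component locks onto the
  # best-fitting subpopulation rather than the corrupted majority.
  u <- 1 / 2
  mu <- unname(stats::quantile(e, 0.1))
  low <- e[e <= stats::median(e)]
  sigma <- min(max(1.4826 * stats::mad(low, center = mu), 0.01), 0.08)
  pi_in <- 0.5
  g <- rep(0.5, length(e))
  for (it in seq_len(n_iter)) {
    din <- stats::dnorm(e, mu, sigma)
    g <- pi_in * din / (pi_in * din + (1 - pi_in) * u + 1e-300)
    sg <- sum(g)
    if (sg < 1e-9) break
    mu_new <- sum(g * e) / sg
    sigma <- sqrt(sum(g * (e - mu_new)^2) / sg)
    # width prior on the inlier component: slices that agree with the volume
    # do so within a narrow NCC band; without the cap a diffuse "inlier"
    # component can absorb uniformly misregistered slices
    sigma <- min(max(sigma, 0.005), 0.08)
    # inliers are the low-residual mode: anchor the mean at or below median
    mu <- min(mu_new, stats::median(e))
    pi_in <- min(max(sg / length(e), 0.05), 0.98)
  }
  w[ok] <- g
  w
}

slice_report <- function(model, proj, mask_px, scores, weights, threshold) {
  rows <- list()
  idx0 <- 0L
  for (i in seq_along(model)) {
    for (k in seq_len(model[[i]]$n_slices)) {
      idx0 <- idx0 + 1L
      px <- mask_px[[i]][[k]]
      evaluable <- is.finite(scores[idx0])
      rows[[idx0]] <- tibble::tibble(
        stack = i, slice = k, package = model[[i]]$packages[k],
        score = scores[idx0], weight = weights[idx0],
        # slices whose projection misses the reconstruction mask carry no
        # information and are left out of the exclusion statistics (NA)
        excluded = if (evaluable) weights[idx0] < threshold else NA,
        ncc = if (evaluable) 1 - scores[idx0] else NA_real_
      )
    }
  }
  dplyr::bind_rows(rows)
}

# small per-slice rigid refinement against the current volume, over the
# in-mask pixels only
refine_slice_transforms <- function(model, x, dims, cfg, mask_px) {
  for (i in seq_along(model)) {
    m <- model[[i]]
    for (k in seq_len(m$n_slices)) {
      y <- m$data[[k]]
      px <- mask_px[[i]][[k]]
      if (sum(px) < 64L) next
      yv <- y[px]
      sy <- stats::sd(yv)
      if (sy == 0) next
      base <- m$maps[[k]]
      ctr <- drop(base %*% c((m$nx - 1) / 2, (m$ny - 1) / 2, 0, 1))[1:3]
      obj <- function(dq) {
        Mk <- perturb_map(base, dq, ctr)
        p <- c_project_slices(x, dims, list(Mk), list(m$offsets[[k]]),
                              m$weights, m$nx, m$ny, 0)[[1]]
        b <- p[px]
        sb <- stats::sd(b)
        if (sb == 0) return(0)
        mean((yv - mean(yv)) * (b - mean(b))) * length(b) / (length(b) - 1) /
          (sy * sb)
      }
      q <- rep(0, 6)
      cur <- obj(q)
      if (!is.finite(cur)) next
      step <- 0.5
      for (it in seq_len(cfg$slice_reg_iter)) {
        g <- numeric(6)
        for (p in 1:6) {
          e <- numeric(6); e[p] <- 0.1
          g[p] <- (obj(q + e) - obj(q - e)) / 0.2
        }
        gn <- sqrt(sum(g^2))
        if (!is.finite(gn) || gn == 0) break
        d <- g / gn
        accepted <- FALSE
        while (step >= 0.05) {
          cand <- q + step * d
          val <- obj(cand)
          if (is.finite(val) && val > cur) {
            q <- cand; cur <- val; accepted <- TRUE; break
          }
          step <- step / 2
        }
        if (!accepted) break
      }
      if (any(q != 0)) model[[i]]$maps[[k]] <- perturb_map(base, q, ctr)
    }
  }
  model
}

# apply a small voxel-space rigid perturbation (rotations in degrees about
# `ctr`, translations in output voxels) to a slice map
perturb_map <- function(M, q, ctr) {
  Rm <- euler_deg(q[1:3])
  P <- diag(4)
  P[1:3, 1:3] <- Rm
  P[1:3, 4] <- q[4:6] + ctr - Rm %*% ctr
  P %*% M
}

#' @export
print.svr_result <- function(x, ...) {
  cat(sprintf("<svr_result> %s voxels at %.3g mm, %.1f%% slices excluded\n",
              paste(dim(x$volume$data), collapse = " x "),
              voxel_spacing(x$volume)[1], x$excluded_pct))
  invisible(x)
}

#' Per-slice weight report of a reconstruction
#' @param x an `svr_result`.
#' @param ... unused.
#' @return the per-slice tibble (`stack`, `slice`, `package`, `score`,
#'   `weight`, `excluded`, `ncc`).
#' @export
tidy.svr_result <- function(x, ...) x$report

#' One-row summary of a reconstruction
#' @param x an `svr_result`.
#' @param ... unused.
#' @return a one-row tibble with slice counts, total and per-stack maximum
#'   exclusion percentages and the mean slice NCC.
#' @export
glance.svr_result <- function(x, ...) {
  per_stack <- dplyr::summarise(
    dplyr::group_by(x$report, .data$stack),
    pct = 100 * mean(.data$excluded, na.rm = TRUE))
  tibble::tibble(
    n_slices = nrow(x$report),
    n_evaluable = sum(is.finite(x$report$score)),
    pct_excluded = x$excluded_pct,
    max_stack_pct_excluded = max(per_stack$pct, na.rm = TRUE),
    mean_slice_ncc = mean(x$report$ncc, na.rm = TRUE)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.svr_result <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$slice, y = .data$weight,
                               colour = .data$excluded)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~stack, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "slice", y = "robust weight",
                  title = "Per-slice robust inclusion weights") +
    ggplot2::theme_minimal()
}
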