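test_that("landmark extraction subtracts contained organs before centroids", {
  ph <- fx_phantom()
  lm <- extract_landmarks(ph$organ_labels)
  expect_equal(rownames(lm$points), c("thorax", "abdomen", "heart", "liver"))
  # passing overlapping binary masks gives the same result as the exclusive
  # integer map (the subtraction happens before centroid computation)
  masks <- list(
    thorax = label_map(array(as.integer(ph$organ_labels$data %in% c(1L, 3L)),
                             dim(ph$organ_labels$data)),
                       ph$organ_labels$affine, c(thorax = 1L)),
    abdomen = label_map(array(as.integer(ph$organ_labels$data %in% c(2L, 4L)),
                              dim(ph$organ_labels$data)),
                        ph$organ_labels$affine, c(abdomen = 1L)),
    heart = label_mask(ph$organ_labels, "heart"),
    liver = label_mask(ph$organ_labels, "liver")
  )
  lm2 <- extract_landmarks(masks)
  expect_equal(lm2$points, lm$points, tolerance = 1e-12)
})

test_that("centroids are equivariant under rigid transforms of the labels", {
  ph <- fx_phantom()
  tr <- rt_about_center(euler_deg(c(25, -40, 60)), c(6, -3, 9))
  moved <- resample_onto(ph$organ_labels, ph$organ_labels, transform = tr,
                         method = "nearest", fill = 0)
  moved <- label_map(array(as.integer(moved$data), dim(moved$data)),
                     moved$affine, ph$organ_labels$labels)
  lm_moved <- extract_landmarks(moved)$points
  expected <- rt_apply(tr, ph$landmarks$points)
  expect_lt(max(sqrt(rowSums((lm_moved - expected)^2))), ph$spec$voxel_mm)
})

test_that("an empty organ label is an error, not a 3-point registration", {
  ph <- fx_phantom_small()
  broken <- ph$organ_labels
  broken$data[broken$data == broken$labels[["heart"]]] <- 0L
  expect_error(extract_landmarks(broken),
               class = "fetalrecon_landmark_missing")
})

test_that("point registration is exact on the self-match", {
  lm <- fx_phantom_small()$landmarks
  tr <- point_register(lm, lm)
  expect_lt(max(abs(tr$R - diag(3))), 1e-12)
  expect_lt(max(abs(tr$t)), 1e-12)
})

test_that("point registration recovers random rigid transforms exactly", {
  src <- fx_phantom_small()$landmarks$points
  withr::with_seed(99, {
    for (i in 1:25) {
      R <- random_rotations(1)[[1]]
      t <- rnorm(3, sd = 20)
      tgt <- rt_apply(rigid_transform(R, t), src)
      est <- point_register(src, tgt)
      expect_lt(rotation_angle_deg(t(est$R) %*% R) * pi / 180, 1e-9)
      expect_lt(max(abs(est$t - t)), 1e-9)
    }
  })
})

test_that("noisy registration residual matches a numerical optimiser oracle", {
  src <- fx_phantom_small()$landmarks$points
  withr::with_seed(12, {
    R <- random_rotations(1)[[1]]
    t <- rnorm(3, sd = 10)
    tgt <- rt_apply(rigid_transform(R, t), src) + matrix(rnorm(12, sd = 1.5),
                                                         4, 3)
    est <- point_register(src, tgt)
    rss <- function(tr) sum((rt_apply(tr, src) - tgt)^2)
    got <- rss(est)
    # independent oracle: numerical minimisation over an Euler/translation
    # parameterisation from several starts
    obj <- function(p) rss(rigid_transform(euler_deg(p[1:3]), p[4:6]))
    starts <- list(rep(0, 6), c(10, -20, 30, 0, 0, 0), c(-45, 60, 10, 5, -5, 5))
    best <- min(vapply(starts, function(s) {
      stats::optim(s, obj, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-15))$value
    }, numeric(1)))
    expect_lt(got, best + 1e-6)
    expect_gt(got, best - 1e-6)
  })
})

test_that("collinear landmark configurations are rejected", {
  pts <- cbind(1:4, 2 * (1:4), -1 * (1:4))
  expect_error(landmark_set(pts), class = "fetalrecon_degenerate_landmarks")
  good <- fx_phantom_small()$landmarks$points
  expect_error(point_register(good, pts),
               class = "fetalrecon_degenerate_landmarks")
})

test_that("reorientation is a pure header update and is idempotent", {
  ph <- fx_phantom()
  atlas <- atlas_reference(ph$landmarks)
  pose <- rt_about_center(euler_deg(c(30, 100, -45)), c(8, -12, 5),
                          ph$trunk_centroid)
  st <- simulate_stack(ph, pose, fx_acq(), seed = 3)
  lm <- extract_landmarks(segment_organs(st, fx_backend()))
  out <- reorient_to_atlas(st, lm, atlas)
  # voxel data untouched
  expect_identical(out$stack$data, st$data)
  expect_equal(out$stack$affine, rt_as_affine(out$transform) %*% st$affine)
  # composed organ centroids land on the atlas points within 2 voxels
  moved <- rt_apply(out$transform, lm$points)
  expect_lt(max(sqrt(rowSums((moved - atlas$points)^2))),
            2 * max(voxel_spacing(st)))
  # landmarks already at the atlas leave the affine unchanged
  same <- reorient_to_atlas(st, landmark_set(atlas$points), atlas)
  expect_equal(same$stack$affine, st$affine, tolerance = 1e-9)
  # applying reorientation twice: the second transform is near identity
  st2 <- out$stack
  truth <- attr(st2, "truth")
  lm2 <- extract_landmarks(
    fetalrecon:::oracle_sample_labels(st2, truth$organ_labels,
                                      rt_compose(out$transform, truth$pose)))
  out2 <- reorient_to_atlas(st2, lm2, atlas)
  expect_lt(rotation_angle_deg(out2$transform$R), 1)
  expect_lt(sqrt(sum(out2$transform$t^2)), 2)
})

test_that("point registration is equivariant under conjugation", {
  src <- fx_phantom_small()$landmarks$points
  withr::with_seed(5, {
    P <- rigid_transform(random_rotations(1)[[1]], rnorm(3, sd = 5))
    noise <- matrix(rnorm(12, sd = 1), 4, 3)
    tgt <- rt_apply(P, src) + noise
    base <- point_register(src, tgt)
    Q <- rigid_transform(random_rotations(1)[[1]], rnorm(3, sd = 8))
    conj <- point_register(rt_apply(Q, src), rt_apply(Q, tgt))
    expected <- rt_compose(Q, rt_compose(base, rt_invert(Q)))
    expect_equal(conj$R, expected$R, tolerance = 1e-9)
    expect_equal(conj$t, expected$t, tolerance = 1e-9)
  })
})

test_that("atlas references survive a JSON round trip", {
  atlas <- atlas_reference(fx_phantom_small()$landmarks)
  path <- withr::local_tempfile(fileext = ".json")
  write_atlas(atlas, path)
  back <- read_atlas(path)
  expect_equal(back$points, atlas$points, tolerance = 1e-12)
})
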