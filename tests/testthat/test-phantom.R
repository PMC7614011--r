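test_that("organ mask centroids match dense-integration analytic centroids", {
  ph <- fx_phantom()
  spec <- ph$spec
  # oracle: integrate the same ellipsoid set definitions on a 2x finer grid
  f <- 2L
  n <- spec$grid_size * f
  v <- spec$voxel_mm / f
  coord <- (seq_len(n) - 1) * v - v * (n - 1) / 2
  X <- array(rep(coord, times = n * n), c(n, n, n))
  Y <- array(rep(rep(coord, each = n), times = n), c(n, n, n))
  Z <- array(rep(coord, each = n * n), c(n, n, n))
  g <- spec$geom
  ins <- function(e) {
    ((X - e$center[1]) / e$semi[1])^2 + ((Y - e$center[2]) / e$semi[2])^2 +
      ((Z - e$center[3]) / e$semi[3])^2 <= 1
  }
  trunk <- ins(g$trunk)
  thorax <- ins(g$thorax) & trunk
  abdomen <- ins(g$abdomen) & trunk & !thorax
  heart <- ins(g$heart) & thorax
  liver <- ins(g$liver) & abdomen
  regions <- list(thorax = thorax & !heart, abdomen = abdomen & !liver,
                  heart = heart, liver = liver)
  oracle <- t(vapply(regions, function(m) {
    c(mean(X[m]), mean(Y[m]), mean(Z[m]))
  }, numeric(3)))

  got <- ph$landmarks$points
  for (nm in rownames(got)) {
    expect_lt(sqrt(sum((got[nm, ] - oracle[nm, ])^2)), spec$voxel_mm)
  }
})

test_that("phantom generation is deterministic for a given spec", {
  sp <- phantom_spec(grid_size = 40, voxel_mm = 2.8, seed = 3L)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$intensity$data, b$intensity$data)
  expect_identical(a$global_labels$data, b$global_labels$data)
  expect_identical(a$organ_labels$data, b$organ_labels$data)
})

test_that("geometry violating organ containment is a specification error", {
  expect_error(
    phantom_spec(organs = list(
      heart = list(center = c(5, 3, 11), semi = c(40, 40, 40)))),
    class = "fetalrecon_spec_error")
})

test_that("global and organ label maps are mutually exclusive by voxel", {
  ph <- fx_phantom_small()
  expect_true(all(ph$global_labels$data %in% 0:3))
  expect_true(all(ph$organ_labels$data %in% 0:4))
  # organ labels live inside the trunk label
  trunk <- ph$global_labels$data == ph$global_labels$labels[["trunk"]]
  expect_true(all(trunk[ph$organ_labels$data > 0]))
})

test_that("motion-free simulated stacks overlay the phantom", {
  ph <- fx_phantom()
  st <- simulate_stack(ph, rt_identity(), fx_acq(), seed = 1)
  r <- resample_onto(st, ph$intensity, fill = NA_real_)
  trunk <- label_mask(ph$global_labels, "trunk")$data
  expect_gt(ncc(r$data, ph$intensity$data, region = trunk & !is.na(r$data)),
            0.95)
})

test_that("a posed stack maps back onto the phantom under the inverse pose", {
  ph <- fx_phantom()
  pose <- rt_about_center(euler_deg(c(180, 0, 0)), center = ph$trunk_centroid)
  st0 <- simulate_stack(ph, rt_identity(), fx_acq(), seed = 1)
  st1 <- simulate_stack(ph, pose, fx_acq(), seed = 1)
  # resample the posed stack back through pose^-1 onto the identity stack grid
  back <- resample_onto(st1, st0, transform = rt_invert(pose),
                        fill = NA_real_)
  region <- !is.na(back$data) & st0$data > 1
  expect_gt(ncc(back$data, st0$data, region = region), 0.98)
  # landmark ground truth transforms exactly by the pose (point transform)
  lm0 <- ph$landmarks$points
  lm1 <- extract_landmarks(segment_organs(st1, fx_backend()))$points
  moved <- rt_apply(pose, lm0)
  expect_lt(max(sqrt(rowSums((lm1 - moved)^2))), 2 * ph$spec$voxel_mm)
})

test_that("stack simulation is deterministic and pose-validated", {
  ph <- fx_phantom_small()
  acq <- fx_acq(noise_sigma = 3, jitter_rot_deg = 2, jitter_trans_mm = 1,
                bias_amplitude = 0.2)
  a <- simulate_stack(ph, rt_identity(), acq, seed = 5)
  b <- simulate_stack(ph, rt_identity(), acq, seed = 5)
  expect_identical(a$data, b$data)
  c <- simulate_stack(ph, rt_identity(), acq, seed = 6)
  expect_false(identical(a$data, c$data))
  expect_error(simulate_stack(ph, list(R = diag(3) * 2, t = c(0, 0, 0)), acq),
               class = "fetalrecon_invalid_transform")
})

test_that("interleaved stacks split into packages with the expected spacing", {
  ph <- fx_phantom()
  # protocol-style acquisition: 1.25 mm spacing, 4 packages, 5 mm in-package
  acq <- acquisition_spec(in_plane_mm = 2.5, slice_thickness_mm = 2.5,
                          slice_spacing_mm = 1.25, n_packages = 4)
  st <- simulate_stack(ph, rt_identity(), acq, seed = 1)
  pk <- split_packages(st)
  expect_length(pk, 4)
  expect_equal(sum(vapply(pk, function(p) dim(p$data)[3], integer(1))),
               dim(st$data)[3])
  for (p in pk) {
    expect_equal(p$slice_spacing_mm, 5)
    expect_equal(sqrt(sum(p$affine[1:3, 3]^2)), 5)
  }
  # slice positions of the packages interleave across the stack extent
  starts <- vapply(pk, function(p) p$affine[3, 4], numeric(1))
  expect_equal(sort(starts) - min(starts), c(0, 1.25, 2.5, 3.75))
})

test_that("package splitting is a partition: re-merging restores the stack", {
  ph <- fx_phantom_small()
  acq <- fx_acq(n_packages = 4)
  st <- simulate_stack(ph, rt_identity(), acq, seed = 2)
  merged <- merge_packages(split_packages(st))
  expect_equal(merged$data, st$data, tolerance = 1e-12)
  expect_equal(merged$affine, st$affine, tolerance = 1e-9)
})

test_that("single-package (ascending) stacks pass through unchanged", {
  ph <- fx_phantom_small()
  st <- simulate_stack(ph, rt_identity(), fx_acq(slice_order = "ascending"),
                       seed = 1)
  pk <- split_packages(st)
  expect_length(pk, 1)
  expect_identical(pk[[1]]$data, st$data)
})
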