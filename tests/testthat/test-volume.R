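test_that("voxel/world mappings invert each other and respect the affine", {
  A <- diag(c(1.25, 1.25, 2.5, 1))
  A[1:3, 4] <- c(-10, 5, 3)
  vol <- image_volume(array(0, c(8, 10, 6)), A)
  expect_equal(voxel_spacing(vol), c(1.25, 1.25, 2.5))
  ijk <- rbind(c(1, 1, 1), c(8, 10, 6), c(3.5, 2, 4))
  w <- voxel_to_world(vol, ijk)
  expect_equal(w[1, ], c(-10, 5, 3))
  expect_equal(world_to_voxel(vol, w), ijk)
})

test_that("non-invertible affines are rejected", {
  A <- diag(4); A[1, 1] <- 0
  expect_error(image_volume(array(0, c(4, 4, 4)), A), "invertible")
})

test_that("resampling onto the same grid is the identity", {
  set.seed(1)
  arr <- array(rnorm(6^3), c(6, 6, 6))
  vol <- image_volume(arr, diag(c(2, 2, 2, 1)))
  out <- resample_onto(vol, vol, method = "nearest")
  expect_identical(out$data, arr)
  lin <- resample_onto(vol, vol, method = "linear")
  expect_equal(lin$data, arr, tolerance = 1e-12)
})

test_that("resampling through a rigid transform is geometrically consistent", {
  # a volume moved by T then sampled back under T^-1 reproduces itself
  ph <- fx_phantom_small()
  tr <- rt_about_center(euler_deg(c(20, -10, 35)), c(4, -6, 2))
  moved <- resample_onto(ph$intensity, ph$intensity, transform = tr,
                         fill = NA_real_)
  back <- resample_onto(moved, ph$intensity, transform = rt_invert(tr),
                        fill = NA_real_)
  region <- !is.na(back$data) & ph$intensity$data > 1
  expect_gt(ncc(back$data, ph$intensity$data, region = region), 0.98)
})

test_that("rigid transforms compose, invert and apply correctly", {
  withr::with_seed(7, {
    Rs <- random_rotations(2)
    a <- rigid_transform(Rs[[1]], c(1, 2, 3))
    b <- rigid_transform(Rs[[2]], c(-2, 0.5, 4))
    p <- matrix(rnorm(15), 5, 3)
    expect_equal(rt_apply(rt_compose(a, b), p), rt_apply(a, rt_apply(b, p)),
                 tolerance = 1e-12)
    ab_inv <- rt_compose(rt_invert(b), rt_invert(a))
    expect_equal(rt_apply(rt_invert(rt_compose(a, b)), p), rt_apply(ab_inv, p),
                 tolerance = 1e-12)
    expect_equal(rt_apply(rt_compose(a, rt_invert(a)), p), p,
                 tolerance = 1e-12)
  })
})

test_that("improper or non-orthogonal matrices are rejected as transforms", {
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), class = "fetalrecon_invalid_transform")
  expect_error(rigid_transform(diag(3) * 1.1),
               class = "fetalrecon_invalid_transform")
})

test_that("rotation angle and axis rotations behave as expected", {
  expect_equal(rotation_angle_deg(diag(3)), 0)
  expect_equal(rotation_angle_deg(axis_rotation_deg(1, 180)), 180)
  expect_equal(rotation_angle_deg(axis_rotation_deg(2, 45)), 45)
  expect_equal(rotation_about_axis(c(0, 0, 1), 90), axis_rotation_deg(3, 90),
               tolerance = 1e-12)
})

test_that("transforms survive a text round trip", {
  tr <- rt_about_center(euler_deg(c(10, 20, 30)), c(1.5, -2, 0.25))
  path <- withr::local_tempfile(fileext = ".txt")
  write_transform(tr, path)
  tr2 <- read_transform(path)
  expect_equal(tr2$R, tr$R, tolerance = 1e-12)
  expect_equal(tr2$t, tr$t, tolerance = 1e-12)
})

test_that("volumes survive a NIfTI round trip with their affine", {
  ph <- fx_phantom_small()
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$intensity, path)
  back <- read_volume(path)
  expect_equal(back$data, ph$intensity$data, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(unclass(back$affine), unclass(ph$intensity$affine),
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("mask utilities report volume and centroid in world units", {
  arr <- array(0L, c(10, 10, 10))
  arr[3:5, 4:6, 2:4] <- 1L
  A <- diag(c(2, 2, 2, 1))
  lm <- label_map(arr, A, c(roi = 1L))
  expect_equal(mask_volume_mm3(lm), 27 * 8)
  expect_equal(mask_centroid(lm), drop(voxel_to_world(lm, c(4, 5, 3))))
  empty <- label_map(array(0L, c(4, 4, 4)), A, c(roi = 1L))
  expect_error(mask_centroid(empty), class = "fetalrecon_empty_mask")
})
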