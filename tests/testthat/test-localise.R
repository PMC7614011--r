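test_that("resample_to_grid preserves aspect ratio and world geometry", {
  set.seed(2)
  arr <- array(rnorm(100 * 100 * 50), c(100, 100, 50))
  vol <- image_volume(arr, diag(c(1, 1, 2, 1)))
  out <- resample_to_grid(vol, 64)
  expect_equal(dim(out$data), c(64, 64, 64))
  sp <- voxel_spacing(out)
  expect_equal(sp[1], sp[2])
  expect_equal(sp[2], sp[3])
  # world coordinates of the centre are preserved to < 0.5 voxel
  expect_lt(sqrt(sum((volume_center(out) - volume_center(vol))^2)),
            0.5 * max(sp))
})

test_that("resampling a cube to its own size is the identity for NN", {
  set.seed(3)
  arr <- array(rnorm(32^3), c(32, 32, 32))
  vol <- image_volume(arr, diag(c(1.5, 1.5, 1.5, 1)))
  out <- resample_to_grid(vol, 32, method = "nearest")
  expect_identical(out$data, arr)
  expect_error(resample_to_grid(vol, 0))
})

test_that("oracle global segmentation reproduces the ground-truth trunk", {
  ph <- fx_phantom()
  st <- simulate_stack(ph, rt_identity(), fx_acq(), seed = 1)
  seg <- segment_global(st, fx_backend())
  truth <- resample_volume(ph$global_labels, dim(st$data), st$affine,
                           method = "nearest", fill = 0)
  # Dice of the trunk label against directly-sampled ground truth is 1
  a <- seg$data == seg$labels[["trunk"]]
  b <- truth$data == 3
  expect_equal(2 * sum(a & b) / (sum(a) + sum(b)), 1.0)
})

test_that("brain-only stacks yield an empty trunk label, not a failure", {
  ph <- fx_phantom()
  u <- ph$spec$grid_size * ph$spec$voxel_mm / 2
  st <- simulate_stack(ph, rt_identity(), fx_acq(), seed = 1,
                       fov_mm = 0.5 * u, center_mm = c(0, 0.02 * u, 0.82 * u))
  seg <- segment_global(st, fx_backend())
  expect_equal(sum(seg$data == seg$labels[["trunk"]]), 0)
  expect_gt(sum(seg$data == seg$labels[["brain"]]), 0)
  trunk <- label_mask(seg, "trunk")
  expect_error(crop_to_roi(st, trunk, 15), class = "fetalrecon_trunk_absent")
})

test_that("the cnn backend without weights raises an explicit error", {
  ph <- fx_phantom_small()
  st <- simulate_stack(ph, rt_identity(), fx_acq(), seed = 1)
  expect_error(segment_global(st, segmenter_backend("cnn")),
               class = "fetalrecon_untrained_backend")
  expect_error(segment_organs(st, segmenter_backend("cnn")),
               class = "fetalrecon_untrained_backend")
})

test_that("largest_component keeps exactly the biggest 26-connected blob", {
  arr <- array(0L, c(20, 20, 20))
  arr[2:6, 2:6, 2:5] <- 1L       # 100 voxels
  arr[12:15, 12:15, 12:14] <- 1L # fewer voxels, plus diagonal connectivity
  arr[16, 16, 15] <- 1L          # 26-connected to the corner of the blob
  lm <- label_map(arr, diag(4), c(roi = 1L))
  out <- largest_component(lm)
  expect_equal(sum(out$data), 100)
  expect_true(all(out$data[2:6, 2:6, 2:5] == 1))
  # single blob passes through unchanged; empty input stays empty
  single <- label_map(array(c(0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L), c(2, 2, 2)),
                      diag(4), c(roi = 1L))
  expect_identical(largest_component(single)$data, single$data)
  empty <- label_map(array(0L, c(4, 4, 4)), diag(4), c(roi = 1L))
  expect_identical(largest_component(empty)$data, empty$data)
})

test_that("component size ties break deterministically by bounding-box origin", {
  arr <- array(0L, c(20, 10, 10))
  arr[12:14, 2:4, 2:4] <- 1L   # 27 voxels, larger origin
  arr[2:4, 5:7, 5:7] <- 1L     # 27 voxels, smaller x origin
  lm <- label_map(arr, diag(4), c(roi = 1L))
  outs <- replicate(3, which(largest_component(lm)$data != 0), simplify = FALSE)
  expect_identical(outs[[1]], outs[[2]])
  expect_identical(outs[[2]], outs[[3]])
  idx <- which(largest_component(lm)$data != 0, arr.ind = TRUE)
  expect_equal(min(idx[, 1]), 2)
})

test_that("crop_to_roi honours the margin and preserves world geometry", {
  ph <- fx_phantom()
  st <- simulate_stack(ph, rt_identity(), fx_acq(), seed = 1)
  seg <- segment_global(st, fx_backend())
  trunk <- largest_component(label_mask(seg, "trunk"))
  idx <- which(trunk$data != 0, arr.ind = TRUE)
  bb <- apply(idx, 2, range)

  tight <- crop_to_roi(st, trunk, 0)
  expect_equal(dim(tight$data), unname(bb[2, ] - bb[1, ] + 1))

  wide <- crop_to_roi(st, trunk, 20)
  grow <- ceiling(20 / voxel_spacing(st))
  expect_equal(dim(wide$data),
               unname(pmin(dim(st$data), bb[2, ] + grow) -
                        pmax(1, bb[1, ] - grow) + 1))

  # cropping is geometry-preserving: resampling the cropped and uncropped
  # stacks to the phantom grid agrees inside the trunk
  a <- resample_onto(tight, ph$intensity, fill = NA_real_)
  b <- resample_onto(st, ph$intensity, fill = NA_real_)
  inside <- !is.na(a$data) & label_mask(ph$global_labels, "trunk")$data > 0
  expect_equal(a$data[inside], b$data[inside], tolerance = 1e-9)
})
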