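test_that("ncc has the expected exact properties", {
  set.seed(10)
  x <- array(abs(rnorm(16^3)) + 0.5, c(16, 16, 16))
  expect_equal(ncc(x, x), 1.0, tolerance = 1e-12)
  expect_equal(ncc(x, 3.2 * x + 7), 1.0, tolerance = 1e-12)
  expect_equal(ncc(x, array(2, dim(x))), 0)   # zero variance convention
  expect_equal(ncc(array(0, c(4, 4, 4)), array(0, c(4, 4, 4))), 0)
  expect_error(ncc(x, array(1, c(8, 8, 8))), "different grids")
})

test_that("ncc equals a naive two-pass loop on random volumes", {
  withr::with_seed(21, {
    for (n in c(16, 24, 32)) {
      a <- array(rnorm(n^3), c(n, n, n))
      b <- 0.6 * a + array(rnorm(n^3), c(n, n, n))
      # zero out a corner to exercise the non-zero-overlap region rule
      a[1:4, 1:4, 1:4] <- 0
      expect_equal(ncc(a, b), naive_ncc(a, b), tolerance = 1e-12)
    }
  })
})

test_that("motion score equals the brute-force sequential-pair mean", {
  withr::with_seed(22, {
    arr <- array(rnorm(12 * 12 * 10), c(12, 12, 10))
    arr[, , 4] <- 0   # a blank slice: its two pairs contribute 0
    got <- motion_score(arr)
    vals <- vapply(1:9, function(j) naive_ncc(arr[, , j], arr[, , j + 1]),
                   numeric(1))
    expect_equal(got, mean(vals), tolerance = 1e-12)
    expect_error(motion_score(arr[, , 1, drop = FALSE]), "2 slices")
  })
})

test_that("slice permutation strictly lowers the motion score of a smooth stack", {
  ph <- fx_phantom()
  st <- simulate_stack(ph, rt_identity(), fx_acq(), seed = 4)
  st <- crop_to_roi(st, largest_component(
    label_mask(segment_global(st, fx_backend()), "trunk")), 10)
  base <- motion_score(st)
  withr::with_seed(8, {
    perm <- st
    perm$data <- st$data[, , sample(dim(st$data)[3])]
    expect_lt(motion_score(perm), base)
  })
})

test_that("stack similarity equals a brute-force double loop, self term included", {
  withr::with_seed(23, {
    vols <- lapply(1:4, function(i) {
      v <- array(abs(rnorm(16^3)), c(16, 16, 16))
      v[1:3, , ] <- 0
      v
    })
    got <- stack_similarity(vols)
    pair <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) pair[i, j] <- naive_ncc(vols[[i]], vols[[j]])
    expect_equal(got, rowMeans(pair), tolerance = 1e-12)
  })
  # identical aligned stacks score 1; a single stack scores 1 (self term)
  one <- array(abs(rnorm(5^3)) + 1, c(5, 5, 5))
  expect_equal(stack_similarity(list(one, one, one)), rep(1, 3),
               tolerance = 1e-12)
  expect_equal(stack_similarity(list(one)), 1, tolerance = 1e-12)
})

test_that("volume deviation is |V - median| / median", {
  expect_equal(volume_deviation(c(100, 100, 100)), c(0, 0, 0))
  expect_equal(volume_deviation(c(80, 100, 120)), c(0.2, 0, 0.2))
  expect_error(volume_deviation(c(0, 0, 0)), "median")
  # a mask half the median size is excluded by the volume criterion
  cvol <- volume_deviation(c(50, 100, 100, 100))
  expect_equal(cvol[1], 0.5)
  m <- tibble::tibble(Ccor = rep(0.9, 4), Csim = rep(0.9, 4), Cvol = cvol)
  out <- apply_inclusion(m)
  expect_false(out$included[1])
  expect_true(all(out$included[2:4]))
})

test_that("inclusion rules are strict inequalities on every branch", {
  m <- tibble::tibble(Ccor = c(0.9, 0.9, 0.3), Csim = rep(0.8, 3),
                      Cvol = rep(0, 3))
  out <- apply_inclusion(m)
  expect_equal(out$included, c(TRUE, TRUE, FALSE))
  expect_match(out$reason[3], "motion_corrupted")

  # boundary: Ccor exactly 0.5 * max is excluded (strict)
  m2 <- tibble::tibble(Ccor = c(1.0, 0.5), Csim = c(1, 1), Cvol = c(0, 0))
  expect_equal(apply_inclusion(m2)$included, c(TRUE, FALSE))
  # boundary: Cvol exactly 0.40 is excluded (strict)
  m3 <- tibble::tibble(Ccor = c(1, 1), Csim = c(1, 1), Cvol = c(0, 0.40))
  expect_equal(apply_inclusion(m3)$included, c(TRUE, FALSE))
  # Csim branch
  m4 <- tibble::tibble(Ccor = c(1, 1), Csim = c(1, 0.45), Cvol = c(0, 0))
  out4 <- apply_inclusion(m4)
  expect_equal(out4$included, c(TRUE, FALSE))
  expect_match(out4$reason[2], "dissimilar")
  # single stack is always included (its own max, Cvol = 0)
  m5 <- tibble::tibble(Ccor = 0.2, Csim = 0.1, Cvol = 0)
  expect_true(apply_inclusion(m5)$included)
  # all excluded is an explicit failure listing the metrics
  m6 <- tibble::tibble(Ccor = c(1, 1), Csim = c(1, 1), Cvol = c(0.5, 0.6))
  expect_error(apply_inclusion(m6), class = "fetalrecon_no_usable_stacks")
})

test_that("inclusion decisions are invariant to intensity scaling", {
  withr::with_seed(31, {
    vols <- lapply(1:3, function(i) array(abs(rnorm(12^3)) + i, c(12, 12, 12)))
    stacks <- lapply(vols, function(v) v)
    m1 <- tibble::tibble(
      Ccor = vapply(stacks, motion_score, numeric(1)),
      Csim = stack_similarity(vols),
      Cvol = volume_deviation(c(90, 100, 110)))
    scaled <- lapply(vols, function(v) 17.3 * v)
    m2 <- tibble::tibble(
      Ccor = vapply(scaled, motion_score, numeric(1)),
      Csim = stack_similarity(scaled),
      Cvol = volume_deviation(c(90, 100, 110)))
    expect_equal(apply_inclusion(m1)$included, apply_inclusion(m2)$included)
    expect_equal(m1$Ccor, m2$Ccor, tolerance = 1e-12)
  })
})

test_that("reference selection maximises Ccor * Csim with lowest-index ties", {
  m <- tibble::tibble(Ccor = c(0.8, 0.9), Csim = c(0.9, 0.8), Cvol = c(0, 0))
  expect_equal(select_reference(apply_inclusion(m)), 1)
  m2 <- tibble::tibble(Ccor = c(0.5, 0.9), Csim = c(0.5, 0.9), Cvol = c(0, 0))
  expect_equal(select_reference(apply_inclusion(m2)), 2)
  # excluded stacks cannot be selected even with the highest product
  m3 <- tibble::tibble(Ccor = c(1, 0.9), Csim = c(1, 0.9), Cvol = c(0.5, 0))
  expect_equal(select_reference(apply_inclusion(m3)), 2)
})

test_that("the median template is robust and order invariant", {
  cl <- fx_clean_set()
  tm <- build_template(cl$stacks, cl$transforms, cl$masks)
  ord <- c(4, 2, 6, 1, 3, 5)
  tm2 <- build_template(cl$stacks[ord], cl$transforms[ord], cl$masks[ord])
  expect_equal(tm2$template$data, tm$template$data, tolerance = 1e-12)
  expect_identical(tm2$mask$data, tm$mask$data)
  # single stack: template is that stack resampled, mask its mask
  tm1 <- build_template(cl$stacks[1], cl$transforms[1], cl$masks[1])
  r <- resample_onto(cl$stacks[[1]], tm1$template, fill = NA_real_)
  inside <- !is.na(r$data)
  expect_equal(tm1$template$data[inside], r$data[inside], tolerance = 1e-12)
  # voxelwise median suppresses a gross artifact in one stack
  expect_equal(median(c(10, 11, 300)), 11)  # the rule the template applies
  spiked <- cl$stacks
  spiked[[1]]$data[] <- spiked[[1]]$data + 500
  tm3 <- build_template(spiked, cl$transforms, cl$masks)
  delta <- abs(tm3$template$data - tm$template$data)
  # a +500 artifact in one of six stacks barely moves the voxelwise median
  expect_lt(median(delta[tm$mask$data > 0]), 1)
})

test_that("median averaging of noisy stacks beats every single noisy stack", {
  ph <- fx_phantom()
  backend <- fx_backend()
  stacks <- list(); masks <- list()
  for (s in 1:6) {
    st <- simulate_stack(ph, rt_identity(), fx_acq(noise_sigma = 10),
                         seed = 100 + s, slice_axis = ((s - 1) %% 3) + 1)
    seg <- segment_global(st, backend)
    st <- crop_to_roi(st, largest_component(label_mask(seg, "trunk")), 15)
    stacks[[s]] <- st
    masks[[s]] <- fetalrecon:::thorax_mask(segment_organs(st, backend))
  }
  transforms <- replicate(6, rt_identity(), simplify = FALSE)
  tm <- build_template(stacks, transforms, masks)
  singles <- vapply(stacks, fx_ncc_vs_phantom, numeric(1), ph = ph)
  expect_gt(fx_ncc_vs_phantom(tm$template, ph), max(singles))
})

test_that("pairwise refinement keeps aligned stacks near identity", {
  cl <- fx_clean_set()
  ref <- refine_pairwise(cl$stacks, cl$transforms, cl$masks)
  # stays near identity up to the anisotropic slice-profile bias between
  # differently oriented stacks at this slice thickness
  for (tr in ref$transforms) {
    expect_lt(rotation_angle_deg(tr$R), 1.5)
    expect_lt(sqrt(sum(tr$t^2)), 1.5)
  }
})

test_that("refinement recovers a small residual landmark error", {
  cl <- fx_clean_set()
  bad <- cl$transforms
  # perturb a stack that is not the registration target
  j <- which.min(vapply(cl$stacks, motion_score, numeric(1)))
  bad[[j]] <- rt_about_center(euler_deg(c(5, 0, 0)), c(2, 0, 0))
  ref <- refine_pairwise(cl$stacks, bad, cl$masks)
  expect_lt(rotation_angle_deg(ref$transforms[[j]]$R), 1.5)
  expect_lt(sqrt(sum(ref$transforms[[j]]$t^2)), 1.5)
})

test_that("a pure-noise stack takes the divergence path and keeps its init", {
  cl <- fx_clean_set()
  noisy <- cl$stacks
  set.seed(40)
  noisy[[3]]$data <- array(rnorm(length(noisy[[3]]$data), sd = 100),
                           dim(noisy[[3]]$data))
  init <- cl$transforms
  init[[3]] <- rt_about_center(euler_deg(c(3, -2, 1)), c(1, 1, -1))
  ref <- refine_pairwise(noisy, init, cl$masks)
  # the divergence path keeps the landmark-only transform exactly
  expect_false(ref$refined[3])
  expect_equal(ref$transforms[[3]]$R, init[[3]]$R, tolerance = 1e-12)
})
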