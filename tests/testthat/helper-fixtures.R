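# Shared fixtures, built once per test run and cached. Sizes are chosen so
# the full suite runs on a single CPU in minutes: a 64^3 phantom at 1.75 mm
# keeps the 112 mm field of view of the default phantom while shrinking the
# grid, and the test acquisition uses 2 mm in-plane / 3 mm slices.

.fx <- new.env(parent = emptyenv())

fx_phantom <- function() {
  if (is.null(.fx$ph)) {
    .fx$ph <- make_phantom(phantom_spec(grid_size = 64, voxel_mm = 1.75))
  }
  .fx$ph
}

fx_phantom_small <- function() {
  if (is.null(.fx$ph_small)) {
    .fx$ph_small <- make_phantom(phantom_spec(grid_size = 40, voxel_mm = 2.8))
  }
  .fx$ph_small
}

fx_acq <- function(...) {
  acquisition_spec(in_plane_mm = 2.0, slice_thickness_mm = 3.0,
                   slice_spacing_mm = 1.5, ...)
}

fx_backend <- function() segmenter_backend("oracle")

# six motion-free stacks in alternating orientations, cropped to the trunk,
# with their thorax masks (used by super-resolution and selection tests)
fx_clean_set <- function() {
  if (is.null(.fx$clean)) {
    ph <- fx_phantom()
    stacks <- list(); masks <- list()
    for (s in 1:6) {
      st <- simulate_stack(ph, rt_identity(), fx_acq(), seed = s,
                           slice_axis = ((s - 1) %% 3) + 1)
      seg <- segment_global(st, fx_backend())
      trunk <- largest_component(label_mask(seg, "trunk"))
      st <- crop_to_roi(st, trunk, 15)
      stacks[[s]] <- st
      masks[[s]] <- fetalrecon:::thorax_mask(segment_organs(st, fx_backend()))
    }
    .fx$clean <- list(stacks = stacks, masks = masks,
                      transforms = replicate(6, rt_identity(),
                                             simplify = FALSE))
  }
  .fx$clean
}

# masked NCC of a volume against the phantom ground truth over the thorax
fx_ncc_vs_phantom <- function(vol, ph = fx_phantom()) {
  thx <- fetalrecon:::thorax_mask(ph$organ_labels)$data != 0
  r <- resample_onto(vol, ph$intensity, fill = NA_real_)
  ncc(r$data, ph$intensity$data, region = thx & !is.na(r$data))
}

# naive two-pass Pearson correlation used as the brute-force NCC oracle
naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- 0; my <- 0
  for (i in seq_len(n)) { mx <- mx + x[i]; my <- my + y[i] }
  mx <- mx / n; my <- my / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# brute-force NCC over the non-zero overlap (the metric oracle)
naive_ncc <- function(a, b) {
  keep <- which(a != 0 & b != 0)
  if (length(keep) < 2) return(0)
  x <- a[keep]; y <- b[keep]
  if (length(unique(x)) == 1 || length(unique(y)) == 1) return(0)
  naive_pearson(x, y)
}
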