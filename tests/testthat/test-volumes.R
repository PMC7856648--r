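test_that("cube neighborhoods enumerate and truncate correctly", {
  dims <- c(12L, 12L, 12L)
  # interior, half-width 2: the 125-voxel searchlight cube
  expect_length(cube_indices(c(6, 6, 6), 2, dims), 125)
  # interior, half-width 1: full 27; corner truncates to 8, edge to 12
  expect_length(cube_indices(c(6, 6, 6), 1, dims), 27)
  expect_length(cube_indices(c(1, 1, 1), 1, dims), 8)
  expect_length(cube_indices(c(1, 1, 6), 1, dims), 12)
  # brute-force oracle: enumerate all voxels within the Chebyshev ball
  co <- expand.grid(x = 1:12, y = 1:12, z = 1:12)
  for (center in list(c(2, 3, 11), c(1, 12, 5))) {
    keep <- abs(co$x - center[1]) <= 2 & abs(co$y - center[2]) <= 2 &
      abs(co$z - center[3]) <= 2
    oracle <- sort(which(keep))
    expect_equal(sort(cube_indices(center, 2, dims)), oracle)
  }
  expect_error(cube_indices(c(1, 1, 1), 0, dims), "half_width")
})

test_that("pattern extraction respects mask, ordering and minimum voxels", {
  dims <- c(6L, 6L, 6L)
  mask <- rep(TRUE, prod(dims))
  mask[1:100] <- FALSE
  vol <- make_cond_volume(dims, mask = mask, seed = 7)
  roi <- 90:130   # straddles the mask edge
  pat <- extract_patterns(vol, roi, "L1", 1)
  expect_length(pat, sum(roi > 100))
  expect_equal(pat, vol_full <- vol$data[, "1:L1"][roi[roi > 100]])
  # below the minimum -> flagged empty
  small <- extract_patterns(vol, 1:5, "L1", 1)
  expect_length(small, 0)
  expect_equal(attr(small, "flag"), "too_few_voxels")
  # cube spec resolves through the same path
  cube <- extract_patterns(vol, list(center = c(3, 3, 3), half_width = 1),
                           "L2", 2)
  expect_length(cube, sum(mask[cube_indices(c(3, 3, 3), 1, dims)]))
})

test_that("condition-level volumes require every language in every run", {
  dims <- c(4L, 4L, 4L)
  data <- matrix(rnorm(64 * 3), 64, 3)
  idx <- data.frame(run = c(1, 2, 1), unit = c("L1", "L1", "L2"))
  expect_error(pattern_volume(data, idx, dims), "missing from run")
})

test_that("pattern volumes and ROI sets round-trip through NIfTI", {
  dims <- c(6L, 6L, 6L)
  vol <- make_cond_volume(dims, seed = 3)
  prefix <- tempfile()
  write_pattern_volume(vol, prefix)
  back <- read_pattern_volume(prefix)
  expect_lt(max(abs(back$data - vol$data)), 1e-6)
  expect_equal(back$dims, vol$dims)
  expect_equal(back$index$unit, vol$index$unit)
  expect_equal(back$mask, vol$mask)

  labels <- array(0L, dims)
  labels[1:2, 1:2, 1:2] <- 1L
  labels[4:5, 4:5, 4:5] <- 2L
  rois <- roi_set(labels, dims, names = c(`1` = "left box", `2` = "right box"))
  rprefix <- tempfile()
  write_roi_set(rois, rprefix)
  rback <- read_roi_set(rprefix)
  expect_equal(rback$labels, rois$labels)
  expect_equal(rback$label_table, rois$label_table)
})

test_that("default ROI naming lists the ten bilateral regions", {
  nm <- default_roi_names()
  expect_length(nm, 10)
  expect_true(any(grepl("pars opercularis", nm)))
  expect_true(any(grepl("supramarginal", nm)))
})
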