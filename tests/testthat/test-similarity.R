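test_that("Fisher z is the clamped odd monotone atanh", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.9), 0.5 * log(1.9 / 0.1), tolerance = 1e-12)
  expect_equal(round(fisher_z(0.9), 4), 1.4722)
  rs <- seq(-0.95, 0.95, by = 0.1)
  expect_equal(fisher_z(-rs), -fisher_z(rs))
  expect_true(all(diff(fisher_z(rs)) > 0))
  expect_true(is.finite(fisher_z(1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_error(fisher_z(1.2), "outside")
})

test_that("pattern correlation matches the textbook formula and its invariances", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  expect_equal(pattern_correlation(x, y), oracle_pearson(x, y))
  expect_equal(pattern_correlation(x, x), 1)
  expect_equal(pattern_correlation(x, -x), -1)
  set.seed(9)
  a <- rnorm(50); b <- rnorm(50)
  r0 <- pattern_correlation(a, b)
  expect_equal(pattern_correlation(a + 5, b), r0)
  expect_equal(pattern_correlation(a * 3, b), r0)
  expect_equal(pattern_correlation(-a, b), -r0)
  # degenerate inputs are flagged NA
  expect_true(is.na(pattern_correlation(rep(1, 10), rnorm(10))))
  expect_true(is.na(pattern_correlation(c(1, 2), c(3, 4))))
  # non-finite voxels are removed pairwise
  a2 <- a; a2[1:3] <- NA
  expect_equal(pattern_correlation(a2, b), cor(a[-(1:3)], b[-(1:3)]))
})

test_that("cross-language similarity averages Fisher z across runs", {
  dims <- c(6L, 6L, 6L)
  vol <- make_cond_volume(dims, seed = 5)
  vs <- seq_len(prod(dims))
  rec <- cross_language_similarity(vol, c("L1", "L2"), vs)
  r1 <- oracle_pearson(vol$data[, "1:L1"], vol$data[, "1:L2"])
  r2 <- oracle_pearson(vol$data[, "2:L1"], vol$data[, "2:L2"])
  expect_equal(rec$z, mean(c(atanh(r1), atanh(r2))), tolerance = 1e-12)
  # averaging happens on the z scale, not on r (they differ here)
  expect_false(isTRUE(all.equal(rec$z, atanh(mean(c(r1, r2))))))
  # identical patterns hit the clamped maximum
  vol2 <- vol
  vol2$data[, "1:L2"] <- vol2$data[, "1:L1"]
  vol2$data[, "2:L2"] <- vol2$data[, "2:L1"]
  rec2 <- cross_language_similarity(vol2, c("L1", "L2"), vs)
  expect_equal(rec2$z, atanh(1 - 1e-7))
})

test_that("within-language exceeds between-language for planted signals", {
  dims <- c(7L, 7L, 7L)
  vol <- make_cond_volume(dims, signal_sd = 1.5, noise_sd = 1, seed = 21)
  wb <- within_between_similarity(vol, seq_len(prod(dims)))
  within <- wb$z[startsWith(wb$pair, "within:")]
  between <- wb$z[startsWith(wb$pair, "between:")]
  expect_length(within, 3)
  expect_length(between, 3)
  expect_true(all(within > max(between)))
})

test_that("null within/between similarities center on zero", {
  dims <- c(6L, 6L, 6L)
  zs <- replicate(200, {
    vol <- make_cond_volume(dims, signal_sd = 0, seed = sample.int(1e6, 1))
    wb <- within_between_similarity(vol, seq_len(prod(dims)))
    mean(wb$z)
  })
  se <- sd(zs) / sqrt(length(zs))
  expect_lt(abs(mean(zs)), 4 * se + 0.01)
})

test_that("searchlight values equal the ROI pipeline on each cube", {
  dims <- c(7L, 7L, 7L)
  mask <- rep(TRUE, prod(dims))
  mask[1:30] <- FALSE
  vol <- make_cond_volume(dims, signal_sd = 0.5, seed = 13, mask = mask)
  sl <- searchlight_map(vol, c("L1", "L3"), half_width = 1,
                        min_mask_frac = 0.5)
  centers <- which(vol$mask)
  coords <- arrayInd(centers, dims)
  for (k in seq_along(centers)) {
    idx <- cube_indices(coords[k, ], 1, dims)
    in_mask <- idx[vol$mask[idx]]
    expected <- if (length(in_mask) < 0.5 * 27) {
      NA_real_
    } else {
      cross_language_similarity(vol, c("L1", "L3"), in_mask)$z
    }
    expect_equal(sl[centers[k]], expected)
  }
  # out-of-mask voxels are missing
  expect_true(all(is.na(sl[!vol$mask])))
})

test_that("within-between searchlight contrast is positive for stable signals", {
  dims <- c(6L, 6L, 6L)
  vol <- make_cond_volume(dims, signal_sd = 1.5, noise_sd = 1, seed = 33)
  sl <- searchlight_map(vol, contrast = "within_between", half_width = 1)
  expect_gt(mean(sl, na.rm = TRUE), 0)
})

test_that("ROI similarity tables cover every region and pair", {
  dims <- c(8L, 8L, 8L)
  vol <- make_cond_volume(dims, seed = 2)
  labels <- array(0L, dims)
  labels[1:3, 1:3, 1:3] <- 1L
  labels[5:7, 5:7, 5:7] <- 2L
  rois <- roi_set(labels, dims)
  tab <- roi_similarity_table(vol, rois,
                              list(c("L1", "L2"), c("L1", "L3")))
  expect_equal(nrow(tab), 4)
  expect_equal(sort(unique(tab$pair)), c("L1-L2", "L1-L3"))
  # whole-mask ROI equals cross_language_similarity on the whole mask
  whole <- roi_set(array(1L, dims), dims)
  t2 <- roi_similarity_table(vol, whole, list(c("L1", "L2")))
  ref <- cross_language_similarity(vol, c("L1", "L2"), seq_len(prod(dims)))
  expect_equal(t2$z, ref$z)
})

test_that("item-level RDMs match hand-computed correlations", {
  # 2x2 toy: two items per language on a 3-voxel grid
  pats <- cbind(a1 = c(1, 2, 3), a2 = c(3, 2, 1),
                b1 = c(1, 2, 4), b2 = c(3, 1, 1))
  vol <- make_item_volume(pats, languages = c("LA", "LA", "LB", "LB"))
  rdm <- item_level_rdm(vol, 1:3, c("LA", "LB"))
  for (i in 1:2) {
    for (j in 1:2) {
      expect_equal(rdm$values[i, j],
                   atanh(oracle_pearson(pats[, i], pats[, j + 2])),
                   tolerance = 1e-12)
    }
  }
  expect_equal(rdm$sign_convention, "similarity")
  # duplicated maps give the clamped maximum on the diagonal
  dup <- cbind(pats[, 1:2], pats[, 1:2])
  colnames(dup) <- c("a1", "a2", "b1", "b2")
  vol2 <- make_item_volume(dup, languages = c("LA", "LA", "LB", "LB"))
  rdm2 <- item_level_rdm(vol2, 1:3, c("LA", "LB"))
  expect_equal(unname(diag(rdm2$values)), rep(atanh(1 - 1e-7), 2))
  # missing maps are reported by id
  vol3 <- vol
  vol3$languages <- c(vol3$languages, extra = "LB")
  expect_error(item_level_rdm(vol3, 1:3, c("LA", "LB")), "extra")
})

test_that("averaging neural RDMs is cell-wise on the z scale", {
  pats <- cbind(a1 = c(1, 2, 3), a2 = c(3, 2, 1),
                b1 = c(1, 2, 4), b2 = c(3, 1, 1))
  vol <- make_item_volume(pats, languages = c("LA", "LA", "LB", "LB"))
  r1 <- item_level_rdm(vol, 1:3, c("LA", "LB"))
  r2 <- r1; r2$values <- r1$values + 1
  avg <- average_neural_rdms(list(r1, r2))
  expect_equal(avg$values, r1$values + 0.5)
})
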