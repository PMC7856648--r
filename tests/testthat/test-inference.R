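make_scores <- function(za, zb, roi = "1") {
  n <- length(za)
  data.frame(subject_id = rep(sprintf("s%02d", 1:n), 2),
             roi = roi, roi_name = "box",
             pair = rep(c("L1-L3", "L1-L2"), each = n),
             z = c(za, zb), stringsAsFactors = FALSE)
}

test_that("two-level repeated-measures F equals the squared paired t", {
  set.seed(31)
  for (i in 1:10) {
    za <- rnorm(12); zb <- rnorm(12)
    res <- rm_anova_pair(make_scores(za, zb), "1",
                         pair_order = c("L1-L3", "L1-L2"))
    tt <- t.test(za, zb, paired = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
    expect_equal(res$p, tt$p.value, tolerance = 1e-12)
    # and the full RM-ANOVA decomposition agrees
    df <- data.frame(z = c(za, zb),
                     pair = factor(rep(c("a", "b"), each = 12)),
                     subj = factor(rep(1:12, 2)))
    fit <- summary(aov(z ~ pair + Error(subj/pair), data = df))
    Fa <- fit[["Error: subj:pair"]][[1]]["pair", "F value"]
    expect_equal(res$F, Fa, tolerance = 1e-8)
  }
})

test_that("paired contrast reproduces the hand-computed example", {
  d <- c(0.2, 0.1, 0.3, 0.0, 0.4)
  res <- rm_anova_pair(make_scores(d, rep(0, 5)), "1",
                       pair_order = c("L1-L3", "L1-L2"))
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$F, t_oracle^2, tolerance = 1e-12)
  expect_equal(res$df, c(1L, 4L))
  # constant nonzero differences have no variance to test against
  expect_error(rm_anova_pair(make_scores(rep(0.3, 5), rep(0, 5)), "1"),
               "variance")
})

test_that("covariate adjustment behaves across the designed cases", {
  set.seed(77)
  d <- rnorm(15, mean = 0.3)
  scores <- make_scores(d, rep(0, 15))
  subs <- sprintf("s%02d", 1:15)
  # covariate orthogonal to the differences by construction
  cv <- rnorm(15)
  cv <- stats::setNames(residuals(lm(cv ~ d)), subs)
  plain <- rm_anova_pair(scores, "1", c("L1-L3", "L1-L2"))
  adj <- ancova_pair(scores, "1", cv, c("L1-L3", "L1-L2"))
  expect_true(adj$adjusted)
  expect_equal(adj$F, plain$F, tolerance = 0.15 * plain$F)
  # covariate identical to the differences is fully absorbed: the fit is
  # exact, leaving (numerically) no residual variance against the intercept
  full <- suppressWarnings(   # lm flags the (intended) perfect fit
    ancova_pair(scores, "1", stats::setNames(d, subs), c("L1-L3", "L1-L2")))
  expect_true(full$adjusted)
  expect_gt(full$F, plain$F)
  # zero-variance covariate falls back with a warning
  expect_warning(
    flat <- ancova_pair(scores, "1", stats::setNames(rep(1, 15), subs),
                        c("L1-L3", "L1-L2")),
    "zero variance")
  expect_equal(flat$F, plain$F)
})

test_that("Bonferroni threshold is alpha over the family size", {
  res <- bonferroni_flags(rep(0.5, 10), alpha = 0.05)
  expect_equal(res$threshold, 0.005)
  expect_equal(bonferroni_flags(0.2)$threshold, 0.05)
  flags <- bonferroni_flags(c(0.004, 0.006, rep(0.5, 8)), alpha = 0.05)
  expect_equal(flags$significant[1:2], c(TRUE, FALSE))
  expect_error(bonferroni_flags(c(0.5, 1.2)), "0, 1")
})

test_that("RDM Spearman respects ranks and the sign convention", {
  set.seed(3)
  # bare matrices are taken as dissimilarities: monotone transform -> 1
  neural <- matrix(rnorm(25), 5)
  expect_equal(spearman_rdm(neural, exp(neural)), 1)
  expect_equal(spearman_rdm(matrix(c(1, 3, 2, 4), 2),
                            matrix(c(4, 2, 3, 1), 2)), -1)
  # a neural_rdm stores similarities: negation flips the sign
  nr <- structure(list(values = neural, row_items = letters[1:5],
                       col_items = letters[6:10], subject_id = "s01",
                       roi = "1", sign_convention = "similarity"),
                  class = "neural_rdm")
  mod <- structure(list(values = exp(neural), row_items = letters[1:5],
                        col_items = letters[6:10],
                        feature_kind = "visual"),
                   class = "prediction_rdm")
  expect_equal(spearman_rdm(nr, mod, sign_convention = "negate"), -1)
  expect_equal(spearman_rdm(nr, mod, sign_convention = "as_is"), 1)
  expect_error(spearman_rdm(neural, matrix(1, 5, 5)), "constant")
  # null calibration: independent matrices hover near zero
  set.seed(11)
  rhos <- replicate(100, spearman_rdm(matrix(rnorm(400), 20),
                                      matrix(rnorm(400), 20)))
  expect_lt(abs(mean(rhos)), 3 / sqrt(400))
})

test_that("partial Spearman matches a brute-force residualization oracle", {
  set.seed(8)
  ctrl <- matrix(rnorm(36), 6)
  target <- matrix(rnorm(36), 6)
  neural <- target + ctrl + matrix(rnorm(36, sd = 0.3), 6)
  got <- partial_spearman_rdm(neural, target, list(ctrl))
  # oracle: rank everything, project out the control by explicit least
  # squares, correlate the residuals
  rk <- function(m) rank(as.vector(m))
  rn <- rk(neural); rt <- rk(target); rc <- rk(ctrl)
  X <- cbind(1, rc)
  beta <- solve(t(X) %*% X, t(X) %*% cbind(rn, rt))
  res <- cbind(rn, rt) - X %*% beta
  expect_equal(got, oracle_pearson(res[, 1], res[, 2]), tolerance = 1e-10)
  # removing the control's shared noise sharpens the target correlation
  expect_gt(got, spearman_rdm(neural, target))
  # no controls reduces to the marginal Spearman
  expect_equal(partial_spearman_rdm(neural, target),
               spearman_rdm(neural, target), tolerance = 1e-12)
  # self-adjustment: a control collinear with the target leaves no unique
  # variance, so the partial correlation collapses to 0 (with a warning)
  expect_warning(self <- partial_spearman_rdm(neural, target, list(target)),
                 "collinear")
  expect_equal(self, 0)
})

test_that("permutation test is deterministic, bounded and rank-invariant", {
  set.seed(14)
  model <- matrix(runif(64), 8)
  neural <- model + matrix(rnorm(64, sd = 0.1), 8)
  p1 <- permutation_test_rdm(neural, model, n_perm = 200, seed = 42)
  p2 <- permutation_test_rdm(neural, model, n_perm = 200, seed = 42)
  expect_identical(p1$perms, p2$perms)
  expect_identical(p1$p, p2$p)
  # observed beats all permutations -> p = 0 under the k/n convention
  expect_equal(p1$p, 0)
  p3 <- permutation_test_rdm(neural, model, n_perm = 200, seed = 42,
                             convention = "add_one")
  expect_equal(p3$p, 1 / 201)
  # invariant under common monotone transforms (rank statistic)
  p4 <- permutation_test_rdm(neural, exp(model), n_perm = 200, seed = 42)
  expect_identical(p1$perms, p4$perms)
  expect_identical(p1$p, p4$p)
})

test_that("voxelwise group maps threshold equivalent-Z correctly", {
  set.seed(6)
  dims <- c(5L, 5L, 5L)
  n <- 12
  # planted positive region
  maps <- lapply(1:n, function(i) {
    m <- array(rnorm(prod(dims)), dims)
    m[1:2, 1:2, 1:2] <- m[1:2, 1:2, 1:2] + 3
    m
  })
  res <- group_voxelwise_map(maps, threshold = 3.1)
  expect_true(all(res$zmap[res$suprathreshold] > 3.1))
  expect_true(all(res$suprathreshold[1:2, 1:2, 1:2]))
  # t and Z agree in tail probability at a few voxels
  tv <- res$tmap[3, 3, 3]
  expect_equal(pt(abs(tv), n - 1, lower.tail = FALSE),
               pnorm(abs(res$zmap[3, 3, 3]), lower.tail = FALSE),
               tolerance = 1e-10)
  # identical constant maps are capped, not infinite
  const <- lapply(1:5, function(i) array(1, dims))
  res2 <- group_voxelwise_map(const)
  expect_true(all(is.finite(res2$zmap)))
  expect_equal(res2$n_capped, prod(dims))
  expect_error(group_voxelwise_map(maps[1:2]), "3 subjects")
  bad <- maps; bad[[2]] <- array(0, dims + 1L)
  expect_error(group_voxelwise_map(bad), "misaligned")
})

test_that("inverse efficiency divides reaction time by accuracy", {
  expect_equal(inverse_efficiency(900, 0.9), 1000)
  expect_equal(inverse_efficiency(750, 1), 750)
  expect_equal(inverse_efficiency(982.33, 0.9799), 982.33 / 0.9799)
  expect_error(inverse_efficiency(900, 0), "accuracy")
})

test_that("t-test power matches theory and a Monte-Carlo oracle", {
  expect_equal(ttest_power(0, 20), 0.05, tolerance = 1e-12)
  expect_gt(ttest_power(1.651, 23), 0.999)
  # cross-check against power.t.test (independent implementation; it
  # neglects the opposite rejection tail, hence the loose tolerance)
  expect_equal(ttest_power(0.5, 20),
               power.t.test(n = 20, delta = 0.5, sd = 1,
                            type = "one.sample")$power,
               tolerance = 1e-4)
  # Monte-Carlo rejection-rate oracle
  set.seed(123)
  nrep <- 20000
  x <- matrix(rnorm(20 * nrep, mean = 0.5), nrow = 20)
  tstat <- colMeans(x) / (apply(x, 2, sd) / sqrt(20))
  rej <- mean(abs(tstat) > qt(0.975, 19))
  expect_equal(ttest_power(0.5, 20), rej, tolerance = 0.02)
})
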