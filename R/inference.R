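# Group-level inference: pair contrasts with covariates, Bonferroni
# control, model-RDM Spearman/partial-Spearman correlations with
# permutation tests, voxelwise group maps, and behavioral/power helpers.

#' Repeated-measures contrast of two language pairs in one ROI
#'
#' One-way repeated-measures ANOVA with two within-subject levels (the two
#' cross-language pairs), computed via the paired t statistic: `F = t^2`
#' with `df = (1, n - 1)` — the exact two-level RM-ANOVA identity.
#'
#' @param scores data frame with columns `subject_id`, `roi`, `pair`, `z`;
#'   both pairs must be present for every subject in the ROI.
#' @param roi ROI id to test.
#' @param pair_order character pair giving the direction of the difference
#'   (`z[pair_order[1]] - z[pair_order[2]]`); defaults to the two pairs in
#'   table order.
#' @return list with `F`, `df`, `p`, `t`, `mean_diff`, `n`.
#' @export
rm_anova_pair <- function(scores, roi, pair_order = NULL) {
  s <- scores[scores$roi == roi, , drop = FALSE]
  pairs <- pair_order %||% unique(s$pair)
  if (length(pairs) != 2L) stopf("exactly two pairs are required")
  wide <- merge(s[s$pair == pairs[1L], c("subject_id", "z")],
                s[s$pair == pairs[2L], c("subject_id", "z")],
                by = "subject_id", suffixes = c(".a", ".b"))
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  n <- nrow(wide)
  if (n < 3L) stopf("need at least 3 subjects with both pair scores")
  d <- wide$z.a - wide$z.b
  if (var(d) == 0) stopf("zero within-subject difference variance")
  tval <- mean(d) / (sd(d) / sqrt(n))
  Fval <- tval^2
  list(F = Fval, df = c(1L, n - 1L),
       p = pf(Fval, 1, n - 1, lower.tail = FALSE),
       t = tval, mean_diff = mean(d), n = n)
}

#' Pair contrast adjusted for a subject-level covariate
#'
#' Tests the pair effect on the within-subject difference scores while
#' adjusting for a per-subject covariate (e.g. the reaction-time difference
#' between the two non-native languages). The covariate is mean-centred and
#' the difference scores are regressed on it; the reported F is the squared
#' t of the intercept (the adjusted pair effect at the mean covariate).
#' A constant covariate triggers a warning and falls back to
#' [rm_anova_pair()].
#'
#' @param scores as in [rm_anova_pair()].
#' @param roi ROI id.
#' @param covariate named numeric vector (names = subject ids) or data
#'   frame with columns `subject_id`, `value`.
#' @param pair_order as in [rm_anova_pair()].
#' @return list with `F`, `df`, `p`, `t`, `adjusted` (logical).
#' @export
ancova_pair <- function(scores, roi, covariate, pair_order = NULL) {
  if (is.data.frame(covariate)) {
    cv <- covariate$value
    names(cv) <- covariate$subject_id
  } else cv <- covariate
  s <- scores[scores$roi == roi, , drop = FALSE]
  pairs <- pair_order %||% unique(s$pair)
  wide <- merge(s[s$pair == pairs[1L], c("subject_id", "z")],
                s[s$pair == pairs[2L], c("subject_id", "z")],
                by = "subject_id", suffixes = c(".a", ".b"))
  if (!all(wide$subject_id %in% names(cv))) {
    stopf("covariate missing for subject(s): %s",
          paste(setdiff(wide$subject_id, names(cv)), collapse = ", "))
  }
  d <- wide$z.a - wide$z.b
  x <- cv[wide$subject_id]
  if (var(x) == 0) {
    warnf("covariate has zero variance; returning unadjusted contrast")
    out <- rm_anova_pair(scores, roi, pair_order)
    out$adjusted <- FALSE
    return(out)
  }
  x <- x - mean(x)
  fit <- stats::lm(d ~ x)
  ct <- summary(fit)$coefficients
  tval <- ct["(Intercept)", "t value"]
  n <- length(d)
  list(F = tval^2, df = c(1L, n - 2L),
       p = pf(tval^2, 1, n - 2, lower.tail = FALSE),
       t = tval, adjusted = TRUE)
}

#' Bonferroni significance flags
#'
#' Family-wise error control by dividing alpha by the number of tests:
#' with the 10 ROIs and alpha 0.05 the threshold is 0.005.
#'
#' @param pvals p values in `[0, 1]`.
#' @param alpha family-wise level.
#' @return list with `threshold` (`alpha / m`) and logical `significant`
#'   (`p < threshold`).
#' @export
bonferroni_flags <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stopf("p values must lie in [0, 1]")
  }
  thr <- alpha / length(pvals)
  list(threshold = thr, significant = pvals < thr)
}

# Vectorized cells of an RDM. neural_rdm objects store Fisher-z
# similarities and are negated to dissimilarities under the default sign
# convention; prediction RDMs and bare matrices are taken as already
# dissimilarity-coded.
rdm_cells <- function(rdm, sign_convention = "negate") {
  if (inherits(rdm, "neural_rdm")) {
    v <- as.vector(rdm$values)
    if (identical(sign_convention, "negate")) -v else v
  } else if (inherits(rdm, "prediction_rdm")) {
    as.vector(rdm$values)
  } else {
    as.vector(rdm)
  }
}

check_aligned <- function(neural, model) {
  gi <- function(x, f) if (is.list(x)) x[[f]] else dimnames(x)[[if (f == "row_items") 1 else 2]]
  rn <- gi(neural, "row_items"); rm_ <- gi(model, "row_items")
  cn <- gi(neural, "col_items"); cm <- gi(model, "col_items")
  if (!is.null(rn) && !is.null(rm_) &&
      (!identical(rn, rm_) || !identical(cn, cm))) {
    stopf("neural and model RDMs are not index-aligned")
  }
  nv <- if (is.list(neural)) neural$values else neural
  mv <- if (is.list(model)) model$values else model
  if (!all(dim(nv) == dim(mv))) stopf("RDM shapes differ")
}

#' Spearman correlation between a neural and a model RDM
#'
#' Rank correlation over all cells of the (non-symmetric) cross-language
#' matrices — rows and columns index different item sets, so no triangle is
#' extracted. Neural Fisher-z similarities are converted to dissimilarities
#' first (negation, under the default sign convention), so a positive rho
#' means the model's dissimilarity structure is present in the patterns.
#' Ties receive average ranks.
#'
#' @param neural a `neural_rdm` (or matrix).
#' @param model a `prediction_rdm` (or matrix).
#' @param sign_convention `"negate"` (default) or `"as_is"`.
#' @return Spearman rho.
#' @export
spearman_rdm <- function(neural, model, sign_convention = "negate") {
  check_aligned(neural, model)
  nv <- rdm_cells(neural, sign_convention)
  mv <- rdm_cells(model)
  if (var(mv) == 0) stopf("model matrix is constant; rank correlation undefined")
  if (var(nv) == 0) stopf("neural matrix is constant; rank correlation undefined")
  cor(nv, mv, method = "spearman")
}

#' Partial Spearman correlation controlling for other model RDMs
#'
#' Rank-transforms all matrices, residualizes the neural and target ranks
#' on the control ranks (with intercept), and correlates the residuals.
#' With no controls this equals [spearman_rdm()].
#'
#' @param neural a `neural_rdm` (or matrix).
#' @param target the model `prediction_rdm` of interest.
#' @param controls list of control `prediction_rdm`s.
#' @param sign_convention as in [spearman_rdm()].
#' @param tol collinearity tolerance: controls absorbing more than
#'   `1 - tol` of the target's rank variance leave no unique target
#'   variance, so the partial correlation is reported as 0 with a warning
#'   naming the controls (the self-adjustment case).
#' @return partial rank correlation.
#' @export
partial_spearman_rdm <- function(neural, target, controls = list(),
                                 sign_convention = "negate", tol = 1e-10) {
  check_aligned(neural, target)
  nv <- rank(rdm_cells(neural, sign_convention))
  tv <- rank(rdm_cells(target))
  if (length(controls) == 0L) {
    return(cor(nv, tv))
  }
  cm <- sapply(controls, function(cc) {
    check_aligned(neural, cc)
    rank(rdm_cells(cc))
  })
  X <- cbind(1, cm)
  res_t <- stats::lm.fit(X, tv)$residuals
  if (sum(res_t^2) < tol * sum((tv - mean(tv))^2)) {
    nm <- names(controls) %||% seq_along(controls)
    warnf("control matrix (%s) is collinear with the target; no unique target variance, partial correlation is 0",
          paste(nm, collapse = ", "))
    return(0)
  }
  res_n <- stats::lm.fit(X, nv)$residuals
  cor(res_n, res_t)
}

#' Permutation test for a neural-model RDM correlation
#'
#' Builds the null distribution by shuffling the item labels of the rows of
#' the model matrix `n_perm` times and recomputing the Spearman correlation
#' each time. One-sided (greater) by default: `p` is the proportion of
#' permuted statistics at or above the observed one (`k / n`); the
#' `"add_one"` convention returns `(k + 1) / (n + 1)` instead, which cannot
#' be exactly zero.
#'
#' @param neural a `neural_rdm` (or matrix).
#' @param model a `prediction_rdm` (or matrix).
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed recorded in the result.
#' @param sign_convention as in [spearman_rdm()].
#' @param convention `"proportion"` (default) or `"add_one"`.
#' @return a `perm_test`: list with `observed`, `perms`, `p`, `n_perm`,
#'   `seed`, `tail`.
#' @export
permutation_test_rdm <- function(neural, model, n_perm = 5000L, seed = NULL,
                                 sign_convention = "negate",
                                 convention = c("proportion", "add_one")) {
  convention <- match.arg(convention)
  if (n_perm < 1L) stopf("n_perm must be at least 1")
  check_aligned(neural, model)
  nv <- rdm_cells(neural, sign_convention)
  mv_mat <- if (is.list(model)) model$values else model
  if (var(as.vector(mv_mat)) == 0) stopf("model matrix is constant")
  if (var(nv) == 0) stopf("neural matrix is constant")
  nr <- nrow(mv_mat)
  # Spearman rho = Pearson on (tie-averaged) ranks; permuting row labels
  # permutes cells, so ranks can be computed once and re-indexed.
  rn <- rank(nv)
  rn <- (rn - mean(rn)) / sqrt(sum((rn - mean(rn))^2))
  rm_mat <- matrix(rank(as.vector(mv_mat)), nrow = nr)
  rmc <- as.vector(rm_mat)
  rmc_sd <- sqrt(sum((rmc - mean(rmc))^2))
  rho_of <- function(m) sum(rn * (as.vector(m) - mean(rmc))) / rmc_sd
  observed <- rho_of(rm_mat)
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      rho_of(rm_mat[sample.int(nr), , drop = FALSE])
    }, numeric(1))
  })
  k <- sum(perms >= observed)
  p <- switch(convention,
              proportion = k / n_perm,
              add_one = (k + 1) / (n_perm + 1))
  structure(list(observed = observed, perms = perms, p = p,
                 n_perm = n_perm, seed = seed, tail = "greater",
                 convention = convention),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test: observed rho = %.4f, p = %.4f (%d perms, %s tail)>\n",
              x$observed, x$p, x$n_perm, x$tail))
  invisible(x)
}

#' Thresholded voxelwise group map
#'
#' One-sample t test across subjects at every voxel of the per-subject
#' searchlight difference maps, converted to equivalent Gaussian Z, and
#' thresholded at `Z > threshold` (default 3.1; voxelwise only — no
#' cluster-level correction). Voxels with zero between-subject variance are
#' capped at `z_cap` and flagged.
#'
#' @param z_diff_maps list of aligned 3D arrays (one per subject), or a
#'   voxel-by-subject matrix.
#' @param threshold Z height threshold.
#' @param mask optional logical mask; voxels outside are `NA`.
#' @param z_cap cap for degenerate (zero-variance) voxels.
#' @return list with `zmap` (array or vector matching input), `tmap`,
#'   `suprathreshold` (logical), `threshold`, `df`, `n_capped`.
#' @export
group_voxelwise_map <- function(z_diff_maps, threshold = 3.1, mask = NULL,
                                z_cap = 40) {
  if (is.list(z_diff_maps)) {
    dims <- dim(z_diff_maps[[1L]])
    for (m in z_diff_maps) {
      if (!identical(dim(m), dims)) stopf("subject maps have misaligned grids")
    }
    X <- sapply(z_diff_maps, as.vector)
  } else {
    X <- as.matrix(z_diff_maps)
    dims <- NULL
  }
  n <- ncol(X)
  if (n < 3L) stopf("need at least 3 subjects")
  mu <- rowMeans(X)
  s <- sqrt(rowSums((X - mu)^2) / (n - 1))
  tval <- mu / (s / sqrt(n))
  df <- n - 1L
  # t -> Z via tail probability, evaluated on the log scale for stability
  z <- qnorm(pt(abs(tval), df, lower.tail = FALSE, log.p = TRUE),
             lower.tail = FALSE, log.p = TRUE) * sign(tval)
  degenerate <- !is.finite(tval)
  z[degenerate] <- sign(mu[degenerate]) * z_cap
  z[is.finite(z) & z > z_cap] <- z_cap
  z[is.finite(z) & z < -z_cap] <- -z_cap
  if (!is.null(mask)) {
    keep <- as.vector(mask)
    z[!keep] <- NA_real_
    tval[!keep] <- NA_real_
  }
  supra <- !is.na(z) & z > threshold
  if (!is.null(dims)) {
    dim(z) <- dims; dim(tval) <- dims; dim(supra) <- dims
  }
  list(zmap = z, tmap = tval, suprathreshold = supra,
       threshold = threshold, df = df, n_capped = sum(degenerate))
}

#' Inverse efficiency score
#'
#' Mean reaction time divided by accuracy, combining speed and errors into
#' one behavioral measure (ms).
#'
#' @param rt_ms mean reaction time in milliseconds (> 0).
#' @param acc proportion correct in `(0, 1]`.
#' @return IES in ms.
#' @export
inverse_efficiency <- function(rt_ms, acc) {
  if (any(acc <= 0) || any(acc > 1)) stopf("accuracy must lie in (0, 1]")
  if (any(rt_ms <= 0)) stopf("reaction time must be positive")
  rt_ms / acc
}

#' Power of a one-sample / paired t test
#'
#' Exact power from the noncentral t distribution with noncentrality
#' `d * sqrt(n)`.
#'
#' @param d Cohen's d effect size (>= 0).
#' @param n number of subjects (pairs).
#' @param alpha significance level.
#' @param two_sided two-sided test (default) or one-sided.
#' @return power in `[0, 1]`.
#' @export
ttest_power <- function(d, n, alpha = 0.05, two_sided = TRUE) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (n < 2) stopf("need at least 2 subjects")
  if (d < 0) stopf("effect size must be non-negative")
  df <- n - 1
  ncp <- d * sqrt(n)
  if (two_sided) {
    tc <- qt(1 - alpha / 2, df)
    pt(-tc, df, ncp) + pt(tc, df, ncp, lower.tail = FALSE)
  } else {
    tc <- qt(1 - alpha, df)
    pt(tc, df, ncp, lower.tail = FALSE)
  }
}
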