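# Pattern similarity: Fisher-z Pearson correlations between multivoxel
# activation patterns — within/between language, searchlight, ROI-level and
# item-level cross-language neural RDMs.

#' Fisher's z transform
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, with `r` clamped to
#' `±(1 - 1e-7)` first so degenerate identical patterns stay finite.
#' Averages of correlations are always taken on this scale.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @param clamp clamping bound.
#' @return Fisher-z value(s).
#' @export
fisher_z <- function(r, clamp = 1 - 1e-7) {
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) {
    stopf("correlation outside [-1, 1]")
  }
  atanh(pmin(pmax(r, -clamp), clamp))
}

#' Pearson correlation between two activation patterns
#'
#' Voxels that are not finite in either pattern are removed pairwise. If
#' fewer than 3 voxels remain, or either pattern has zero variance, the
#' value is undefined and `NA` is returned (flagged via the
#' `"reason"` attribute).
#'
#' @param x,y numeric vectors of equal length.
#' @return Pearson r, or flagged `NA`.
#' @export
pattern_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("patterns have different lengths")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    return(structure(NA_real_, reason = "fewer than 3 usable voxels"))
  }
  if (var(x) == 0 || var(y) == 0) {
    return(structure(NA_real_, reason = "zero-variance pattern"))
  }
  cor(x, y)
}

similarity_record <- function(subject_id, scope, pair, z, n_voxels) {
  data.frame(subject_id = subject_id, scope = scope, pair = pair,
             z = z, n_voxels = n_voxels, stringsAsFactors = FALSE)
}

#' Cross-language pattern similarity in a voxel set
#'
#' For each run, the activation patterns of the two language conditions are
#' correlated over the voxel set; the correlations are Fisher-z transformed
#' and averaged across runs (mean of z values, never z of the mean r).
#'
#' @param vol condition-level [pattern_volume()].
#' @param pair character pair of language tags, e.g. `c("L1", "L3")`.
#' @param voxel_set as in [extract_patterns()].
#' @param min_voxels minimum usable voxels.
#' @return one-row `data.frame`: `subject_id`, `scope`, `pair`, `z`,
#'   `n_voxels` (`z` is `NA` when flagged).
#' @export
cross_language_similarity <- function(vol, pair, voxel_set,
                                      min_voxels = 3L) {
  runs <- sort(unique(vol$index$run))
  scope <- attr(voxel_set, "scope") %||% "voxel_set"
  zs <- numeric(0)
  nv <- NA_integer_
  for (r in runs) {
    a <- extract_patterns(vol, voxel_set, pair[1L], r, min_voxels)
    b <- extract_patterns(vol, voxel_set, pair[2L], r, min_voxels)
    if (length(a) == 0L || length(b) == 0L) {
      return(similarity_record(vol$subject_id, scope,
                               paste(pair, collapse = "-"),
                               NA_real_, 0L))
    }
    nv <- length(a)
    zs <- c(zs, fisher_z(pattern_correlation(a, b)))
  }
  similarity_record(vol$subject_id, scope, paste(pair, collapse = "-"),
                    mean(zs), nv)
}

#' Within- and between-language split-run similarity
#'
#' Validity check of the RSA: within-language similarity correlates a
#' language's pattern in run 1 with the same language's pattern in run 2;
#' between-language similarity crosses languages across runs (both run
#' orderings, averaged on the Fisher-z scale).
#'
#' @param vol condition-level [pattern_volume()] with two runs.
#' @param voxel_set as in [extract_patterns()].
#' @param min_voxels minimum usable voxels.
#' @return `data.frame` with one `within:<lang>` row per language and one
#'   `between:<A>-<B>` row per unordered language pair.
#' @export
within_between_similarity <- function(vol, voxel_set, min_voxels = 3L) {
  runs <- sort(unique(vol$index$run))
  if (length(runs) != 2L) stopf("within/between similarity needs exactly 2 runs")
  langs <- unique(vol$index$unit)
  scope <- attr(voxel_set, "scope") %||% "voxel_set"
  pat <- function(l, r) extract_patterns(vol, voxel_set, l, r, min_voxels)
  out <- list()
  for (l in langs) {
    a <- pat(l, runs[1L]); b <- pat(l, runs[2L])
    z <- if (length(a) && length(b)) fisher_z(pattern_correlation(a, b)) else NA_real_
    out[[length(out) + 1L]] <- similarity_record(
      vol$subject_id, scope, paste0("within:", l), z, length(a))
  }
  if (length(langs) > 1L) {
    cmb <- utils::combn(langs, 2L)
    for (j in seq_len(ncol(cmb))) {
      la <- cmb[1L, j]; lb <- cmb[2L, j]
      z1 <- fisher_z(pattern_correlation(pat(la, runs[1L]), pat(lb, runs[2L])))
      z2 <- fisher_z(pattern_correlation(pat(la, runs[2L]), pat(lb, runs[1L])))
      out[[length(out) + 1L]] <- similarity_record(
        vol$subject_id, scope, paste0("between:", la, "-", lb),
        mean(c(z1, z2)), length(pat(la, runs[1L])))
    }
  }
  do.call(rbind, out)
}

#' Searchlight map of cross-language similarity
#'
#' For every in-mask voxel, computes the Fisher-z pattern similarity on the
#' cubic neighborhood of side `2 * half_width + 1` centred there (125 voxels
#' at the default half-width 2), truncated at the volume boundary. A voxel
#' is computed only when at least `min_mask_frac` of its cube lies in-mask;
#' otherwise, and outside the mask, the map holds `NA`.
#'
#' @param vol condition-level [pattern_volume()].
#' @param pair language pair for [cross_language_similarity()], or `NULL`
#'   when `contrast = "within_between"`.
#' @param half_width cube half-width (default 2).
#' @param contrast `"pair"` (default) maps the pair's similarity;
#'   `"within_between"` maps mean within-language minus mean
#'   between-language z.
#' @param min_mask_frac minimum in-mask fraction of the cube.
#' @param min_voxels minimum usable voxels for a correlation.
#' @return 3D array of z values (`NA` where not computed).
#' @export
searchlight_map <- function(vol, pair = NULL, half_width = 2L,
                            contrast = c("pair", "within_between"),
                            min_mask_frac = 0.5, min_voxels = 3L) {
  contrast <- match.arg(contrast)
  if (contrast == "pair" && is.null(pair)) stopf("pair must be given")
  dims <- vol$dims
  if (!any(vol$mask)) stopf("empty brain mask")
  out <- array(NA_real_, dim = dims)
  centers <- which(vol$mask)
  coord <- arrayInd(centers, dims)
  full_cube <- (2L * half_width + 1L)^3L
  for (k in seq_along(centers)) {
    idx <- cube_indices(coord[k, ], half_width, dims)
    in_mask <- idx[vol$mask[idx]]
    if (length(in_mask) < min_mask_frac * full_cube) next
    vs <- in_mask
    if (contrast == "pair") {
      rec <- cross_language_similarity(vol, pair, vs, min_voxels)
      out[centers[k]] <- rec$z
    } else {
      wb <- within_between_similarity(vol, vs, min_voxels)
      w <- wb$z[startsWith(wb$pair, "within:")]
      b <- wb$z[startsWith(wb$pair, "between:")]
      out[centers[k]] <- mean(w, na.rm = TRUE) - mean(b, na.rm = TRUE)
    }
  }
  out
}

#' ROI-level similarity table
#'
#' One Fisher-z similarity record per (subject, ROI, language pair); ROIs
#' falling below the minimum voxel count inside the mask are flagged `NA`.
#'
#' @param vol condition-level [pattern_volume()].
#' @param rois an [roi_set()] aligned to the volume grid.
#' @param pairs list of language pairs (character vectors of length 2).
#' @param min_voxels minimum usable voxels.
#' @return `data.frame` with columns `subject_id`, `roi`, `roi_name`,
#'   `pair`, `z`, `n_voxels`.
#' @export
roi_similarity_table <- function(vol, rois, pairs, min_voxels = 3L) {
  if (!all(rois$dims == vol$dims)) stopf("ROI set not aligned to volume grid")
  ids <- names(rois$label_table)
  out <- list()
  for (id in ids) {
    vs <- roi_voxels(rois, as.integer(id))
    for (p in pairs) {
      rec <- cross_language_similarity(vol, p, vs, min_voxels)
      rec$scope <- NULL
      rec <- cbind(subject_id = rec$subject_id, roi = id,
                   roi_name = unname(rois$label_table[id]),
                   rec[c("pair", "z", "n_voxels")])
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Item-level cross-language neural RDM
#'
#' For one ROI and one language pair, correlates the ROI voxel pattern of
#' every item of the first language with that of every item of the second
#' (each item's map comes from the run the item was shown in), yielding the
#' 80 x 80 matrix of Fisher-z Pearson correlations at the default design.
#' Cells are stored as similarities; the `sign_convention` field records
#' how they should be read (negated to act as dissimilarities during model
#' comparison, see [spearman_rdm()]).
#'
#' @param vol item-level [pattern_volume()] with a `languages` map.
#' @param voxel_set ROI spec as in [extract_patterns()].
#' @param pair language pair `c(langA, langB)`.
#' @param roi label or name used for bookkeeping.
#' @param min_voxels minimum usable voxels.
#' @return a `neural_rdm`: list with `values` (z matrix, dimnames = item
#'   ids), `row_items`, `col_items`, `subject_id`, `roi`,
#'   `sign_convention = "similarity"`.
#' @export
item_level_rdm <- function(vol, voxel_set, pair, roi = "roi",
                           min_voxels = 3L) {
  if (is.null(vol$languages)) stopf("item-level volume lacks a languages map")
  items_a <- names(vol$languages)[vol$languages == pair[1L]]
  items_b <- names(vol$languages)[vol$languages == pair[2L]]
  missing <- setdiff(c(items_a, items_b), vol$index$unit)
  if (length(missing)) {
    stopf("missing item map(s): %s", paste(missing, collapse = ", "))
  }
  idx <- resolve_voxel_set(voxel_set, vol$dims)
  idx <- idx[vol$mask[idx]]
  if (length(idx) < min_voxels) stopf("fewer than %d usable voxels in ROI",
                                      min_voxels)
  grab <- function(items) {
    sapply(items, function(it) {
      run <- vol$index$run[vol$index$unit == it][1L]
      vol_map(vol, run, it)[idx]
    })
  }
  pa <- grab(items_a)   # n_vox x n_items_a
  pb <- grab(items_b)
  r <- cor(pa, pb)
  z <- fisher_z(r)
  dimnames(z) <- list(items_a, items_b)
  structure(list(values = z, row_items = items_a, col_items = items_b,
                 subject_id = vol$subject_id, roi = roi,
                 sign_convention = "similarity"),
            class = "neural_rdm")
}

#' @export
print.neural_rdm <- function(x, ...) {
  cat(sprintf("<neural_rdm %s roi=%s: %d x %d Fisher-z (%s)>\n",
              x$subject_id, x$roi, nrow(x$values), ncol(x$values),
              x$sign_convention))
  invisible(x)
}

#' Average neural RDMs across subjects
#'
#' Cell-wise mean on the Fisher-z scale over a list of index-aligned
#' `neural_rdm`s.
#'
#' @param rdms list of `neural_rdm` objects with identical item indices.
#' @return a `neural_rdm` with `subject_id = "group"`.
#' @export
average_neural_rdms <- function(rdms) {
  ref <- rdms[[1L]]
  for (r in rdms[-1L]) {
    if (!identical(r$row_items, ref$row_items) ||
        !identical(r$col_items, ref$col_items)) {
      stopf("neural RDMs are not index-aligned")
    }
  }
  vals <- Reduce(`+`, lapply(rdms, `[[`, "values")) / length(rdms)
  out <- ref
  out$values <- vals
  out$subject_id <- "group"
  out
}
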