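# Pattern volumes, ROI label sets and voxel selection.
#
# A pattern_volume holds a per-subject stack of 3D statistic maps (T-map
# proxies), one per (run, unit), where a unit is either a language condition
# (condition-level stack) or an item id (item-level stack). Maps are stored
# flattened in the native R column-major order, i.e. the x index varies
# fastest, then y, then z; all voxel orderings in the package follow this
# convention.

#' Construct a pattern volume
#'
#' @param data numeric matrix, `prod(dims)` rows (voxels, x-fastest order)
#'   by one column per map.
#' @param index data frame with one row per column of `data`: `run`
#'   (integer) and `unit` (language tag or item id). For a condition-level
#'   stack every unit must appear in every run; item-level units appear in
#'   exactly one run each.
#' @param dims integer triple of grid dimensions.
#' @param mask logical vector/array of in-brain voxels (default all).
#' @param subject_id subject identifier.
#' @param level `"condition"` or `"item"`.
#' @param languages optional map unit -> language tag for item-level stacks.
#' @return a list of class `pattern_volume`.
#' @export
pattern_volume <- function(data, index, dims, mask = NULL,
                           subject_id = "s01",
                           level = c("condition", "item"),
                           languages = NULL) {
  level <- match.arg(level)
  dims <- as.integer(dims)
  if (length(dims) != 3L) stopf("dims must have length 3")
  data <- as.matrix(data)
  if (nrow(data) != prod(dims)) {
    stopf("data has %d rows but prod(dims) = %d", nrow(data), prod(dims))
  }
  if (nrow(index) != ncol(data)) {
    stopf("index has %d rows for %d maps", nrow(index), ncol(data))
  }
  mask <- if (is.null(mask)) rep(TRUE, prod(dims)) else as.logical(mask)
  dim(mask) <- NULL
  if (length(mask) != prod(dims)) stopf("mask length does not match dims")
  index$run <- as.integer(index$run)
  index$unit <- as.character(index$unit)
  if (level == "condition") {
    runs <- sort(unique(index$run))
    if (length(runs) < 2L) stopf("condition-level stacks need two runs")
    for (u in unique(index$unit)) {
      have <- index$run[index$unit == u]
      if (!all(runs %in% have)) {
        stopf("condition %s is missing from run(s) %s",
              sQuote(u), paste(setdiff(runs, have), collapse = ", "))
      }
    }
  }
  if (anyDuplicated(index[c("run", "unit")])) {
    stopf("duplicate (run, unit) maps in volume")
  }
  colnames(data) <- paste(index$run, index$unit, sep = ":")
  structure(list(data = data, index = index, dims = dims, mask = mask,
                 subject_id = subject_id, level = level,
                 languages = languages),
            class = "pattern_volume")
}

#' @export
print.pattern_volume <- function(x, ...) {
  cat(sprintf("<pattern_volume %s: %s-level, %d maps on %s grid, %d in-mask voxels>\n",
              x$subject_id, x$level, ncol(x$data),
              paste(x$dims, collapse = "x"), sum(x$mask)))
  invisible(x)
}

# full-grid vector for one (run, unit) map
vol_map <- function(vol, run, unit) {
  key <- paste(run, unit, sep = ":")
  j <- match(key, colnames(vol$data))
  if (is.na(j)) stopf("no map for run %s, unit %s", run, sQuote(unit))
  vol$data[, j]
}

#' Construct an ROI label set
#'
#' @param labels integer vector/array over the grid; 0 = unlabeled.
#' @param dims grid dimensions.
#' @param names named character vector or plain character vector mapping
#'   label ids (1..k) to region names.
#' @return a list of class `roi_set`.
#' @export
roi_set <- function(labels, dims, names = NULL) {
  dims <- as.integer(dims)
  labels <- as.integer(labels)
  dim(labels) <- NULL
  if (length(labels) != prod(dims)) stopf("label volume does not match dims")
  ids <- sort(unique(labels[labels > 0L]))
  if (is.null(names)) names <- paste0("roi", ids)
  if (is.null(base::names(names))) base::names(names) <- as.character(ids)
  structure(list(labels = labels, dims = dims, label_table = names),
            class = "roi_set")
}

#' Default bilateral phonological-network region names
#'
#' The ten regions used in the ROI analysis: pars opercularis, precentral
#' gyrus, angular gyrus, posterior superior temporal gyrus and supramarginal
#' gyrus in the left and right hemispheres.
#'
#' @return character vector of 10 names.
#' @export
default_roi_names <- function() {
  regions <- c("pars opercularis", "precentral gyrus", "angular gyrus",
               "posterior superior temporal gyrus", "supramarginal gyrus")
  out <- as.vector(t(outer(c("L", "R"), regions, paste)))
  names(out) <- as.character(seq_along(out))
  out
}

roi_voxels <- function(rois, label) which(rois$labels == label)

#' Linear indices of a cubic searchlight neighborhood
#'
#' The cube of side `2 * half_width + 1` centred on `center`, truncated at
#' the volume boundary. Indices are returned in x-fastest order.
#'
#' @param center integer triple of 1-based voxel coordinates.
#' @param half_width cube half-width in voxels (2 gives the 125-voxel cube).
#' @param dims grid dimensions.
#' @return integer vector of linear voxel indices.
#' @export
cube_indices <- function(center, half_width, dims) {
  if (half_width < 1L) stopf("half_width must be at least 1")
  rng <- function(c, d) max(1L, c - half_width):min(d, c + half_width)
  xs <- rng(center[1L], dims[1L])
  ys <- rng(center[2L], dims[2L])
  zs <- rng(center[3L], dims[3L])
  # x varies fastest, then y, then z
  as.integer(outer(outer(xs, (ys - 1L) * dims[1L], "+"),
                   (zs - 1L) * dims[1L] * dims[2L], "+"))
}

# Resolve a voxel-set spec to linear indices (before masking):
#   integer vector | logical vector/array | list(center=, half_width=) |
#   list(rois = roi_set, label = id)
resolve_voxel_set <- function(voxel_set, dims) {
  if (is.list(voxel_set) && !is.null(voxel_set$center)) {
    cube_indices(voxel_set$center, voxel_set$half_width %||% 2L, dims)
  } else if (is.list(voxel_set) && !is.null(voxel_set$rois)) {
    roi_voxels(voxel_set$rois, voxel_set$label)
  } else if (is.logical(voxel_set)) {
    which(as.vector(voxel_set))
  } else {
    as.integer(voxel_set)
  }
}

#' Extract an activation pattern
#'
#' Values of one statistic map at a voxel set (intersected with the brain
#' mask), in the package's fixed x-fastest voxel order. When fewer than
#' `min_voxels` usable voxels remain, a flagged empty result is returned
#' (length-0 vector with attribute `flag = "too_few_voxels"`).
#'
#' @param vol a [pattern_volume()].
#' @param voxel_set integer linear indices, a logical mask, a cube spec
#'   `list(center =, half_width =)`, or `list(rois =, label =)`.
#' @param unit condition tag or item id.
#' @param run run number.
#' @param min_voxels minimum usable voxel count (default 3).
#' @return numeric vector of statistic values (possibly flagged empty).
#' @export
extract_patterns <- function(vol, voxel_set, unit, run, min_voxels = 3L) {
  idx <- resolve_voxel_set(voxel_set, vol$dims)
  idx <- idx[vol$mask[idx]]
  if (length(idx) < min_voxels) {
    return(structure(numeric(0), flag = "too_few_voxels"))
  }
  vol_map(vol, run, unit)[idx]
}

# ---- NIfTI I/O ------------------------------------------------------------

#' Write / read a pattern volume as NIfTI + index TSV
#'
#' The stack is written as one 4D NIfTI (identity affine) plus an index TSV
#' (`run`, `unit`) and a 3D mask NIfTI, under `prefix_maps.nii.gz`,
#' `prefix_index.tsv` and `prefix_mask.nii.gz`.
#'
#' @param vol a [pattern_volume()].
#' @param prefix file path prefix.
#' @return `read_pattern_volume` returns a `pattern_volume`.
#' @export
write_pattern_volume <- function(vol, prefix) {
  arr <- vol$data
  dim(arr) <- c(vol$dims, ncol(vol$data))
  RNifti::writeNifti(RNifti::asNifti(arr), paste0(prefix, "_maps.nii.gz"),
                     datatype = "double")
  m <- array(as.integer(vol$mask), dim = vol$dims)
  RNifti::writeNifti(RNifti::asNifti(m), paste0(prefix, "_mask.nii.gz"),
                     datatype = "int16")
  idx <- vol$index
  idx$subject_id <- vol$subject_id
  idx$level <- vol$level
  utils::write.table(idx, paste0(prefix, "_index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_pattern_volume
#' @export
read_pattern_volume <- function(prefix) {
  arr <- RNifti::readNifti(paste0(prefix, "_maps.nii.gz"))
  idx <- read.delim(paste0(prefix, "_index.tsv"), stringsAsFactors = FALSE)
  mask <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))
  d <- dim(arr)
  if (length(d) != 4L) stopf("%s_maps.nii.gz is not a 4D stack", prefix)
  if (!all(dim(mask)[1:3] == d[1:3])) {
    stopf("mask dimensions do not match the map stack in %s", prefix)
  }
  if (nrow(idx) != d[4L]) {
    stopf("index rows (%d) do not match 4D volumes (%d)", nrow(idx), d[4L])
  }
  data <- matrix(as.numeric(arr), nrow = prod(d[1:3]), ncol = d[4L])
  pattern_volume(data, idx[c("run", "unit")], dims = d[1:3],
                 mask = as.vector(mask) != 0,
                 subject_id = idx$subject_id[1L] %||% "s01",
                 level = idx$level[1L] %||% "condition")
}

#' Write / read an ROI label set as NIfTI + label TSV
#'
#' @param rois an [roi_set()].
#' @param prefix file path prefix (writes `prefix_labels.nii.gz` and
#'   `prefix_labels.tsv`).
#' @return `read_roi_set` returns an `roi_set`.
#' @export
write_roi_set <- function(rois, prefix) {
  arr <- array(rois$labels, dim = rois$dims)
  RNifti::writeNifti(RNifti::asNifti(arr), paste0(prefix, "_labels.nii.gz"),
                     datatype = "int16")
  tab <- data.frame(label = names(rois$label_table),
                    name = unname(rois$label_table))
  utils::write.table(tab, paste0(prefix, "_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(prefix) {
  arr <- RNifti::readNifti(paste0(prefix, "_labels.nii.gz"))
  tab <- read.delim(paste0(prefix, "_labels.tsv"), stringsAsFactors = FALSE)
  nm <- tab$name
  names(nm) <- as.character(tab$label)
  roi_set(as.integer(arr), dims = dim(arr), names = nm)
}

#' Write a 3D statistic map as NIfTI
#'
#' @param map 3D numeric array (NA allowed; written as NaN).
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_map_nifti <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(map), path, datatype = "double")
  invisible(path)
}
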