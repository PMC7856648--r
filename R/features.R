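# Stimulus tables and prediction (model) RDMs.
#
# A stimulus table holds one row per word: item id, language tag,
# orthography, space-separated phoneme tokens, optional tone token and a
# semantic category. From it, three item-by-item prediction matrices are
# built: visual (silhouette pixel overlap), phonological (vowel-centric
# position matching) and semantic (category identity).

#' Default semantic category set
#'
#' Twelve noun categories used to label stimuli (human, animal, plants, ...).
#'
#' @return character vector of 12 category labels.
#' @export
default_categories <- function() {
  c("human", "animal", "plants", "food", "tool", "clothing",
    "vehicle", "building", "nature", "body", "furniture", "abstract")
}

#' Semantic dissimilarity of two category labels
#'
#' Item pairs from the same semantic category score 0, pairs from different
#' categories score 1.
#'
#' @param a,b category labels, both drawn from `categories`.
#' @param categories the configured category set.
#' @return 0 or 1.
#' @export
semantic_dissimilarity <- function(a, b, categories = default_categories()) {
  bad <- setdiff(c(a, b), categories)
  if (length(bad)) {
    stopf("unknown semantic category label(s): %s",
          paste(sQuote(bad), collapse = ", "))
  }
  as.numeric(a != b)
}

#' Assemble a stimulus table
#'
#' Validates and classes a data frame of stimulus items.
#'
#' @param df data frame with columns `item_id`, `language`, `orthography`,
#'   `phonemes` (space-separated phoneme tokens), optional `tone`
#'   (`NA` for non-tonal items) and `category`.
#' @param categories allowed category labels.
#' @return the validated data frame, classed `stimulus_table`.
#' @export
stimulus_table <- function(df, categories = default_categories()) {
  need <- c("item_id", "language", "orthography", "phonemes", "category")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("stimulus table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (!"tone" %in% names(df)) df$tone <- NA_character_
  if (anyDuplicated(df$item_id)) {
    stopf("duplicated item_id(s): %s",
          paste(unique(df$item_id[duplicated(df$item_id)]), collapse = ", "))
  }
  if (any(!nzchar(trimws(df$phonemes)))) {
    stopf("empty phoneme sequence for item(s): %s",
          paste(df$item_id[!nzchar(trimws(df$phonemes))], collapse = ", "))
  }
  bad <- setdiff(unique(df$category), categories)
  if (length(bad)) stopf("categories outside the configured set: %s",
                         paste(sQuote(bad), collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("stimulus_table", "data.frame")
  df
}

#' Read / write a stimulus table (TSV)
#'
#' @param path TSV file with the columns documented in [stimulus_table()].
#' @param categories allowed category labels.
#' @return a `stimulus_table`.
#' @export
read_stimulus_table <- function(path, categories = default_categories()) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  df$item_id <- as.character(df$item_id)
  stimulus_table(df, categories = categories)
}

#' @rdname read_stimulus_table
#' @param items a `stimulus_table`.
#' @export
write_stimulus_table <- function(items, path) {
  utils::write.table(items, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

phoneme_list <- function(items) {
  strsplit(trimws(items$phonemes), "\\s+")
}

#' Build a prediction RDM from stimulus items
#'
#' Computes the item-by-item model dissimilarity matrix for one feature kind.
#' Cell `(i, j)` is the pairwise dissimilarity of row item `i` and column
#' item `j`: silhouette pixel non-overlap (`"visual"`), vowel-centric phoneme
#' position mismatch (`"phonological"`), or category difference
#' (`"semantic"`). For the cross-language analyses `row_items` and
#' `col_items` are the 80 items of each language of a pair, giving the
#' 80 x 80 prediction matrix paired cell-by-cell with the neural RDM.
#'
#' @param row_items,col_items `stimulus_table`s (may be the same table).
#' @param feature_kind `"visual"`, `"phonological"` or `"semantic"`.
#' @param tone_mode passed to [phonological_dissimilarity()].
#' @param render_config passed to [render_silhouette()] for the visual kind.
#' @param normalizer passed to [visual_dissimilarity()].
#' @param categories allowed semantic categories.
#' @return a `prediction_rdm`: list with `values` (numeric matrix in
#'   `[0, 1]`, dimnames = item ids), `row_items`, `col_items`,
#'   `feature_kind`.
#' @export
build_prediction_rdm <- function(row_items, col_items = row_items,
                                 feature_kind = c("visual", "phonological",
                                                  "semantic"),
                                 tone_mode = c("include", "exclude"),
                                 render_config = silhouette_config(),
                                 normalizer = "union",
                                 categories = default_categories()) {
  feature_kind <- match.arg(feature_kind)
  tone_mode <- match.arg(tone_mode)
  check_fields <- function(items, col) {
    bad <- items$item_id[is.na(items[[col]]) | !nzchar(trimws(items[[col]]))]
    if (length(bad)) stopf("items missing %s needed for the %s feature: %s",
                           col, feature_kind, paste(bad, collapse = ", "))
  }
  nr <- nrow(row_items); nc <- nrow(col_items)
  vals <- matrix(NA_real_, nr, nc,
                 dimnames = list(row_items$item_id, col_items$item_id))
  if (feature_kind == "visual") {
    check_fields(row_items, "orthography"); check_fields(col_items, "orthography")
    # render each distinct orthography once
    orth <- unique(c(row_items$orthography, col_items$orthography))
    imgs <- lapply(orth, render_silhouette, config = render_config)
    names(imgs) <- orth
    for (i in seq_len(nr)) {
      a <- imgs[[row_items$orthography[i]]]
      for (j in seq_len(nc)) {
        vals[i, j] <- visual_dissimilarity(a, imgs[[col_items$orthography[j]]],
                                           normalizer = normalizer)
      }
    }
  } else if (feature_kind == "phonological") {
    check_fields(row_items, "phonemes"); check_fields(col_items, "phonemes")
    pr <- phoneme_list(row_items); pc <- phoneme_list(col_items)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        vals[i, j] <- phonological_dissimilarity(
          pr[[i]], pc[[j]],
          tone_a = row_items$tone[i], tone_b = col_items$tone[j],
          tone_mode = tone_mode)
      }
    }
  } else {
    check_fields(row_items, "category"); check_fields(col_items, "category")
    vals <- outer(row_items$category, col_items$category,
                  function(a, b) as.numeric(a != b))
    bad <- setdiff(unique(c(row_items$category, col_items$category)), categories)
    if (length(bad)) stopf("categories outside the configured set: %s",
                           paste(sQuote(bad), collapse = ", "))
    dimnames(vals) <- list(row_items$item_id, col_items$item_id)
  }
  structure(list(values = vals,
                 row_items = row_items$item_id,
                 col_items = col_items$item_id,
                 feature_kind = feature_kind),
            class = "prediction_rdm")
}

#' @export
print.prediction_rdm <- function(x, ...) {
  cat(sprintf("<prediction_rdm %s: %d x %d, range [%.3f, %.3f]>\n",
              x$feature_kind, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Write / read a prediction or neural RDM as CSV
#'
#' Values are stored with row/column item ids as headers.
#'
#' @param rdm a `prediction_rdm` or `neural_rdm`.
#' @param path CSV path.
#' @return `read_rdm_csv` returns the numeric matrix with dimnames.
#' @export
write_rdm_csv <- function(rdm, path) {
  vals <- if (is.list(rdm)) rdm$values else rdm
  write.csv(vals, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_rdm_csv
#' @export
read_rdm_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
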