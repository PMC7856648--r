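# Shared fixture builders: everything is generated in code at test time.

# glyph_image from a 0/1 matrix (rows = y, cols = x)
make_glyph <- function(px) {
  structure(list(pixels = px, width = ncol(px), height = nrow(px)),
            class = "glyph_image")
}

# small condition-level volume: 2 runs x 3 languages on a given grid,
# optionally with a run-stable language-specific signal added
make_cond_volume <- function(dims = c(8L, 8L, 8L), langs = c("L1", "L2", "L3"),
                             signal_sd = 0, noise_sd = 1, seed = 1,
                             subject_id = "s01", mask = NULL) {
  nvox <- prod(dims)
  set.seed(seed)
  sig <- sapply(langs, function(l) rnorm(nvox, sd = signal_sd))
  cols <- list(); idx <- list()
  for (run in 1:2) {
    for (l in langs) {
      cols[[length(cols) + 1L]] <- sig[, l] + rnorm(nvox, sd = noise_sd)
      idx[[length(idx) + 1L]] <- data.frame(run = run, unit = l)
    }
  }
  pattern_volume(do.call(cbind, cols), do.call(rbind, idx), dims,
                 mask = mask, subject_id = subject_id)
}

# item-level volume with explicit per-item patterns on a tiny grid
make_item_volume <- function(patterns, languages, runs = NULL,
                             dims = NULL, subject_id = "s01") {
  n <- ncol(patterns)
  dims <- dims %||% c(nrow(patterns), 1L, 1L)
  runs <- runs %||% rep(1L, n)
  ids <- colnames(patterns) %||% sprintf("it%02d", seq_len(n))
  idx <- data.frame(run = runs, unit = ids)
  names(languages) <- ids
  pattern_volume(patterns, idx, dims, subject_id = subject_id,
                 level = "item", languages = languages)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny GPC table used across the regularity tests
toy_gpc <- function() {
  gpc_table(data.frame(
    grapheme = c("p", "u", "u", "t", "s", "h", "sh", "oo", "o"),
    phoneme = c("p", "ʊ", "ʌ", "t", "s", "h", "ʃ", "uː", "ɒ"),
    probability = c(1, 0.6, 0.3, 1, 0.95, 0.9, 1, 0.8, 0.7),
    stringsAsFactors = FALSE))
}

# 6-item bilingual stimulus table for feature-RDM tests
toy_items <- function() {
  stimulus_table(data.frame(
    item_id = c("A1", "A2", "A3", "B1", "B2", "B3"),
    language = c("LA", "LA", "LA", "LB", "LB", "LB"),
    orthography = c("tam", "sol", "kip", "team", "sole", "keep"),
    phonemes = c("t ɑ m", "s o l", "k i p", "t iː m", "s oː l", "k iː p"),
    tone = NA_character_,
    category = c("animal", "plants", "tool", "animal", "food", "tool"),
    stringsAsFactors = FALSE))
}

# textbook Pearson correlation, used as an independent oracle
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
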