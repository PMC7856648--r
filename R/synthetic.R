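# Synthetic trilingual stimulus sets and multivoxel statistic volumes.
#
# The generator emulates the study design it stands in for: 3 languages
# (L1 = native, transparent; L2 = opaque, tonal; L3 = non-native,
# transparent) x 80 items each, shown once across 2 runs of 40 items per
# language, for 23 subjects. Item patterns are built from three feature
# channels — position-coded phonemes, downsampled silhouette pixels, and
# one-hot semantic category — embedded into voxel space by seeded Gaussian
# random projections, plus independent voxel noise. Cross-language sharing
# is planted only in the phonological channel: L1 and L3 load on a common
# phonological projection (the hypothesized shared orthography-to-phonology
# code of two transparent scripts), L2 does not.

#' Synthetic study design
#'
#' @param n_subjects number of subjects (default 23).
#' @param languages three language tags; roles are fixed as L1 = native
#'   transparent, L2 = opaque tonal, L3 = non-native transparent.
#' @param items_per_language items per language (default 80); must equal
#'   `runs * trials_per_language_per_run`.
#' @param runs functional runs (default 2).
#' @param trials_per_language_per_run items of each language per run (40).
#' @param dims voxel grid (default `c(24, 24, 24)`).
#' @param n_rois number of ROIs to place (default 10).
#' @param seed master seed recorded in all outputs.
#' @return list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_subjects = 23L,
                             languages = c("L1", "L2", "L3"),
                             items_per_language = 80L,
                             runs = 2L,
                             trials_per_language_per_run = 40L,
                             dims = c(24L, 24L, 24L),
                             n_rois = 10L,
                             seed = 1L) {
  if (length(languages) != 3L) stopf("exactly three languages are required")
  if (items_per_language != runs * trials_per_language_per_run) {
    stopf("items_per_language must equal runs * trials_per_language_per_run")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 languages = languages,
                 items_per_language = as.integer(items_per_language),
                 runs = as.integer(runs),
                 trials_per_language_per_run = as.integer(trials_per_language_per_run),
                 dims = as.integer(dims),
                 n_rois = as.integer(n_rois),
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Planted effect specification
#'
#' Channel weights and noise level of the generator. `shared_phon_strength`
#' gives, per language pair, the loading of both pair members on a common
#' phonological projection; the default plants sharing only for L1-L3 (the
#' two transparent scripts). The ground-truth ordering of pair similarities
#' is derivable from these weights via [ground_truth()].
#'
#' @param w_phon item-varying phonological channel weight (>= 0); drives
#'   the item-level neural RDM structure.
#' @param w_phon_base language-level phonological base-pattern weight; a
#'   run- and item-stable topography per language whose sharing across a
#'   pair follows `shared_phon_strength`, driving the condition-level
#'   cross-language similarity contrast.
#' @param w_vis,w_sem visual / semantic channel weights (>= 0).
#' @param shared_phon_strength named vector over `"L1-L3"`, `"L1-L2"`,
#'   `"L2-L3"` in `[0, 1]`.
#' @param roi_gain_phon per-ROI multiplier on the phonological channel
#'   (length `n_rois` or 1; all ROIs are phonological-network boxes).
#' @param noise_sd per-voxel noise standard deviation of an item map.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(w_phon = 0.3, w_phon_base = 0.4,
                        w_vis = 0.3, w_sem = 0.3,
                        shared_phon_strength = c("L1-L3" = 0.8,
                                                 "L1-L2" = 0,
                                                 "L2-L3" = 0),
                        roi_gain_phon = 1,
                        noise_sd = 1) {
  if (any(c(w_phon, w_phon_base, w_vis, w_sem) < 0)) {
    stopf("channel weights must be >= 0")
  }
  if (any(shared_phon_strength < 0 | shared_phon_strength > 1)) {
    stopf("shared_phon_strength values must lie in [0, 1]")
  }
  structure(list(w_phon = w_phon, w_phon_base = w_phon_base,
                 w_vis = w_vis, w_sem = w_sem,
                 shared_phon_strength = shared_phon_strength,
                 roi_gain_phon = roi_gain_phon,
                 noise_sd = noise_sd),
            class = "effect_spec")
}

#' Null effect specification (no planted signal)
#' @return an [effect_spec()] with all channel weights zero.
#' @export
null_effect_spec <- function() {
  effect_spec(w_phon = 0, w_phon_base = 0, w_vis = 0, w_sem = 0,
              shared_phon_strength = c("L1-L3" = 0, "L1-L2" = 0, "L2-L3" = 0))
}

# per-language loading on the common phonological projection; exact when a
# single pair shares (cross-pair covariance ~ sqrt(alpha_i * alpha_j))
.lang_alpha <- function(design, effects) {
  langs <- design$languages
  alpha <- stats::setNames(rep(0, 3), langs)
  s <- effects$shared_phon_strength
  for (nm in names(s)) {
    pr <- strsplit(nm, "-")[[1L]]
    i <- match(pr, c("L1", "L2", "L3"))
    alpha[langs[i]] <- pmax(alpha[langs[i]], s[[nm]])
  }
  alpha
}

# phoneme inventories: L1 and L3 share the alphabetic inventory; L2 has
# its own syllable inventory plus tone tokens. A few onset consonants are
# common to all three languages (as for real phone inventories), so the
# L1-L2 phonological prediction matrix varies without any planted neural
# sharing for that pair.
.alpha_consonants <- c("p", "t", "k", "b", "d", "g", "m", "n",
                       "s", "z", "l", "r", "f", "v", "ʃ", "tʃ")
.alpha_vowels <- c("a", "e", "i", "o", "u", "ɛ", "ɑ", "ø")
.tonal_onsets <- c("t", "k", "m", "ʈʂ", "tɕ", "ɕ", "x", "h", "w", "ts")
.tonal_rimes <- c("ɤ", "ɨ", "ʉ", "ai", "ei", "au", "ou", "ɔŋ", "əŋ", "an")
.tones <- c("T1", "T2", "T3", "T4")

#' Generate a synthetic trilingual lexicon
#'
#' Produces `items_per_language` items per language. L1 and L3 carry
#' phoneme sequences of 3-6 segments drawn from a shared consonant/vowel
#' inventory and letter-string orthographies of 3-6 symbols; L2 is tonal
#' and holistic: 3-digit glyph ids with no letter-phoneme mapping,
#' onset-rime syllables from its own inventory (a few onset consonants are
#' shared with the alphabetic inventory) plus a tone token. Orthographies
#' are drawn independently of the phoneme sequences, so the visual,
#' phonological and semantic prediction matrices of the synthetic lexicon
#' are mutually near-orthogonal and channel recovery is identifiable (real
#' transparent scripts couple spelling and sound; see the package
#' vignette). Categories are balanced over the 12 default labels; no two
#' items share a phoneme sequence or an orthography.
#'
#' @param design a [synthetic_design()].
#' @param seed RNG seed (defaults to the design seed).
#' @return a [stimulus_table()] with `run` and `language` columns.
#' @export
generate_lexicon <- function(design, seed = design$seed) {
  n <- design$items_per_language
  langs <- design$languages
  cats <- default_categories()
  # disjoint letter ranges keep the two alphabetic scripts visually distinct
  alphabets <- list(L1 = letters[1:13], L3 = letters[14:26])
  if (any(lengths(alphabets) < 8L)) stopf("alphabet too small for inventory")
  with_seed(seed, {
    make_alpha_word <- function() {
      len <- sample(3:6, 1L)
      # alternate C/V starting from a consonant
      tok <- character(len)
      for (k in seq_len(len)) {
        tok[k] <- if (k %% 2L == 1L) sample(.alpha_consonants, 1L)
                  else sample(.alpha_vowels, 1L)
      }
      tok
    }
    make_orthography <- function(alphabet) {
      paste(sample(alphabet, sample(3:6, 1L), replace = TRUE), collapse = "")
    }
    gen_unique <- function(maker, n, taken = character(0)) {
      out <- list()
      keys <- taken
      guard <- 0L
      while (length(out) < n) {
        guard <- guard + 1L
        if (guard > 50000L) stopf("inventory too small for requested uniqueness")
        w <- maker()
        key <- paste(w, collapse = " ")
        if (!key %in% keys) {
          keys <- c(keys, key)
          out[[length(out) + 1L]] <- w
        }
      }
      out
    }
    w1 <- gen_unique(make_alpha_word, n)
    w3 <- gen_unique(make_alpha_word, n, taken = sapply(w1, paste, collapse = " "))
    make_tonal_word <- function() {
      c(sample(.tonal_onsets, 1L), sample(.tonal_rimes, 1L))
    }
    w2 <- gen_unique(make_tonal_word, n)
    tones2 <- sample(.tones, n, replace = TRUE)
    orth1 <- unlist(gen_unique(function() make_orthography(alphabets$L1), n))
    orth3 <- unlist(gen_unique(function() make_orthography(alphabets$L3), n))
    rows <- list()
    run_of <- rep(seq_len(design$runs),
                  each = design$trials_per_language_per_run)
    cat_of <- rep_len(cats, n)
    for (li in seq_along(langs)) {
      lang <- langs[li]
      for (i in seq_len(n)) {
        word <- switch(li, w1[[i]], w2[[i]], w3[[i]])
        orth <- switch(li,
                       orth1[i],
                       sprintf("%03d", i),   # holistic glyph id
                       orth3[i])
        rows[[length(rows) + 1L]] <- data.frame(
          item_id = sprintf("%s_%03d", lang, i),
          language = lang,
          orthography = orth,
          phonemes = paste(word, collapse = " "),
          tone = if (li == 2L) tones2[i] else NA_character_,
          category = cat_of[i],
          run = run_of[i],
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    stimulus_table(tab)
  })
}

# ---- feature channels -----------------------------------------------------

# position-coded phoneme bag: vocabulary x position one-hots, tone in a
# dedicated final slot
lexicon_phon_features <- function(items, max_pos = 6L) {
  phon <- phoneme_list(items)
  # radix sort is locale-independent, keeping feature positions (and hence
  # every simulated voxel) identical across collation environments
  vocab <- sort(unique(c(unlist(phon), .tones)), method = "radix")
  d <- length(vocab) * max_pos + length(.tones)
  F <- matrix(0, nrow = d, ncol = nrow(items))
  for (i in seq_len(nrow(items))) {
    toks <- phon[[i]]
    for (k in seq_len(min(length(toks), max_pos))) {
      F[(k - 1L) * length(vocab) + match(toks[k], vocab), i] <- 1
    }
    if (!is.na(items$tone[i])) {
      F[length(vocab) * max_pos + match(items$tone[i], .tones), i] <- 1
    }
  }
  F
}

# block-averaged silhouette pixels (16 x 12 grid of the 226 x 151 canvas)
lexicon_visual_features <- function(items, nx = 16L, ny = 12L,
                                    config = silhouette_config()) {
  F <- matrix(0, nrow = nx * ny, ncol = nrow(items))
  xb <- floor(seq(0L, config$width, length.out = nx + 1L))
  yb <- floor(seq(0L, config$height, length.out = ny + 1L))
  for (i in seq_len(nrow(items))) {
    px <- render_silhouette(items$orthography[i], config)$pixels
    blk <- matrix(0, ny, nx)
    for (a in seq_len(ny)) for (b in seq_len(nx)) {
      blk[a, b] <- mean(px[(yb[a] + 1L):yb[a + 1L], (xb[b] + 1L):xb[b + 1L]])
    }
    F[, i] <- as.vector(blk)
  }
  F
}

lexicon_semantic_features <- function(items, categories = default_categories()) {
  F <- matrix(0, nrow = length(categories), ncol = nrow(items))
  F[cbind(match(items$category, categories), seq_len(nrow(items)))] <- 1
  F
}

#' Precompute the generator's feature channels for a lexicon
#'
#' Rendering silhouettes dominates generation cost, so features are built
#' once per lexicon and passed to [simulate_subject()].
#'
#' @param lexicon a [generate_lexicon()] table.
#' @return list with matrices `phon`, `vis`, `sem` (features x items); each
#'   item's feature column is unit-normalized so the channel weights of
#'   [effect_spec()] directly set the per-voxel signal standard deviation.
#' @export
lexicon_features <- function(lexicon) {
  unitize <- function(F) {
    nrm <- sqrt(colSums(F^2))
    nrm[nrm == 0] <- 1
    sweep(F, 2L, nrm, "/")
  }
  list(phon = unitize(lexicon_phon_features(lexicon)),
       vis = unitize(lexicon_visual_features(lexicon)),
       sem = unitize(lexicon_semantic_features(lexicon)))
}

# 10 disjoint 5x5x5 boxes on the grid
synthetic_roi_set <- function(design) {
  dims <- design$dims
  if (any(dims < 19L)) stopf("grid too small for the requested ROIs (need >= 19)")
  origins <- rbind(expand.grid(x = c(3L, 15L), y = c(3L, 15L), z = c(3L, 15L)),
                   data.frame(x = 9L, y = 9L, z = 3L),
                   data.frame(x = 9L, y = 9L, z = 15L))
  if (design$n_rois > nrow(origins)) stopf("at most %d ROIs supported",
                                           nrow(origins))
  labels <- array(0L, dim = dims)
  for (r in seq_len(design$n_rois)) {
    o <- origins[r, ]
    labels[o$x:(o$x + 4L), o$y:(o$y + 4L), o$z:(o$z + 4L)] <- r
  }
  nm <- default_roi_names()[seq_len(design$n_rois)]
  roi_set(labels, dims, names = nm)
}

#' Simulate one subject's statistic volumes
#'
#' Builds condition-level and item-level T-map proxies on the design grid.
#' Each item's voxel pattern inside an ROI is the weighted sum of its three
#' feature channels pushed through subject-specific Gaussian random
#' projections, plus independent Gaussian noise everywhere; voxels outside
#' the ROIs carry noise only. The phonological projection is split into a
#' common part (loading `sqrt(alpha_lang)`, shared across languages) and a
#' language-private part, planting cross-language structure only where
#' `shared_phon_strength` says so. Each item appears in exactly one run;
#' condition maps are the within-run averages of the language's item maps.
#'
#' @param design a [synthetic_design()].
#' @param effects an [effect_spec()].
#' @param lexicon a [generate_lexicon()] table.
#' @param subject_seed integer seed for this subject.
#' @param subject_id subject identifier.
#' @param features optional precomputed [lexicon_features()].
#' @return list with `cond` (condition-level [pattern_volume()]), `items`
#'   (item-level volume) and `rois` (the [roi_set()]).
#' @export
simulate_subject <- function(design, effects, lexicon, subject_seed,
                             subject_id = "s01", features = NULL) {
  features <- features %||% lexicon_features(lexicon)
  rois <- synthetic_roi_set(design)
  dims <- design$dims
  nvox <- prod(dims)
  langs <- design$languages
  alpha <- .lang_alpha(design, effects)
  gains <- rep_len(effects$roi_gain_phon, design$n_rois)
  n_items <- nrow(lexicon)
  with_seed(subject_seed, {
    # noise for every item map over the whole grid
    data <- matrix(rnorm(nvox * n_items, sd = effects$noise_sd),
                   nrow = nvox, ncol = n_items)
    roi_idx <- lapply(seq_len(design$n_rois),
                      function(r) roi_voxels(rois, r))
    d_phon <- nrow(features$phon)
    d_vis <- nrow(features$vis)
    d_sem <- nrow(features$sem)
    for (r in seq_len(design$n_rois)) {
      vox <- roi_idx[[r]]
      nv <- length(vox)
      # unit-variance projections + unit-norm features => per-voxel signal
      # sd of a channel equals its weight
      proj <- function(d) matrix(rnorm(nv * d), nv, d)
      Wc <- proj(d_phon)
      base_common <- rnorm(nv)
      # the three languages' semantic subspaces are drawn exactly
      # orthogonal (QR of one Gaussian block), so the cross-language
      # semantic null holds by construction, not just in expectation —
      # with one shared random 12x12 cross-projection per subject the
      # realized category-block structure leaks into every cell of the
      # 80x80 RDM and the semantic model test becomes anticonservative
      if (nv >= 3L * d_sem) {
        Wsem_all <- qr.Q(qr(matrix(rnorm(nv * 3L * d_sem), nv))) * sqrt(nv)
      } else {
        Wsem_all <- matrix(rnorm(nv * 3L * d_sem), nv)
      }
      for (lang in langs) {
        sel <- which(lexicon$language == lang)
        a <- alpha[[lang]]
        # private draws happen for every language so the RNG stream does
        # not depend on the alpha values
        Wp <- proj(d_phon)
        base_priv <- rnorm(nv)
        Wl <- sqrt(a) * Wc + sqrt(1 - a) * Wp
        base <- sqrt(a) * base_common + sqrt(1 - a) * base_priv
        li <- match(lang, langs)
        Wsem <- Wsem_all[, ((li - 1L) * d_sem + 1L):(li * d_sem), drop = FALSE]
        sig <- effects$w_phon * gains[r] * (Wl %*% features$phon[, sel])
        sig <- sig + effects$w_phon_base * gains[r] * base
        sig <- sig + effects$w_vis * (proj(d_vis) %*% features$vis[, sel])
        sig <- sig + effects$w_sem * (Wsem %*% features$sem[, sel])
        data[vox, sel] <- data[vox, sel] + sig
      }
    }
    item_index <- data.frame(run = lexicon$run, unit = lexicon$item_id)
    languages <- stats::setNames(lexicon$language, lexicon$item_id)
    items_vol <- pattern_volume(data, item_index, dims,
                                subject_id = subject_id, level = "item",
                                languages = languages)
    # condition maps: within-run averages of the language's item maps
    cond_cols <- list()
    cond_index <- list()
    for (run in seq_len(design$runs)) {
      for (lang in langs) {
        sel <- which(lexicon$language == lang & lexicon$run == run)
        cond_cols[[length(cond_cols) + 1L]] <- rowMeans(data[, sel, drop = FALSE])
        cond_index[[length(cond_index) + 1L]] <- data.frame(run = run, unit = lang)
      }
    }
    cond_vol <- pattern_volume(do.call(cbind, cond_cols),
                               do.call(rbind, cond_index), dims,
                               subject_id = subject_id, level = "condition")
    list(cond = cond_vol, items = items_vol, rois = rois)
  })
}

#' Ground truth implied by a design and effect specification
#'
#' Machine-readable statement of which language pair should show the larger
#' similarity in the (phonological) ROIs and which model RDM should
#' correlate with the neural RDM of each pair.
#'
#' @param design a [synthetic_design()].
#' @param effects an [effect_spec()].
#' @return list with `pair_strength` (planted cross-pair phonological
#'   covariance weight per pair), `expected_winner` (pair with the largest
#'   strength, or `NA` if tied at zero), `expected_order`, and
#'   `channel_map` (data frame pair x model -> expected correlation).
#' @export
ground_truth <- function(design, effects) {
  alpha <- .lang_alpha(design, effects)
  langs <- design$languages
  pair_names <- c("L1-L2", "L1-L3", "L2-L3")
  idx <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  shared <- vapply(idx, function(ii) {
    sqrt(alpha[[langs[ii[1L]]]] * alpha[[langs[ii[2L]]]])
  }, numeric(1))
  strength <- (effects$w_phon^2 + effects$w_phon_base^2) * shared
  names(strength) <- names(shared) <- pair_names
  winner <- if (max(strength) > 0 &&
                sum(strength == max(strength)) == 1L) {
    pair_names[which.max(strength)]
  } else NA_character_
  channel <- expand.grid(pair = pair_names,
                         model = c("visual", "phonological", "semantic"),
                         stringsAsFactors = FALSE)
  # item-level RDM structure needs the item-varying phonological weight
  channel$expected <- channel$model == "phonological" &
    effects$w_phon^2 * shared[channel$pair] > 0
  list(pair_strength = strength,
       expected_winner = winner,
       expected_order = pair_names[order(strength, decreasing = TRUE)],
       channel_map = channel)
}
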