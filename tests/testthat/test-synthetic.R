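small_design <- function(seed = 1) {
  synthetic_design(n_subjects = 4L, items_per_language = 12L,
                   trials_per_language_per_run = 6L,
                   dims = c(20L, 20L, 20L), n_rois = 2L, seed = seed)
}

test_that("lexicon generation matches the design counts and is deterministic", {
  d <- synthetic_design(seed = 5)
  lex <- generate_lexicon(d, seed = 5)
  expect_equal(nrow(lex), 240)
  expect_equal(as.vector(table(lex$language)), rep(80L, 3))
  # near-balanced categories: counts differ by at most 1 within a language
  for (l in unique(lex$language)) {
    counts <- table(lex$category[lex$language == l])
    expect_length(counts, 12)
    expect_lte(diff(range(counts)), 1)
  }
  # half the items of each language in each run
  expect_equal(as.vector(table(lex$run, lex$language)), rep(40L, 6))
  expect_identical(generate_lexicon(d, seed = 5), lex)
  expect_false(identical(generate_lexicon(d, seed = 6)$phonemes, lex$phonemes))
  # the opaque language is tonal and holistic; the transparent ones are not
  expect_true(all(!is.na(lex$tone[lex$language == "L2"])))
  expect_true(all(is.na(lex$tone[lex$language != "L2"])))
  expect_true(all(grepl("^[0-9]+$", lex$orthography[lex$language == "L2"])))
  expect_true(all(grepl("^[a-z]+$", lex$orthography[lex$language != "L2"])))
  # no duplicated pronunciations anywhere
  expect_false(anyDuplicated(lex$phonemes[lex$language == "L1"]) > 0)
})

test_that("subject simulation is a pure function of its seeds", {
  d <- small_design()
  e <- effect_spec()
  lex <- generate_lexicon(d, 1)
  f <- lexicon_features(lex)
  s1 <- simulate_subject(d, e, lex, subject_seed = 99, features = f)
  s2 <- simulate_subject(d, e, lex, subject_seed = 99, features = f)
  expect_identical(s1$items$data, s2$items$data)
  expect_identical(s1$cond$data, s2$cond$data)
  s3 <- simulate_subject(d, e, lex, subject_seed = 100, features = f)
  expect_false(identical(s1$items$data, s3$items$data))
  # condition maps are the within-run averages of the item maps
  sel <- which(lex$language == "L1" & lex$run == 1)
  expect_equal(s1$cond$data[, "1:L1"],
               rowMeans(s1$items$data[, sel]), tolerance = 1e-12)
})

test_that("planted phonological sharing orders the pair similarities", {
  d <- small_design(seed = 3)
  # strong signal, tiny noise: ordering must hold in every phonological ROI
  e <- effect_spec(noise_sd = 0.05)
  lex <- generate_lexicon(d, 3)
  f <- lexicon_features(lex)
  sim <- simulate_subject(d, e, lex, subject_seed = 7, features = f)
  tab <- roi_similarity_table(sim$cond, sim$rois,
                              list(c("L1", "L2"), c("L1", "L3")))
  for (r in unique(tab$roi)) {
    expect_gt(tab$z[tab$roi == r & tab$pair == "L1-L3"],
              tab$z[tab$roi == r & tab$pair == "L1-L2"])
  }
})

test_that("null effects produce similarities centered on zero", {
  d <- synthetic_design(n_subjects = 1L, items_per_language = 8L,
                        trials_per_language_per_run = 4L,
                        dims = c(20L, 20L, 20L), n_rois = 2L)
  e <- null_effect_spec()
  lex <- generate_lexicon(d, 2)
  f <- lexicon_features(lex)
  zs <- sapply(1:60, function(i) {
    sim <- simulate_subject(d, e, lex, subject_seed = 1000 + i, features = f)
    tab <- roi_similarity_table(sim$cond, sim$rois,
                                list(c("L1", "L3")))
    mean(tab$z)
  })
  se <- sd(zs) / sqrt(length(zs))
  expect_lt(abs(mean(zs)), 4 * se + 0.01)
})

test_that("ground truth restates the planted weights", {
  d <- small_design()
  gt <- ground_truth(d, effect_spec())
  expect_equal(gt$expected_winner, "L1-L3")
  expect_equal(gt$expected_order[1], "L1-L3")
  expect_true(all(gt$pair_strength[c("L1-L2", "L2-L3")] == 0))
  ch <- gt$channel_map
  expect_true(ch$expected[ch$pair == "L1-L3" & ch$model == "phonological"])
  expect_false(any(ch$expected[ch$model != "phonological"]))
  # null spec predicts nothing
  gt0 <- ground_truth(d, null_effect_spec())
  expect_true(is.na(gt0$expected_winner))
  expect_false(any(gt0$channel_map$expected))
  # visual-only effect flags no phonological prediction
  gtv <- ground_truth(d, effect_spec(w_phon = 0, w_vis = 0.5, w_sem = 0,
                                     shared_phon_strength = c("L1-L3" = 0,
                                                              "L1-L2" = 0,
                                                              "L2-L3" = 0)))
  expect_false(any(gtv$channel_map$expected))
})

test_that("design and effect validation reject impossible settings", {
  expect_error(synthetic_design(items_per_language = 80,
                                trials_per_language_per_run = 30),
               "must equal")
  expect_error(effect_spec(w_phon = -1), ">= 0")
  expect_error(simulate_subject(synthetic_design(dims = c(10L, 10L, 10L)),
                                effect_spec(),
                                generate_lexicon(small_design(), 1), 1),
               "too small")
})
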