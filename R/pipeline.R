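# End-to-end assembly: simulate a study, run the ROI / item-level RSA,
# correlate neural RDMs with the model RDMs, and write report tables.

#' Run the full pipeline on one synthetic study
#'
#' Generates a lexicon, simulates every subject, computes the ROI-level
#' cross-language similarity table (condition-level RSA) and, for the
#' requested ROIs, the subject-averaged item-level neural RDM of each
#' language pair (Fisher-z mean across subjects).
#'
#' @param design a [synthetic_design()].
#' @param effects an [effect_spec()].
#' @param seed master seed for the study (lexicon + subjects).
#' @param pairs language pairs to analyse (default `L1-L2` and `L1-L3`).
#' @param rdm_rois ROI labels for which item-level RDMs are accumulated
#'   (default the first ROI; `integer(0)` to skip item-level analysis).
#' @return list with `lexicon`, `scores` (all subjects' ROI similarity
#'   records), `rdms` (nested: `rdms[[roi]][[pair]]`, group `neural_rdm`),
#'   `rois`, `truth`, `design`, `effects`, `seed`.
#' @export
run_study <- function(design, effects, seed = design$seed,
                      pairs = list(c("L1", "L2"), c("L1", "L3")),
                      rdm_rois = 1L) {
  lexicon <- generate_lexicon(design, seed)
  features <- lexicon_features(lexicon)
  seeds <- derive_seeds(seed, design$n_subjects)
  scores <- list()
  sums <- list()
  rois <- NULL
  pair_name <- function(p) paste(p, collapse = "-")
  for (s in seq_len(design$n_subjects)) {
    sid <- sprintf("s%02d", s)
    sim <- simulate_subject(design, effects, lexicon, seeds[s],
                            subject_id = sid, features = features)
    rois <- sim$rois
    scores[[s]] <- roi_similarity_table(sim$cond, sim$rois, pairs)
    for (r in rdm_rois) {
      for (p in pairs) {
        rdm <- item_level_rdm(sim$items, list(rois = sim$rois, label = r),
                              p, roi = as.character(r))
        key <- paste(r, pair_name(p), sep = "|")
        if (is.null(sums[[key]])) {
          sums[[key]] <- rdm
        } else {
          sums[[key]]$values <- sums[[key]]$values + rdm$values
        }
      }
    }
  }
  rdms <- list()
  for (r in rdm_rois) {
    rr <- as.character(r)
    rdms[[rr]] <- list()
    for (p in pairs) {
      key <- paste(r, pair_name(p), sep = "|")
      g <- sums[[key]]
      g$values <- g$values / design$n_subjects
      g$subject_id <- "group"
      rdms[[rr]][[pair_name(p)]] <- g
    }
  }
  list(lexicon = lexicon, scores = do.call(rbind, scores), rdms = rdms,
       rois = rois, truth = ground_truth(design, effects),
       design = design, effects = effects, seed = seed)
}

#' Model prediction RDMs for one language pair
#'
#' Builds the visual, phonological and semantic prediction matrices whose
#' rows are the items of `pair[1]` and columns the items of `pair[2]`.
#'
#' @param lexicon a stimulus table with a `language` column.
#' @param pair language pair.
#' @param config an [rsa_config()] (tone mode, visual normalizer).
#' @return named list of three `prediction_rdm`s.
#' @export
model_rdms <- function(lexicon, pair, config = rsa_config()) {
  rows <- lexicon[lexicon$language == pair[1L], , drop = FALSE]
  cols <- lexicon[lexicon$language == pair[2L], , drop = FALSE]
  list(
    visual = build_prediction_rdm(rows, cols, "visual",
                                  normalizer = config$visual_normalizer),
    phonological = build_prediction_rdm(rows, cols, "phonological",
                                        tone_mode = config$tone_mode),
    semantic = build_prediction_rdm(rows, cols, "semantic"))
}

#' ROI contrast table with Bonferroni flags
#'
#' One row per ROI: the repeated-measures contrast of the two language
#' pairs ([rm_anova_pair()], or [ancova_pair()] when a covariate is given)
#' and its Bonferroni significance across the ROI family.
#'
#' @param scores subject-level similarity table from
#'   [roi_similarity_table()] / [run_study()].
#' @param pair_order direction of the contrast, e.g. `c("L1-L3", "L1-L2")`.
#' @param covariate optional per-subject covariate (see [ancova_pair()]).
#' @param alpha family-wise level for the Bonferroni threshold.
#' @return data frame: `roi`, `roi_name`, `mean_diff`, `F`, `df1`, `df2`,
#'   `p`, `significant`, `bonferroni_threshold`.
#' @export
roi_contrast_table <- function(scores, pair_order, covariate = NULL,
                               alpha = 0.05) {
  rois <- unique(scores$roi)
  rows <- lapply(rois, function(r) {
    res <- if (is.null(covariate)) {
      rm_anova_pair(scores, r, pair_order)
    } else {
      ancova_pair(scores, r, covariate, pair_order)
    }
    data.frame(roi = r,
               roi_name = scores$roi_name[scores$roi == r][1L],
               mean_diff = res$mean_diff %||% NA_real_,
               F = res$F, df1 = res$df[1L], df2 = res$df[2L], p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bf <- bonferroni_flags(out$p, alpha)
  out$significant <- bf$significant
  out$bonferroni_threshold <- bf$threshold
  out
}

#' Model-RDM correlation table
#'
#' For every (ROI, pair): Spearman rho of the group neural RDM with each of
#' the three model RDMs with permutation p values, plus the partial
#' correlation of the phonological model controlling for the visual and
#' semantic models — the layout of the study's model-comparison table.
#'
#' @param rdms nested group RDM list from [run_study()]
#'   (`rdms[[roi]][[pair]]`).
#' @param lexicon the stimulus table the RDMs were computed from.
#' @param config an [rsa_config()]; `n_perm`, `perm_seed`,
#'   `sign_convention` and `perm_convention` are honoured.
#' @return data frame: `roi`, `pair`, `model`, `rho`, `p_perm`.
#' @export
rdm_model_table <- function(rdms, lexicon, config = rsa_config()) {
  out <- list()
  for (rr in names(rdms)) {
    for (pn in names(rdms[[rr]])) {
      pair <- strsplit(pn, "-")[[1L]]
      neural <- rdms[[rr]][[pn]]
      models <- model_rdms(lexicon, pair, config)
      for (mn in names(models)) {
        pt <- permutation_test_rdm(neural, models[[mn]],
                                   n_perm = config$n_perm,
                                   seed = config$perm_seed,
                                   sign_convention = config$sign_convention,
                                   convention = config$perm_convention)
        out[[length(out) + 1L]] <- data.frame(
          roi = rr, pair = pn, model = mn,
          rho = spearman_rdm(neural, models[[mn]],
                             config$sign_convention),
          p_perm = pt$p, stringsAsFactors = FALSE)
      }
      ctrl <- models[c("visual", "semantic")]
      out[[length(out) + 1L]] <- data.frame(
        roi = rr, pair = pn, model = "phonological_adjusted",
        rho = partial_spearman_rdm(neural, models$phonological, ctrl,
                                   config$sign_convention),
        p_perm = NA_real_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Assemble and write the report tables
#'
#' Writes the model-correlation table (`model_correlations.csv`), the ROI
#' contrast table (`roi_contrasts.csv`) and a plain-text run log carrying
#' the configuration hash and seeds.
#'
#' @param study result of [run_study()].
#' @param dir output directory (created if missing).
#' @param config an [rsa_config()].
#' @param pair_order contrast direction for the ROI table.
#' @return named list of file paths, invisibly.
#' @export
assemble_report <- function(study, dir, config = rsa_config(),
                            pair_order = c("L1-L3", "L1-L2")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contrasts <- roi_contrast_table(study$scores, pair_order,
                                  alpha = config$alpha)
  tab1 <- rdm_model_table(study$rdms, study$lexicon, config)
  stamp <- function(df) {
    df$config_hash <- config_hash(config)
    df$seed <- study$seed
    df
  }
  paths <- list(
    model_correlations = file.path(dir, "model_correlations.csv"),
    roi_contrasts = file.path(dir, "roi_contrasts.csv"),
    run_log = file.path(dir, "run_log.txt"))
  write.csv(stamp(tab1), paths$model_correlations, row.names = FALSE)
  write.csv(stamp(contrasts), paths$roi_contrasts, row.names = FALSE)
  write_run_log(config, paths$run_log,
                extra = list(study_seed = study$seed,
                             n_subjects = study$design$n_subjects))
  invisible(paths)
}
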