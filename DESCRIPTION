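Package: xlangrsa
Title: Cross-Language Representational Similarity Analysis for Word Reading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Representational similarity analysis (RSA) of multivoxel fMRI
    patterns evoked by written words in a native and two non-native languages.
    Builds stimulus-side prediction matrices (visual silhouette overlap,
    vowel-centric phoneme position matching, semantic category identity) and a
    grapheme-phoneme pronunciation-regularity score; computes searchlight,
    ROI-level and item-level cross-language pattern similarities with Fisher-z
    transformed Pearson correlations; provides group inference (two-level
    repeated-measures contrasts with covariate adjustment, Bonferroni control,
    Spearman and partial-Spearman model-RDM correlations with permutation
    tests, voxelwise group maps, and t-test power helpers); and includes a
    synthetic multivoxel pattern generator that plants visual, phonological
    and semantic representational structure so the full pipeline can be
    validated by parameter recovery without access to subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
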