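---
title: "Cross-language RSA: models, conventions and the synthetic validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-language RSA: models, conventions and the synthetic validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlangrsa)
```

## The question the pipeline answers

A trilingual reader whose native script is orthographically transparent
(regular grapheme-phoneme correspondence) reads words in two non-native
languages: one transparent, one opaque and tonal. If transparency distance
governs how much of the native phonological-access machinery is reused, the
multivoxel activation patterns of the native language should resemble the
transparent non-native language more than the opaque one, specifically in
the phonological reading network (bilateral pars opercularis, precentral
gyrus, angular gyrus, posterior superior temporal gyrus, supramarginal
gyrus). `xlangrsa` implements the full representational similarity analysis
(RSA) that tests this: stimulus-side prediction matrices, searchlight and
ROI pattern similarity, item-level neural representational dissimilarity
matrices (RDMs), and group inference — plus a synthetic data generator so
every stage can be validated by parameter recovery.

## Stimulus-side models

**Visual.** Every word is rendered as a binary silhouette on a fixed
226 × 151-pixel canvas with a packaged 5 × 7 dot-matrix font (integer
magnification, centred), so silhouettes are bit-reproducible across
machines. Pairwise dissimilarity is the pixel non-overlap of the two ink
regions. The normalizer is a genuine design choice; we use the Jaccard
distance |A Δ B| / |A ∪ B|, which is bounded in [0, 1] with identity → 0
and disjoint ink → 1, and offer |A Δ B| / canvas area as a config switch.

**Phonological.** Dissimilarity is 1 minus the proportion of same-position
phonemes under a vowel-centric alignment: both sequences anchor at their
first vowel nucleus, onset consonants are compared outward from the anchor
(right-aligned), the rime forward (left-aligned), and unmatched positions
count as mismatches. The denominator is the longer aligned length — this
rule is forced by the worked examples the measure must reproduce: /t ɑ m/
vs /t iː m/ share 2 of 3 units (1/3 dissimilar), and /t ɑ m/ vs /t i ŋ/
plus a tone token share 1 of 4 units with tone included (3/4) and 1 of 3
with tone excluded (2/3). Lexical tone is one appended rime-final
comparison unit, counted only when `tone_mode = "include"`; two toneless
items reduce to the exclude case. For CVC syllables the alignment
coincides with plain positional matching; for complex onsets it anchors
comparisons at the nucleus, which we consider the defensible reading of a
"vowel-centric, left-to-right" scheme; deviations matter only for clusters
and are documented here rather than hidden.

**Semantic.** Binary: 0 for same semantic category, 1 otherwise, over a
configured 12-category noun set.

**Pronunciation regularity.** For a grapheme with observed pronunciation
*p*, regularity is P(grapheme → *p*) / P(grapheme → modal pronunciation),
1 when the observed pronunciation is the modal one; a word's regularity is
the unweighted mean over its graphemes. Segmentation into graphemes is
greedy longest-match left-to-right over the probability table's inventory
(the concatenation of the output always equals the input); ties for the
modal pronunciation break deterministically by table order.

## Pattern similarity

Patterns are Pearson-correlated and Fisher-z transformed
(z = atanh r, r clamped to ±(1 − 10⁻⁷) so degenerate identical patterns
stay finite). Averaging always happens on the z scale, never on r.

* **Cross-language similarity**: per run, correlate the two language
  condition maps over a voxel set; average z across the two runs.
* **Within/between validity check**: within-language z correlates a
  language's run-1 map with its run-2 map; between-language z averages
  both run-crossed orderings (A₁·B₂ and A₂·B₁) — whether both orderings
  should enter is unstated in the original design, so we average both and
  record the choice.
* **Searchlight**: a cubic neighborhood of half-width 2 (125 voxels)
  around every in-mask voxel, truncated at the volume edge. A voxel is
  computed only when ≥ 50% of its cube is in-mask (configurable);
  zero-variance voxels are removed pairwise, and fewer than 3 usable
  voxels flags the value as missing. Voxel order is fixed (x fastest,
  then y, then z; 0-based indices in all logs and CSVs).
* **Item-level RDM**: for a language pair and ROI, the 80 × 80 matrix of
  Fisher-z correlations between the ROI patterns of every item of one
  language and every item of the other. Each item appears in exactly one
  run (half the materials per run), so its map comes from its own run
  with no cross-run averaging.

**Sign convention.** The item-level matrix is stored as Fisher-z
*similarities* with an explicit `sign_convention` flag. For model
comparison the neural values are negated to act as dissimilarities, so a
positive Spearman rho means the model's dissimilarity structure is present
in the patterns. The published account this pipeline follows reports
positive correlations between a "dissimilarity" matrix described as
Pearson correlations and dissimilarity-coded models, so the intended sign
is ambiguous at the source; negation is the default and the flag makes the
choice explicit and reversible rather than silently guessed.

## Group inference

* **Pair contrast**: one-way repeated-measures ANOVA with two
  within-subject levels, computed as the squared paired t (the exact
  2-level identity), df = (1, n − 1). Covariate adjustment regresses the
  within-subject difference scores on the mean-centred covariate and
  tests the intercept — the simplest model consistent with "pair effect
  adjusted for a subject-level covariate"; a constant covariate falls
  back to the unadjusted test with a warning.
* **Multiplicity**: Bonferroni across the 10-ROI family
  (0.05 / 10 = 0.005).
* **Model-RDM correlation**: Spearman over all cells of the
  non-symmetric cross-language matrix (rows and columns index different
  item sets, so no triangle extraction), average ranks for ties. Partial
  correlation residualizes rank-transformed neural and target matrices on
  the rank-transformed controls.
* **Permutation test**: shuffles the item labels of the model matrix rows
  (row vs column vs both is unstated at the source; rows are the default)
  and recomputes rho; 5,000 permutations by default, one-sided (greater).
  p is the plain proportion of permuted statistics ≥ observed (k/n),
  which can return exactly 0; an add-one convention ((k+1)/(n+1)) is
  available by config.
* **Group maps**: voxelwise one-sample t across subjects on searchlight
  difference maps, converted to equivalent Gaussian Z on the log scale
  for numerical stability, thresholded at Z > 3.1. This is voxelwise
  thresholding only — cluster-level random-field correction is out of
  scope. Zero-variance voxels are capped (default |Z| ≤ 40) and counted.
* **Helpers**: inverse efficiency (mean RT / accuracy) and exact
  noncentral-t power for one-sample/paired designs (at d = 1.651 and
  n = 23 the two-sided power exceeds 0.999).

## The synthetic validation design

No subject data are distributed with this problem, so the generator is a
first-class module that emulates the study conditions: 23 subjects, 3
languages × 80 items, 2 runs × 40 items per language per run, a 24³ voxel
grid, and 10 disjoint 5×5×5 box ROIs named after the bilateral
phonological regions. Three feature channels mirror the three prediction
matrices so model recovery is well-posed:

* *phonological*: position-coded phoneme indicators (plus a tone slot),
* *visual*: block-averaged silhouette pixels (16 × 12),
* *semantic*: one-hot category.

Feature columns are unit-normalized and pushed through subject-specific
unit-variance Gaussian random projections, so each channel weight equals
the per-voxel signal SD it contributes. The three languages' *semantic*
projections are drawn exactly orthogonal within each subject × ROI (QR of
one Gaussian block): with merely independent projections, the one
realized 12 × 12 cross-language category Gram matrix per subject is
shared by all ~6,400 RDM cells, and that dependence makes the semantic
model's permutation test anticonservative even though sharing is zero in
expectation — orthogonality makes the semantic cross-language null exact.
Cross-language sharing is planted *only* in the phonological channel, in
two parts:

* an **item-varying** part (`w_phon`, default 0.3) whose projection is a
  mixture of a common and a language-private matrix with loadings
  √α per language (α = 0.8 for both members of the transparent pair, 0
  for the opaque language) — this produces the item-level RDM structure
  that the phonological model should recover;
* a **language base pattern** (`w_phon_base`, default 0.4), an item- and
  run-stable topography mixed with the same loadings — this produces the
  condition-level cross-language similarity advantage of the transparent
  pair, the analogue of two languages sharing mean activation topography
  because they engage the same phonological access pathway.

Item maps are signal + N(0, noise_sd²) per voxel (noise_sd = 1);
condition maps are the within-run averages of the language's 40 item
maps. The defaults were fixed once so that the planted ordering is
recoverable with 23 subjects without being ceiling-level: the group-mean
item-level phonological rho lands well below 1 while the ROI contrast
passes Bonferroni with a wide margin. With all weights zero the generator
is an exact null.

Two deliberate departures from realistic data, and what they imply:

* T-map proxies are signal-plus-noise draws, not GLM estimates from a
  simulated time series — the pipeline consumes statistic maps, so
  simulating hemodynamics would add nothing the tests could check. There
  is no spatial autocorrelation, anatomy, or motion structure, so passing
  recovery tests demonstrates the *analysis* is correct, not that the
  effect sizes transfer to real acquisitions.
* Transparent-language orthographies are random letter strings drawn
  independently of the phoneme sequences. Real transparent scripts couple
  spelling and sound, which correlates the visual and phonological
  prediction matrices (word length and recurring letter pairs); with a
  strong planted phonological code that coupling leaks into the visual
  model test. Decoupling keeps the three models mutually near-orthogonal
  so that channel recovery is identifiable — the generator validates the
  machinery, it does not claim that visual and phonological structure are
  separable to this degree in real lexicons.

## Numerical and degenerate-input choices

Correlations clamp at ±(1 − 10⁻⁷) before atanh; patterns with fewer than
3 finite voxels or zero variance propagate as flagged missing values;
constant model matrices are rank-degenerate and error; a control matrix
that absorbs the target's rank variance (residual sum of squares below
10⁻¹⁰ of total) errors by name; group-map t → Z conversion runs on the
log-probability scale; all RNG use is seeded and scoped (the caller's
RNG state is restored).

## Problem sizes used by the test suite

The validation suite exercises the full design where it matters and
smaller grids where only correctness is at stake: parameter recovery runs
20 studies at the full design (23 subjects, 240 items, 24³ grid, 1,000
permutations per test); searchlight/ROI equivalence is asserted exactly on
a 12³ volume; permutation calibration uses 500 null datasets of 16 × 16
RDMs with 1,000 permutations; the null group-map rate uses a 40³ grid.
These sizes are the package's own balance between statistical resolution
and a suite that runs in minutes.

## Known limitations

* The vowel-centric alignment is specified to reproduce the worked CVC
  examples; genuinely ambiguous cluster alignments (e.g. unequal complex
  onsets) follow the anchor rule stated above and may differ from other
  implementations of similar schemes.
* The permutation test shuffles model rows only; shuffling columns or
  both is a one-line change but alters the null when row and column item
  sets differ.
* The covariate adjustment is a difference-score regression, not a full
  mixed model; with a single two-level factor they test the same effect.
* Synthetic SNR defaults are calibrated to qualitative recovery (ordering
  and significance pattern), not to any reported effect magnitudes, which
  the source does not provide for these quantities.
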