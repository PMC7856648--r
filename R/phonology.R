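# Phoneme-sequence dissimilarity with vowel-centric alignment.
#
# Two pronunciations are compared position-wise after anchoring each sequence
# at its first vowel nucleus: onset consonants are matched outward from the
# vowel (right-to-left), the rime (vowel and coda) left-to-right. The
# dissimilarity is 1 minus the proportion of aligned positions carrying the
# same phoneme, with the longer aligned length as denominator, so e.g.
# /t ɑ m/ vs /t iː m/ share 2 of 3 units (dissimilarity 1/3), and
# /t ɑ m/ vs /t i ŋ/ + tone share 1 of 4 units when the tone token is
# counted (3/4) and 1 of 3 when it is not (2/3).

# Vowel nuclei are recognised by their first character.
.default_vowel_chars <- c(
  "a", "e", "i", "o", "u",
  "ɑ", "ɒ", "æ", "ɛ", "ə", "ɜ", "ɪ",
  "ɔ", "ʊ", "ʌ", "ø", "œ", "ü", "ö",
  "ɯ", "ɨ", "ʉ", "ɤ", "y"
)

is_vowel_token <- function(tokens, vowels = .default_vowel_chars) {
  substr(tokens, 1L, 1L) %in% vowels
}

# Split a phoneme sequence into onset (before first vowel) and rime (first
# vowel onward). A sequence with no vowel is treated as all-rime.
split_at_nucleus <- function(tokens, vowels) {
  v <- which(is_vowel_token(tokens, vowels))
  if (length(v) == 0L) {
    list(onset = character(0), rime = tokens)
  } else {
    k <- v[1L]
    list(onset = tokens[seq_len(k - 1L)], rime = tokens[k:length(tokens)])
  }
}

#' Phonological dissimilarity of two pronunciations
#'
#' Computes 1 minus the proportion of same-position phonemes shared by two
#' phoneme sequences under vowel-centric alignment (see Details). Lexical
#' tone, when present and `tone_mode = "include"`, is appended as one extra
#' comparison unit at the end of the rime; with `tone_mode = "exclude"` (or
#' when neither item carries tone) tones are ignored.
#'
#' @details Each sequence is anchored at its first vowel nucleus. Onset
#'   consonants are compared outward from the anchor (i.e. right-aligned),
#'   rime positions forward from the anchor (left-aligned); unmatched
#'   positions count as mismatches. The denominator is the longer aligned
#'   length, `max(onset lengths) + max(rime lengths)`. The measure is
#'   symmetric and lies in `[0, 1]`; identical sequences score 0.
#'
#' @param a,b character vectors of phoneme tokens (non-empty).
#' @param tone_a,tone_b optional tone tokens (e.g. `"T1"`), `NULL` or `NA`
#'   for non-tonal items.
#' @param tone_mode `"include"` or `"exclude"`.
#' @param vowels characters recognised as vowel-initial token markers.
#' @return dissimilarity in `[0, 1]`.
#' @export
phonological_dissimilarity <- function(a, b, tone_a = NULL, tone_b = NULL,
                                       tone_mode = c("include", "exclude"),
                                       vowels = .default_vowel_chars) {
  tone_mode <- match.arg(tone_mode)
  if (length(a) == 0L || length(b) == 0L) {
    stopf("phoneme sequences must be non-empty")
  }
  a <- as.character(a); b <- as.character(b)
  norm_tone <- function(t) {
    if (is.null(t) || length(t) == 0L || is.na(t) || !nzchar(t)) NULL else t
  }
  tone_a <- norm_tone(tone_a); tone_b <- norm_tone(tone_b)
  sa <- split_at_nucleus(a, vowels)
  sb <- split_at_nucleus(b, vowels)
  if (tone_mode == "include") {
    # a tone is one extra rime-final comparison unit; two toneless items
    # reduce to the exclude case
    if (!is.null(tone_a)) sa$rime <- c(sa$rime, tone_a)
    if (!is.null(tone_b)) sb$rime <- c(sb$rime, tone_b)
  }
  n_on <- max(length(sa$onset), length(sb$onset))
  n_ri <- max(length(sa$rime), length(sb$rime))
  shared <- 0L
  # onset: compare outward from the vowel, i.e. right-aligned
  k <- min(length(sa$onset), length(sb$onset))
  if (k > 0L) {
    oa <- rev(sa$onset)[seq_len(k)]
    ob <- rev(sb$onset)[seq_len(k)]
    shared <- shared + sum(oa == ob)
  }
  k <- min(length(sa$rime), length(sb$rime))
  if (k > 0L) {
    shared <- shared + sum(sa$rime[seq_len(k)] == sb$rime[seq_len(k)])
  }
  1 - shared / (n_on + n_ri)
}
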