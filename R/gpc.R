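# Grapheme-phoneme correspondence (GPC) tables and pronunciation
# regularity.
#
# The regularity of a grapheme's observed pronunciation is the probability
# of that pronunciation divided by the probability of the grapheme's most
# likely pronunciation (so a modal pronunciation scores 1); a word's
# regularity is the unweighted mean over its graphemes. Higher values mean
# higher spelling-sound consistency (theoretical range 0-1).

#' Assemble a grapheme-to-phoneme probability table
#'
#' @param df data frame with columns `grapheme`, `phoneme`, `probability`
#'   (fractions in `[0, 1]`). Probabilities for one grapheme must sum to at
#'   most 1 (plus a small tolerance). When two pronunciations of a grapheme
#'   tie for the maximum probability, the one listed first is taken as
#'   modal (deterministic tie-break by table order).
#' @param tol tolerance on the per-grapheme probability sum.
#' @return the validated data frame, classed `gpc_table`.
#' @export
gpc_table <- function(df, tol = 1e-6) {
  need <- c("grapheme", "phoneme", "probability")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("GPC table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  p <- df$probability
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1 + tol)) {
    stopf("GPC probabilities must be fractions in [0, 1]")
  }
  sums <- tapply(p, df$grapheme, sum)
  over <- names(sums)[sums > 1 + tol]
  if (length(over)) {
    stopf("probabilities for grapheme(s) %s sum to more than 1",
          paste(sQuote(over), collapse = ", "))
  }
  if (anyDuplicated(df[c("grapheme", "phoneme")])) {
    stopf("duplicate (grapheme, phoneme) rows in GPC table")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("gpc_table", "data.frame")
  df
}

#' Read a GPC probability table (TSV)
#'
#' @param path TSV file with columns `grapheme`, `phoneme`, `probability`.
#' @return a `gpc_table`.
#' @export
read_gpc_table <- function(path) {
  gpc_table(read.delim(path, stringsAsFactors = FALSE))
}

# rows of `table` for one grapheme, preserving table order
.gpc_rows <- function(table, grapheme) {
  rows <- table[table$grapheme == grapheme, , drop = FALSE]
  if (nrow(rows) == 0L) stopf("grapheme %s absent from GPC table",
                              sQuote(grapheme))
  rows
}

#' Pronunciation regularity of one grapheme
#'
#' `P(grapheme -> observed phoneme) / P(grapheme -> most likely phoneme)`;
#' equals 1 when the observed pronunciation is the modal one.
#'
#' @param grapheme grapheme string present in `table`.
#' @param observed_phoneme the pronunciation actually used.
#' @param table a [gpc_table()].
#' @return regularity ratio in `[0, 1]`.
#' @export
grapheme_regularity <- function(grapheme, observed_phoneme, table) {
  rows <- .gpc_rows(table, grapheme)
  modal_p <- max(rows$probability)
  if (modal_p <= 0) stopf("modal pronunciation probability of %s is zero",
                          sQuote(grapheme))
  hit <- rows$probability[rows$phoneme == observed_phoneme]
  if (length(hit) == 0L) {
    stopf("phoneme %s not listed for grapheme %s",
          sQuote(observed_phoneme), sQuote(grapheme))
  }
  hit[1L] / modal_p
}

#' Pronunciation regularity of a word
#'
#' Unweighted mean of the grapheme regularities over a word's segmented
#' (grapheme, phoneme) pairs.
#'
#' @param segmented_word data frame (or two-column matrix/list) with ordered
#'   columns `grapheme` and `phoneme`.
#' @param table a [gpc_table()].
#' @return mean regularity in `[0, 1]`.
#' @export
word_regularity <- function(segmented_word, table) {
  sw <- as.data.frame(segmented_word, stringsAsFactors = FALSE)
  if (nrow(sw) == 0L) stopf("segmented word has no (grapheme, phoneme) pairs")
  if (!all(c("grapheme", "phoneme") %in% names(sw))) {
    names(sw)[1:2] <- c("grapheme", "phoneme")
  }
  ratios <- mapply(grapheme_regularity, sw$grapheme, sw$phoneme,
                   MoreArgs = list(table = table))
  mean(ratios)
}

#' Segment an orthographic string into graphemes
#'
#' Greedy longest-match, left to right, over the grapheme inventory of the
#' table (so `"sh"` is one grapheme when the inventory contains `sh` even
#' though `s` and `h` are also listed). The concatenation of the output
#' always equals the input.
#'
#' @param orthography the written form.
#' @param table a [gpc_table()] (its distinct graphemes form the inventory).
#' @return character vector of graphemes.
#' @export
segment_graphemes <- function(orthography, table) {
  inventory <- unique(table$grapheme)
  if (length(inventory) == 0L) stopf("GPC table is empty")
  max_len <- max(nchar(inventory))
  out <- character(0)
  i <- 1L
  n <- nchar(orthography)
  while (i <= n) {
    found <- FALSE
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      cand <- substr(orthography, i, i + len - 1L)
      if (cand %in% inventory) {
        out <- c(out, cand)
        i <- i + len
        found <- TRUE
        break
      }
    }
    if (!found) {
      stopf("no grapheme in the inventory matches %s at position %d",
            sQuote(orthography), i)
    }
  }
  out
}
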