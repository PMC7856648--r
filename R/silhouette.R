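# Word silhouettes and their pixel-overlap dissimilarity.
#
# Stimuli are rendered as binary ink silhouettes on a fixed canvas (default
# 226 x 151 pixels, the display size of the original word stimuli) using a
# packaged 5x7 dot-matrix font, so that the visual prediction matrix is a
# pure function of the orthographic string and the render configuration.

# 5x7 dot-matrix glyphs; '#' = ink. Lowercase Latin letters and digits.
.font5x7 <- local({
  g <- list(
    a = c(".....", ".....", ".###.", "....#", ".####", "#...#", ".####"),
    b = c("#....", "#....", "#.##.", "##..#", "#...#", "##..#", "#.##."),
    c = c(".....", ".....", ".###.", "#....", "#....", "#...#", ".###."),
    d = c("....#", "....#", ".##.#", "#..##", "#...#", "#..##", ".##.#"),
    e = c(".....", ".....", ".###.", "#...#", "#####", "#....", ".###."),
    f = c("..##.", ".#..#", ".#...", "###..", ".#...", ".#...", ".#..."),
    g = c(".....", ".####", "#...#", "#...#", ".####", "....#", ".###."),
    h = c("#....", "#....", "#.##.", "##..#", "#...#", "#...#", "#...#"),
    i = c("..#..", ".....", ".##..", "..#..", "..#..", "..#..", ".###."),
    j = c("...#.", ".....", "..##.", "...#.", "...#.", "#..#.", ".##.."),
    k = c("#....", "#....", "#..#.", "#.#..", "##...", "#.#..", "#..#."),
    l = c(".##..", "..#..", "..#..", "..#..", "..#..", "..#..", ".###."),
    m = c(".....", ".....", "##.#.", "#.#.#", "#.#.#", "#.#.#", "#...#"),
    n = c(".....", ".....", "#.##.", "##..#", "#...#", "#...#", "#...#"),
    o = c(".....", ".....", ".###.", "#...#", "#...#", "#...#", ".###."),
    p = c(".....", "#.##.", "##..#", "##..#", "#.##.", "#....", "#...."),
    q = c(".....", ".##.#", "#..##", "#..##", ".##.#", "....#", "....#"),
    r = c(".....", ".....", "#.##.", "##..#", "#....", "#....", "#...."),
    s = c(".....", ".....", ".####", "#....", ".###.", "....#", "####."),
    t = c(".#...", ".#...", "####.", ".#...", ".#...", ".#..#", "..##."),
    u = c(".....", ".....", "#...#", "#...#", "#...#", "#..##", ".##.#"),
    v = c(".....", ".....", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
    w = c(".....", ".....", "#...#", "#.#.#", "#.#.#", "#.#.#", ".#.#."),
    x = c(".....", ".....", "#...#", ".#.#.", "..#..", ".#.#.", "#...#"),
    y = c(".....", "#...#", "#...#", "#...#", ".####", "....#", ".###."),
    z = c(".....", ".....", "#####", "...#.", "..#..", ".#...", "#####"),
    `0` = c(".###.", "#...#", "#..##", "#.#.#", "##..#", "#...#", ".###."),
    `1` = c("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", ".###."),
    `2` = c(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####"),
    `3` = c(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###."),
    `4` = c("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#."),
    `5` = c("#####", "#....", "####.", "....#", "....#", "#...#", ".###."),
    `6` = c("..##.", ".#...", "#....", "####.", "#...#", "#...#", ".###."),
    `7` = c("#####", "....#", "...#.", "..#..", ".#...", ".#...", ".#..."),
    `8` = c(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###."),
    `9` = c(".###.", "#...#", "#...#", ".####", "....#", "...#.", ".##.."),
    ` ` = c(".....", ".....", ".....", ".....", ".....", ".....", ".....")
  )
  lapply(g, function(rows) {
    m <- do.call(rbind, strsplit(rows, ""))
    matrix(as.integer(m == "#"), nrow = 7, ncol = 5)
  })
})

#' Silhouette render configuration
#'
#' Canvas and font settings used by [render_silhouette()]. The default canvas
#' is 226 x 151 pixels, matching the on-screen size of the word stimuli. The
#' glyph scale is an integer magnification of the packaged 5x7 dot-matrix
#' font; when `NULL` it is chosen automatically as the largest integer scale
#' at which the text fits the canvas.
#'
#' @param width,height canvas size in pixels.
#' @param scale integer glyph magnification, or `NULL` for automatic.
#' @param ink_threshold grey level in `[0, 1)` above which a pixel counts as
#'   ink after rendering (the packaged font is already binary, so any value
#'   below 1 yields the same silhouette; the knob exists for alternative
#'   renderers).
#' @return a list of class `silhouette_config`.
#' @export
silhouette_config <- function(width = 226L, height = 151L, scale = NULL,
                              ink_threshold = 0.5) {
  if (width < 1 || height < 1) stopf("canvas dimensions must be positive")
  structure(list(width = as.integer(width), height = as.integer(height),
                 scale = scale, ink_threshold = ink_threshold),
            class = "silhouette_config")
}

#' Render a word as a binary silhouette
#'
#' Draws `text` with the packaged deterministic 5x7 dot-matrix font, centred
#' on a fixed canvas, and binarizes with the configured ink threshold.
#' Uppercase Latin letters are case-folded to the lowercase glyphs; supported
#' characters are `a`-`z`, digits and space. Identical `(text, config)` pairs
#' yield bit-identical images.
#'
#' @param text non-empty character string.
#' @param config a [silhouette_config()].
#' @return a `glyph_image`: list with `pixels` (0/1 integer matrix, rows =
#'   canvas height), `width` and `height`.
#' @export
render_silhouette <- function(text, config = silhouette_config()) {
  if (!is.character(text) || length(text) != 1L || nchar(text) == 0L) {
    stopf("text must be a non-empty character string")
  }
  chars <- tolower(strsplit(text, "")[[1]])
  bad <- setdiff(unique(chars), names(.font5x7))
  if (length(bad)) {
    stopf("character(s) not renderable with the packaged glyph set: %s",
          paste(sQuote(bad), collapse = ", "))
  }
  n <- length(chars)
  glyph_w <- 5L; glyph_h <- 7L; advance <- 6L   # 1-pixel inter-glyph gap
  text_w <- advance * n - 1L
  s <- config$scale %||% max(1L, min(config$width %/% text_w,
                                     config$height %/% glyph_h))
  s <- as.integer(s)
  if (s * text_w > config$width || s * glyph_h > config$height) {
    stopf("text %s does not fit the %dx%d canvas at scale %d",
          sQuote(text), config$width, config$height, s)
  }
  canvas <- matrix(0L, nrow = config$height, ncol = config$width)
  x0 <- (config$width - s * text_w) %/% 2L
  y0 <- (config$height - s * glyph_h) %/% 2L
  for (k in seq_len(n)) {
    glyph <- .font5x7[[chars[k]]]
    # integer magnification preserves binarity
    big <- glyph[rep(seq_len(glyph_h), each = s), rep(seq_len(glyph_w), each = s),
                 drop = FALSE]
    rows <- y0 + seq_len(glyph_h * s)
    cols <- x0 + (k - 1L) * advance * s + seq_len(glyph_w * s)
    canvas[rows, cols] <- big
  }
  canvas <- (canvas >= config$ink_threshold) * 1L
  if (!any(canvas == 1L) && any(chars != " ")) {
    stopf("rendered silhouette of %s has no ink pixels", sQuote(text))
  }
  structure(list(pixels = canvas, width = config$width, height = config$height),
            class = "glyph_image")
}

#' @export
print.glyph_image <- function(x, ...) {
  cat(sprintf("<glyph_image %dx%d, %d ink pixels>\n",
              x$width, x$height, sum(x$pixels)))
  invisible(x)
}

#' Pixel-overlap dissimilarity of two silhouettes
#'
#' Quantifies the non-overlap of the ink regions of two binary images. The
#' default normalizer is the union of the two ink sets (Jaccard distance):
#' identical images score 0, disjoint ink sets score 1. `normalizer =
#' "canvas"` divides the symmetric difference by the full canvas area
#' instead.
#'
#' @param a,b `glyph_image` objects sharing canvas dimensions.
#' @param normalizer `"union"` (default) or `"canvas"`.
#' @return dissimilarity in `[0, 1]`.
#' @export
visual_dissimilarity <- function(a, b, normalizer = c("union", "canvas")) {
  normalizer <- match.arg(normalizer)
  if (!inherits(a, "glyph_image") || !inherits(b, "glyph_image")) {
    stopf("inputs must be glyph_image objects")
  }
  if (a$width != b$width || a$height != b$height) {
    stopf("canvas sizes differ: %dx%d vs %dx%d",
          a$width, a$height, b$width, b$height)
  }
  pa <- a$pixels == 1L; pb <- b$pixels == 1L
  sym_diff <- sum(xor(pa, pb))
  if (normalizer == "canvas") return(sym_diff / (a$width * a$height))
  un <- sum(pa | pb)
  if (un == 0L) stopf("both images are empty; overlap ratio undefined")
  sym_diff / un
}

#' Write / read a silhouette as a greyscale PNG
#'
#' Ink pixels are written as black (0), background as white (1). Reading
#' re-binarizes with the supplied threshold.
#'
#' @param img a `glyph_image`.
#' @param path file path ending in `.png`.
#' @param ink_threshold grey level below which a read pixel counts as ink.
#' @return `read_silhouette` returns a `glyph_image`; `write_silhouette`
#'   returns `path` invisibly.
#' @export
write_silhouette <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stopf("the 'png' package is required to write silhouettes")
  }
  png::writePNG(1 - img$pixels, target = path)
  invisible(path)
}

#' @rdname write_silhouette
#' @export
read_silhouette <- function(path, ink_threshold = 0.5) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stopf("the 'png' package is required to read silhouettes")
  }
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  pixels <- (px < ink_threshold) * 1L
  structure(list(pixels = pixels, width = ncol(pixels), height = nrow(pixels)),
            class = "glyph_image")
}
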