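#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor pf pt qnorm qt rnorm sd t.test var aov runif
#' @importFrom utils read.delim write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}

# Derive `n` reproducible child seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# 32-bit FNV-1a hash of a character scalar, returned as 8 hex digits.
# Used to stamp configuration into run logs and result files. State is
# kept in a double and XORed in 16-bit halves because bitwXor only
# accepts values below 2^31.
fnv1a32 <- function(x) {
  xor32 <- function(a, b) {
    bitwXor(a %/% 65536, b %/% 65536) * 65536 +
      bitwXor(a %% 65536, b %% 65536)
  }
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    # 32-bit modular multiply by the FNV prime; h is split so every
    # intermediate stays below 2^53 and remains exact in a double
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 4294967296
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
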