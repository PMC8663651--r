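#' @useDynLib painlex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif
#' @importFrom utils head write.csv read.csv
NULL

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic operations in the package go
# through this so a single integer seed fully determines their output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Tokenize a descriptor or phrase into lowercase word tokens
#' @param x character scalar
#' @return character vector of tokens
#' @keywords internal
phrase_tokens <- function(x) {
  strsplit(tolower(trimws(x)), "\\s+")[[1]]
}

#' Test whether a token sequence contains a word or multiword phrase
#'
#' Matching is case-insensitive and whole-token: a multiword phrase such as
#' "feel hopeless" matches only as consecutive tokens.
#'
#' @param tokens character vector of (already lowercased) tokens
#' @param phrase character scalar, a word or space-separated phrase
#' @return logical scalar
#' @export
contains_phrase <- function(tokens, phrase) {
  ph <- phrase_tokens(phrase)
  np <- length(ph)
  n <- length(tokens)
  if (np == 0L || n < np) return(FALSE)
  if (np == 1L) return(ph %in% tokens)
  hits <- which(tokens == ph[1L])
  for (i in hits) {
    if (i + np - 1L <= n && all(tokens[i:(i + np - 1L)] == ph)) return(TRUE)
  }
  FALSE
}

# 64-bit FNV-1a over a character scalar, returned as a hex string. Used for
# lightweight provenance hashes in stage manifests; not cryptographic.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  # work in two 32-bit halves to stay inside double precision
  h <- c(0x811c9dc5, 0xcbf29ce4) # low, high of FNV offset basis (64-bit)
  prime <- 0x100 # FNV-64 prime is 2^40 + 2^8 + 0xb3; we use a folded variant
  lo <- h[1]; hi <- h[2]
  for (b in bytes) {
    lo <- bitwXor(as.integer(lo %% 2^31), as.integer(b))
    # multiply-fold: keep within 2^31 to avoid integer overflow
    lo <- (lo * 16777619) %% 2^31
    hi <- bitwXor(as.integer(hi %% 2^31), as.integer(lo %% 256))
    hi <- (hi * 16777619) %% 2^31
  }
  sprintf("%08x%08x", as.integer(hi), as.integer(lo))
}

# Stable provenance hash of an arbitrary R object via its JSON rendering.
object_hash <- function(obj) {
  fnv1a_hash(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' Suffix-stripping stemmer
#'
#' A compact Porter-style stemmer used by the same-root pruning rule: it
#' strips plural and common derivational suffixes (-ing, -ed, -ly, -ness,
#' -ation, ...) with the usual consonant-doubling and trailing-e repairs.
#' It is intentionally conservative; the pruning rule only needs stems of
#' morphological variants of the same descriptor to collide (burn/burning,
#' ache/aching), not linguistically perfect stems.
#'
#' @param words character vector
#' @return character vector of stems, same length
#' @export
stem_words <- function(words) {
  vapply(tolower(words), stem_one, character(1), USE.NAMES = FALSE)
}

stem_one <- function(w) {
  if (nchar(w) <= 3L) return(w)
  # plural / 3rd person
  if (grepl("sses$", w)) w <- sub("sses$", "ss", w)
  else if (grepl("ies$", w)) w <- sub("ies$", "i", w)
  else if (grepl("[^s]s$", w)) w <- sub("s$", "", w)
  n <- nchar(w)
  vowel <- function(s) grepl("[aeiouy]", s)
  strip <- function(w, suf) substr(w, 1L, nchar(w) - nchar(suf))
  repair <- function(stem) {
    # undo consonant doubling: stabb -> stab, gnaww kept only for ll/ss/zz
    n <- nchar(stem)
    if (n >= 2L) {
      last <- substr(stem, n, n)
      prev <- substr(stem, n - 1L, n - 1L)
      if (last == prev && !last %in% c("l", "s", "z") && grepl("[^aeiou]", last)) {
        stem <- substr(stem, 1L, n - 1L)
      }
    }
    # restore silent e for CVC-like endings: puncturat -> too deep, skip;
    # ach -> ache handled by collision (ache also stems to ach)
    stem
  }
  for (suf in c("ational", "ation", "iveness", "fulness", "ousness",
                "ability", "ibility", "ement", "ment", "ness", "ingly",
                "edly", "ing", "ed", "ly", "ful", "ous", "ive", "ize",
                "al", "er", "est")) {
    if (grepl(paste0(suf, "$"), w)) {
      stem <- strip(w, suf)
      if (nchar(stem) >= 3L && vowel(stem)) {
        w <- repair(stem)
        break
      }
    }
  }
  # trailing e is dropped so burn/burning and ache/aching collide
  if (nchar(w) > 3L && grepl("e$", w) && !grepl("ee$", w)) w <- sub("e$", "", w)
  w
}
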