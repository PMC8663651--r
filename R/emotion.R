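emotion_channels <- c("anger", "fear", "sadness", "joy", "valence")

#' Build an emotion-intensity lexicon
#'
#' @param entries data.frame with columns `token`, `channel`, `intensity`;
#'   channel must be one of anger, fear, sadness, joy, valence and
#'   intensity in \[0,1\]
#' @return an `emotion_lexicon` object (token -> channel -> intensity)
#' @export
emotion_lexicon <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("token", "channel", "intensity") %in% names(entries)))
  bad <- !(entries$channel %in% emotion_channels)
  if (any(bad)) {
    stop(sprintf("unknown emotion channel(s): %s",
                 paste(unique(entries$channel[bad]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(entries$intensity < 0 | entries$intensity > 1)) {
    stop("intensities must be in [0,1]", call. = FALSE)
  }
  entries$token <- tolower(entries$token)
  structure(list(entries = entries), class = "emotion_lexicon")
}

#' Read an emotion lexicon from TSV
#'
#' The TSV format (columns token, channel, intensity; with header) is the
#' package's plug-in point for standard affect-intensity lexicons.
#'
#' @param path TSV path
#' @return an `emotion_lexicon`
#' @export
read_emotion_lexicon <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  emotion_lexicon(df)
}

#' The small built-in demonstration lexicon
#'
#' A compact, hand-written affect lexicon sufficient for examples and for
#' scoring the synthetic corpus; not a substitute for a full
#' affect-intensity lexicon.
#' @return an `emotion_lexicon`
#' @export
demo_emotion_lexicon <- function() {
  read_emotion_lexicon(system.file("extdata", "demo_emotion_lexicon.tsv",
                                   package = "painlex", mustWork = TRUE))
}

#' Build an emotion lexicon from a planted corpus lexicon
#'
#' Converts the `emotion_words` block of a [planted_lexicon()] into an
#' [emotion_lexicon()], so generated corpora can be scored against exactly
#' the intensities that were planted.
#'
#' @param lexicon a [planted_lexicon()]
#' @return an `emotion_lexicon`
#' @export
emotion_lexicon_from_planted <- function(lexicon) {
  stopifnot(inherits(lexicon, "planted_lexicon"))
  rows <- list()
  for (ch in names(lexicon$emotion_words)) {
    v <- lexicon$emotion_words[[ch]]
    rows[[ch]] <- data.frame(token = names(v), channel = ch,
                             intensity = as.numeric(v),
                             stringsAsFactors = FALSE)
  }
  emotion_lexicon(do.call(rbind, rows))
}

#' Score one post on the five emotion channels
#'
#' Per channel, the score is the maximum lexicon intensity over the post's
#' tokens (0 when no lexicon token occurs). The whole post is one scoring
#' unit; no sentence splitting.
#'
#' @param tokens cleaned tokens of one post
#' @param lexicon an [emotion_lexicon()]
#' @return named numeric of length 5 (anger, fear, sadness, joy, valence),
#'   each in \[0,1\]
#' @export
score_emotions <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "emotion_lexicon"))
  out <- stats::setNames(numeric(length(emotion_channels)), emotion_channels)
  if (length(tokens) == 0L) return(out)
  hit <- lexicon$entries[lexicon$entries$token %in% tokens, , drop = FALSE]
  if (nrow(hit) > 0L) {
    agg <- tapply(hit$intensity, hit$channel, max)
    out[names(agg)] <- agg
  }
  out
}

#' Map five emotion channels to one pain intensity
#'
#' The engine that produced the five channels does not prescribe a pain
#' mapping, so the mapping is explicit and configurable:
#' \describe{
#'   \item{neg_max (default)}{`max(anger, fear, sadness)` -- pain load is
#'     carried by the negative channels}
#'   \item{one_minus_valence}{`1 - valence`}
#'   \item{blend}{weighted mean of the five channels with `weights`
#'     (valence enters as `1 - valence`)}
#' }
#'
#' @param scores named numeric as returned by [score_emotions()]
#' @param mode one of "neg_max", "one_minus_valence", "blend"
#' @param weights named numeric over the five channels (blend mode only);
#'   normalised internally
#' @return pain intensity in \[0,1\]
#' @export
pain_intensity <- function(scores, mode = c("neg_max", "one_minus_valence",
                                            "blend"),
                           weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(emotion_channels %in% names(scores)),
            all(scores >= 0 & scores <= 1))
  val <- switch(mode,
    neg_max = max(scores[["anger"]], scores[["fear"]], scores[["sadness"]]),
    one_minus_valence = 1 - scores[["valence"]],
    blend = {
      if (is.null(weights)) {
        weights <- c(anger = 1, fear = 1, sadness = 1, joy = 0, valence = 1)
      }
      stopifnot(all(names(weights) %in% emotion_channels), sum(weights) > 0)
      x <- scores
      x[["valence"]] <- 1 - x[["valence"]]
      sum(weights * x[names(weights)]) / sum(weights)
    })
  min(1, max(0, val))
}

#' Aggregate pain intensity of a descriptor over its containing posts
#'
#' The descriptor's intensity is the arithmetic mean of per-post pain
#' intensities over all posts containing it. With zero containing posts the
#' intensity is undefined: the function errors, and callers must treat the
#' descriptor as missing rather than as zero.
#'
#' @param token_lists list of token vectors for the posts containing the
#'   descriptor
#' @param lexicon an [emotion_lexicon()]
#' @param mode passed to [pain_intensity()]
#' @param aggregate "mean" (default) or "median"
#' @return intensity in \[0,1\]
#' @export
descriptor_intensity <- function(token_lists, lexicon, mode = "neg_max",
                                 aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (length(token_lists) == 0L) {
    stop("descriptor intensity undefined with zero containing posts",
         call. = FALSE)
  }
  vals <- vapply(token_lists, function(toks) {
    pain_intensity(score_emotions(toks, lexicon), mode = mode)
  }, numeric(1))
  if (aggregate == "mean") mean(vals) else stats::median(vals)
}

#' Per-descriptor statistics over a corpus
#'
#' Computes post-level counts and mean pain intensities for a set of
#' descriptors over a cleaned corpus; descriptors with zero containing
#' posts get count 0 and `NA` intensity (missing, never 0).
#'
#' @param posts cleaned corpus data.frame (with `tokens`)
#' @param descriptors character vector of descriptor words/phrases
#' @param lexicon an [emotion_lexicon()]
#' @param mode passed to [pain_intensity()]
#' @return data.frame descriptor, count, intensity
#' @export
descriptor_stats <- function(posts, descriptors, lexicon,
                             mode = "neg_max") {
  stopifnot(is.data.frame(posts), "tokens" %in% names(posts))
  res <- lapply(descriptors, function(d) {
    has <- vapply(posts$tokens, contains_phrase, logical(1), phrase = d)
    cnt <- sum(has)
    intensity <- if (cnt == 0L) NA_real_ else
      descriptor_intensity(posts$tokens[has], lexicon, mode = mode)
    data.frame(descriptor = tolower(d), count = cnt, intensity = intensity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
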