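#' Sarcasm scoring configuration
#'
#' Posts are rated for sarcasm on a 0-1 scale and posts rated strictly
#' above `threshold` (default 0.7) are removed. The default scorer is a
#' transparent, rule-based stand-in for a trained classifier: it counts
#' surface features of ironic writing and squashes their weighted sum onto
#' \[0,1\] with a scaled logistic anchored at 0 for zero activation.
#'
#' Default features and weights:
#' \describe{
#'   \item{marker (2.0)}{hits on configured sarcasm-marker words/phrases}
#'   \item{juxtaposition (0.8)}{a positive word and a negative-context word
#'     in the same post}
#'   \item{interjection (0.5)}{stock interjections (oh, wow, sure, ...)}
#'   \item{elongation (0.4)}{tokens with a letter repeated 3+ times
#'     ("soooo")}
#'   \item{burst (0.3)}{exclamation/question bursts ("!!", "?!") in the raw
#'     text}
#'   \item{scare_quotes (0.4)}{a quoted single word in the raw text}
#' }
#'
#' @param threshold removal threshold in \[0,1\]; strictly greater ratings
#'   are removed
#' @param scorer scoring function `(tokens, raw_text, cfg) -> list(rating,
#'   trace)`; defaults to the built-in feature scorer
#' @param feature_weights named numeric vector overriding default weights
#' @param sarcasm_markers character vector of marker words/phrases
#' @return a `sarcasm_config` list
#' @export
sarcasm_config <- function(threshold = 0.7,
                           scorer = NULL,
                           feature_weights = NULL,
                           sarcasm_markers = c("yeah right", "totally fun",
                                               "loving this", "just great",
                                               "sure thing")) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  weights <- c(marker = 2.0, juxtaposition = 0.8, interjection = 0.5,
               elongation = 0.4, burst = 0.3, scare_quotes = 0.4)
  if (!is.null(feature_weights)) {
    unknown <- setdiff(names(feature_weights), names(weights))
    if (length(unknown) > 0L) {
      stop(sprintf("unknown feature(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    weights[names(feature_weights)] <- feature_weights
  }
  structure(list(threshold = threshold,
                 scorer = scorer,
                 feature_weights = weights,
                 sarcasm_markers = tolower(sarcasm_markers)),
            class = "sarcasm_config")
}

# Scaled logistic on [0, Inf) -> [0, 1): 0 activation maps exactly to 0,
# and the rating is strictly increasing in the activation.
squash01 <- function(x) 2 / (1 + exp(-x)) - 1

sarcasm_positive_words <- c("love", "loving", "great", "awesome", "fantastic",
                            "wonderful", "perfect", "best", "fun", "nice")
sarcasm_negative_context <- c("pain", "hurts", "hurt", "broken", "worst",
                              "hate", "sick", "awful", "terrible", "misery")
sarcasm_interjections <- c("oh", "wow", "sure", "right", "obviously",
                           "clearly", "totally", "definitely")

default_sarcasm_features <- function(tokens, raw_text, cfg) {
  marker <- sum(vapply(cfg$sarcasm_markers, contains_phrase, logical(1),
                       tokens = tokens))
  juxt <- as.integer(any(tokens %in% sarcasm_positive_words) &&
                       any(tokens %in% sarcasm_negative_context))
  interjection <- sum(tokens %in% sarcasm_interjections)
  elongation <- sum(grepl("([a-z])\\1\\1", tokens))
  burst <- if (is.null(raw_text) || is.na(raw_text)) 0L else
    lengths(regmatches(raw_text, gregexpr("[!?]{2,}", raw_text)))
  scare <- if (is.null(raw_text) || is.na(raw_text)) 0L else
    lengths(regmatches(raw_text, gregexpr("\"[A-Za-z]+\"|'[A-Za-z]+'",
                                          raw_text)))
  c(marker = marker, juxtaposition = juxt, interjection = interjection,
    elongation = elongation, burst = burst, scare_quotes = scare)
}

#' Score one post for sarcasm
#'
#' @param tokens cleaned tokens of the post
#' @param cfg a [sarcasm_config()]
#' @param raw_text optional raw text (enables the punctuation features,
#'   which cleaning removes)
#' @param post_id optional id recorded in the result
#' @return a `sarcasm_score` list: `post_id`, `rating` in \[0,1\] and
#'   `feature_trace` (named numeric of weighted contributions whose sum is
#'   the pre-squash activation)
#' @export
score_sarcasm <- function(tokens, cfg = sarcasm_config(), raw_text = NULL,
                          post_id = NA_character_) {
  stopifnot(inherits(cfg, "sarcasm_config"))
  if (!is.null(cfg$scorer)) {
    res <- cfg$scorer(tokens, raw_text, cfg)
    stopifnot(is.numeric(res$rating), res$rating >= 0, res$rating <= 1)
    return(structure(list(post_id = post_id, rating = res$rating,
                          feature_trace = res$trace %||% numeric(0)),
                     class = "sarcasm_score"))
  }
  if (length(tokens) == 0L) {
    return(structure(list(post_id = post_id, rating = 0,
                          feature_trace = cfg$feature_weights * 0),
                     class = "sarcasm_score"))
  }
  feats <- default_sarcasm_features(tokens, raw_text, cfg)
  contrib <- cfg$feature_weights[names(feats)] * feats
  rating <- squash01(sum(contrib))
  structure(list(post_id = post_id, rating = rating,
                 feature_trace = contrib),
            class = "sarcasm_score")
}

#' Filter a corpus by sarcasm rating
#'
#' Posts with a rating strictly above `cfg$threshold` are removed; a rating
#' exactly at the threshold is kept. The result partitions the input and
#' preserves order.
#'
#' @param posts corpus data.frame with a `tokens` list-column (see
#'   [clean_posts()])
#' @param cfg a [sarcasm_config()]
#' @param ratings optional numeric vector of precomputed ratings (one per
#'   post), e.g. from an external classifier; when supplied the built-in
#'   scorer is bypassed
#' @return list with `kept`, `removed` (data.frames) and `scores`
#'   (data.frame id, rating, removed)
#' @export
filter_sarcastic <- function(posts, cfg = sarcasm_config(), ratings = NULL) {
  stopifnot(is.data.frame(posts), inherits(cfg, "sarcasm_config"))
  if (is.null(ratings)) {
    if (!("tokens" %in% names(posts))) {
      stop("posts must be cleaned first (missing `tokens`); see clean_posts()",
           call. = FALSE)
    }
    ratings <- vapply(seq_len(nrow(posts)), function(i) {
      score_sarcasm(posts$tokens[[i]], cfg,
                    raw_text = posts$text[i], post_id = posts$id[i])$rating
    }, numeric(1))
  }
  stopifnot(length(ratings) == nrow(posts),
            all(ratings >= 0 & ratings <= 1))
  removed_flag <- ratings > cfg$threshold # strict: exactly 0.7 is kept
  list(kept = posts[!removed_flag, , drop = FALSE],
       removed = posts[removed_flag, , drop = FALSE],
       scores = data.frame(id = posts$id, rating = ratings,
                           removed = removed_flag,
                           stringsAsFactors = FALSE))
}

#' Write sarcasm scores as CSV
#' @param scores the `scores` data.frame from [filter_sarcastic()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sarcasm_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
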