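#' Planted lexicon for the synthetic-corpus generator
#'
#' Describes the lexical structure the generator plants in posts: the root
#' pain descriptors, their associated words with co-occurrence propensities,
#' pain conditions, emotion-bearing words with channel intensities, and
#' sarcasm markers.
#'
#' @param root_descriptors character vector of descriptor words/phrases
#' @param associates named list: one entry per root, each a named numeric
#'   vector mapping associate word to co-occurrence propensity in \[0,1\].
#'   No associate may equal a root descriptor or share its stem, so planted
#'   novelty stays detectable downstream.
#' @param conditions character vector of pain-condition words/phrases
#' @param emotion_words named list keyed by channel (anger, fear, sadness,
#'   joy, valence), each a named numeric vector word -> intensity in \[0,1\]
#' @param sarcasm_markers character vector of marker words/phrases
#' @return a `planted_lexicon` list
#' @export
planted_lexicon <- function(root_descriptors,
                            associates = list(),
                            conditions = character(0),
                            emotion_words = list(),
                            sarcasm_markers = character(0)) {
  root_descriptors <- tolower(root_descriptors)
  stopifnot(length(root_descriptors) > 0L)
  root_stems <- stem_words(root_descriptors)
  for (root in names(associates)) {
    if (!(root %in% root_descriptors)) {
      stop(sprintf("associate entry for unknown root '%s'", root),
           call. = FALSE)
    }
    props <- associates[[root]]
    if (any(props < 0 | props > 1)) {
      stop("associate propensities must be in [0,1]", call. = FALSE)
    }
    for (w in names(props)) {
      if (w %in% root_descriptors || stem_words(w) %in% root_stems) {
        stop(sprintf(
          "associate '%s' equals or shares a stem with a root descriptor", w),
          call. = FALSE)
      }
    }
  }
  for (ch in names(emotion_words)) {
    v <- emotion_words[[ch]]
    if (any(v < 0 | v > 1)) {
      stop("emotion intensities must be in [0,1]", call. = FALSE)
    }
  }
  structure(list(root_descriptors = root_descriptors,
                 associates = associates,
                 conditions = tolower(conditions),
                 emotion_words = emotion_words,
                 sarcasm_markers = tolower(sarcasm_markers)),
            class = "planted_lexicon")
}

#' A small default planted lexicon
#'
#' Convenience lexicon used in examples and tests: a handful of MPQ-style
#' roots, one planted associate each, common pain conditions, a toy emotion
#' lexicon and stock sarcasm markers.
#' @return a [planted_lexicon()]
#' @export
default_planted_lexicon <- function() {
  planted_lexicon(
    root_descriptors = c("stabbing", "burning", "throbbing", "aching"),
    associates = list(
      stabbing = c(puncturing = 0.5),
      burning = c(searing2 = 0.0), # probability-zero distractor spelling
      throbbing = c(pulsating = 0.4),
      aching = c(tender2 = 0.3)
    ),
    conditions = c("migraine", "arthritis", "sciatica", "toothache"),
    emotion_words = list(
      anger = c(furious = 0.8),
      fear = c(terrified = 0.85),
      sadness = c(heartbroken = 0.75),
      joy = c(delighted = 0.7),
      valence = c(awful = 0.2)
    ),
    sarcasm_markers = c("yeah right", "totally fun", "loving this")
  )
}

#' Configuration of the synthetic-corpus generator
#'
#' The generator emulates a keyword-harvested social-media corpus: a
#' fraction `p_contains_pain` of posts are "pain posts" that contain the
#' token "pain" with a root descriptor planted adjacent to it (so the
#' round-1 hop criterion is satisfiable), associates co-occurring with
#' their root at the configured propensity, an optional pain condition and
#' an optional emotion word. A fraction `p_sarcastic` of posts carry one
#' sarcasm marker. The remaining tokens are drawn from a noise vocabulary,
#' and surface noise (mentions, URLs, punctuation, case) is layered on at
#' render time only.
#'
#' @param n_posts number of posts (0 gives an empty corpus)
#' @param lexicon a [planted_lexicon()]
#' @param p_contains_pain probability a post is a pain post
#' @param p_sarcastic probability a post carries a sarcasm marker
#' @param p_username probability of a leading @-mention in the rendered text
#' @param p_url probability of an inserted URL token
#' @param p_condition probability a pain post names a pain condition
#' @param p_emotion probability a pain post carries one emotion word
#' @param noise_vocab_size size of the background vocabulary
#' @param post_length_range integer c(min, max) count of noise tokens per
#'   post (min at least 3); planted tokens come on top of these
#' @param seed integer seed; identical (config, seed) pairs produce
#'   byte-identical corpora
#' @return a `corpus_config` list
#' @export
corpus_config <- function(n_posts,
                          lexicon = default_planted_lexicon(),
                          p_contains_pain = 0.35,
                          p_sarcastic = 0.05,
                          p_username = 0.3,
                          p_url = 0.15,
                          p_condition = 0.5,
                          p_emotion = 0.3,
                          noise_vocab_size = 200L,
                          post_length_range = c(5L, 12L),
                          seed = 1L) {
  probs <- c(p_contains_pain = p_contains_pain, p_sarcastic = p_sarcastic,
             p_username = p_username, p_url = p_url,
             p_condition = p_condition, p_emotion = p_emotion)
  bad <- probs < 0 | probs > 1 | !is.finite(probs)
  if (any(bad)) {
    stop(sprintf("probabilities out of [0,1]: %s",
                 paste(names(probs)[bad], collapse = ", ")), call. = FALSE)
  }
  stopifnot(inherits(lexicon, "planted_lexicon"),
            length(post_length_range) == 2L,
            post_length_range[1] >= 3L,
            post_length_range[2] >= post_length_range[1],
            noise_vocab_size >= 1L)
  structure(list(n_posts = as.integer(max(0L, n_posts)), lexicon = lexicon,
                 p_contains_pain = p_contains_pain,
                 p_sarcastic = p_sarcastic, p_username = p_username,
                 p_url = p_url, p_condition = p_condition,
                 p_emotion = p_emotion,
                 noise_vocab_size = as.integer(noise_vocab_size),
                 post_length_range = as.integer(post_length_range),
                 seed = as.integer(seed)),
            class = "corpus_config")
}

noise_vocab <- function(config) {
  sprintf("w%03d", seq_len(config$noise_vocab_size))
}

flat_emotion_words <- function(lexicon) {
  unlist(lapply(lexicon$emotion_words, names), use.names = FALSE)
}

#' Generate a synthetic corpus with hidden labels
#'
#' @param config a [corpus_config()]
#' @return list with `posts` (data.frame id, platform, timestamp, text) and
#'   `labels` (sidecar data.frame: id, relevant, sarcastic, pain, root,
#'   condition, associates -- comma-joined planted associates -- and
#'   emotion_word, marker). Labels never appear inside the text.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  n <- config$n_posts
  empty <- list(
    posts = data.frame(id = character(0), platform = character(0),
                       timestamp = character(0), text = character(0),
                       stringsAsFactors = FALSE),
    labels = data.frame(id = character(0), relevant = logical(0),
                        sarcastic = logical(0), pain = logical(0),
                        root = character(0), condition = character(0),
                        associates = character(0),
                        emotion_word = character(0), marker = character(0),
                        stringsAsFactors = FALSE))
  if (n == 0L) return(empty)
  lex <- config$lexicon
  vocab <- noise_vocab(config)
  emo_words <- flat_emotion_words(lex)
  platforms <- c("twitter", "facebook", "instagram", "youtube")
  year_start <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")

  with_seed(config$seed, {
    ids <- sprintf("p%06d", seq_len(n))
    relevant <- runif(n) < config$p_contains_pain
    sarcastic <- runif(n) < config$p_sarcastic
    platform <- platforms[sample.int(length(platforms), n, replace = TRUE)]
    secs <- floor(runif(n, 0, 365 * 24 * 3600))
    timestamp <- format(year_start + secs, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

    text <- character(n)
    root_lab <- rep(NA_character_, n)
    cond_lab <- rep(NA_character_, n)
    assoc_lab <- rep(NA_character_, n)
    emo_lab <- rep(NA_character_, n)
    marker_lab <- rep(NA_character_, n)

    lr <- config$post_length_range
    for (i in seq_len(n)) {
      len <- sample.int(lr[2] - lr[1] + 1L, 1L) + lr[1] - 1L
      toks <- vocab[sample.int(length(vocab), len, replace = TRUE)]
      if (relevant[i]) {
        root <- lex$root_descriptors[sample.int(length(lex$root_descriptors), 1L)]
        root_lab[i] <- root
        # the root descriptor is used in a "pain <descriptor>" frame,
        # guaranteeing it sits one hop from "pain" in the post's word graph
        toks <- insert_at_random(toks, c("pain", phrase_tokens(root)))
        props <- lex$associates[[root]]
        if (length(props) > 0L) {
          inc <- runif(length(props)) < props
          if (any(inc)) {
            assoc_lab[i] <- paste(names(props)[inc], collapse = ",")
            # associates are used in the same "pain <word>" construction as
            # their root (paradigmatic planting): that is what makes them
            # discoverable as embedding neighbours, while still co-occurring
            # with the root within the post at the stated propensity
            for (a in names(props)[inc]) {
              toks <- insert_at_random(toks, c("pain", phrase_tokens(a)))
            }
          }
        }
        if (length(emo_words) > 0L && runif(1) < config$p_emotion) {
          ew <- emo_words[sample.int(length(emo_words), 1L)]
          emo_lab[i] <- ew
          toks <- insert_at_random(toks, phrase_tokens(ew))
        }
        if (length(lex$conditions) > 0L && runif(1) < config$p_condition) {
          cond <- lex$conditions[sample.int(length(lex$conditions), 1L)]
          cond_lab[i] <- cond
          toks <- insert_at_random(toks, phrase_tokens(cond))
        }
      }
      if (sarcastic[i] && length(lex$sarcasm_markers) > 0L) {
        mk <- lex$sarcasm_markers[sample.int(length(lex$sarcasm_markers), 1L)]
        marker_lab[i] <- mk
        toks <- c(toks, phrase_tokens(mk))
      }
      text[i] <- render_post_text(toks, config)
    }
    posts <- data.frame(id = ids, platform = platform, timestamp = timestamp,
                        text = text, stringsAsFactors = FALSE)
    labels <- data.frame(id = ids, relevant = relevant, sarcastic = sarcastic,
                         pain = relevant, root = root_lab,
                         condition = cond_lab, associates = assoc_lab,
                         emotion_word = emo_lab, marker = marker_lab,
                         stringsAsFactors = FALSE)
    list(posts = posts, labels = labels)
  })
}

insert_at_random <- function(toks, block) {
  at <- sample.int(length(toks) + 1L, 1L) - 1L
  append(toks, block, after = at)
}

# Surface noise applied at render time only: a leading @-mention, an
# inserted URL, occasional trailing exclamations and one upper-cased token.
# All of it is reversed by clean_text(), so cleaned tokens equal the
# generated token sequence exactly.
render_post_text <- function(toks, config) {
  if (runif(1) < 0.2 && length(toks) > 0L) {
    j <- sample.int(length(toks), 1L)
    toks[j] <- toupper(toks[j])
  }
  if (runif(1) < 0.1 && length(toks) > 0L) {
    toks[length(toks)] <- paste0(toks[length(toks)], "!!!")
  }
  if (runif(1) < config$p_url) {
    at <- sample.int(length(toks) + 1L, 1L) - 1L
    toks <- append(toks, sprintf("https://t.co/%05d",
                                 floor(runif(1, 0, 99999))), after = at)
  }
  if (runif(1) < config$p_username) {
    toks <- c(sprintf("@user%04d", floor(runif(1, 0, 9999))), toks)
  }
  paste(toks, collapse = " ")
}

#' Analytic expected post-level counts under the generative model
#'
#' For each queried word, the expected number of posts whose cleaned tokens
#' contain it at least once. Lexicon words follow directly from the planting
#' probabilities; noise-vocabulary words use the occupancy probability
#' `1 - (1 - 1/V)^L` averaged over the post-length range; anything else has
#' expectation 0.
#'
#' @param config a [corpus_config()]
#' @param words character vector of words to evaluate; defaults to all
#'   lexicon words plus "pain"
#' @return named numeric vector of expected counts
#' @export
expected_counts <- function(config, words = NULL) {
  stopifnot(inherits(config, "corpus_config"))
  lex <- config$lexicon
  n <- config$n_posts
  k_root <- length(lex$root_descriptors)
  emo_words <- flat_emotion_words(lex)
  if (is.null(words)) {
    words <- unique(c("pain", lex$root_descriptors,
                      unlist(lapply(lex$associates, names), use.names = FALSE),
                      lex$conditions, emo_words, lex$sarcasm_markers))
  }
  vocab <- noise_vocab(config)
  lr <- config$post_length_range
  lens <- lr[1]:lr[2]
  p_noise <- mean(1 - (1 - 1 / config$noise_vocab_size)^lens)
  out <- numeric(length(words))
  names(out) <- words
  for (w in words) {
    lw <- tolower(w)
    if (lw == "pain") {
      out[w] <- n * config$p_contains_pain
    } else if (lw %in% lex$root_descriptors) {
      out[w] <- n * config$p_contains_pain / k_root
    } else if (any(vapply(lex$associates,
                          function(a) lw %in% names(a), logical(1)))) {
      # an associate may hang off several roots; expectations add because a
      # post plants exactly one root
      e <- 0
      for (root in names(lex$associates)) {
        props <- lex$associates[[root]]
        if (lw %in% names(props)) {
          e <- e + n * config$p_contains_pain / k_root * props[[lw]]
        }
      }
      out[w] <- e
    } else if (lw %in% lex$conditions) {
      out[w] <- n * config$p_contains_pain * config$p_condition /
        length(lex$conditions)
    } else if (lw %in% emo_words) {
      out[w] <- n * config$p_contains_pain * config$p_emotion /
        length(emo_words)
    } else if (lw %in% lex$sarcasm_markers) {
      out[w] <- n * config$p_sarcastic / length(lex$sarcasm_markers)
    } else if (lw %in% vocab) {
      out[w] <- n * p_noise
    } else {
      out[w] <- 0
    }
  }
  out
}

#' Write generator hidden labels as JSON-lines
#' @param labels the `labels` data.frame from [generate_corpus()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_labels_jsonl <- function(labels, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(labels))) {
    rec <- as.list(labels[i, , drop = FALSE])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"),
               con, useBytes = TRUE)
  }
  invisible(path)
}
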