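#' Embedding training configuration
#'
#' Hyperparameters of the skip-gram-with-negative-sampling trainer and of
#' neighbour extraction. Training is single-threaded and fully determined
#' by `seed`: the same corpus and configuration reproduce the same vectors
#' bit for bit.
#'
#' @param dimension embedding dimension (default 100)
#' @param context_window one-sided context window in tokens (default 5)
#' @param min_count minimum corpus frequency for a token to enter the
#'   vocabulary (default 5)
#' @param epochs training passes over the corpus (default 5)
#' @param negative_samples negative samples per positive pair (default 5)
#' @param alpha,min_alpha initial and floor learning rate
#' @param seed integer RNG seed
#' @param max_neighbors maximum associated words returned per keyword
#'   (default 20)
#' @return an `embedding_config` list
#' @export
embedding_config <- function(dimension = 100L, context_window = 5L,
                             min_count = 5L, epochs = 5L,
                             negative_samples = 5L, alpha = 0.025,
                             min_alpha = 0.0001, seed = 1L,
                             max_neighbors = 20L) {
  stopifnot(dimension >= 1, context_window >= 1, min_count >= 1,
            epochs >= 1, negative_samples >= 0, max_neighbors >= 1)
  structure(list(dimension = as.integer(dimension),
                 context_window = as.integer(context_window),
                 min_count = as.integer(min_count),
                 epochs = as.integer(epochs),
                 negative_samples = as.integer(negative_samples),
                 alpha = alpha, min_alpha = min_alpha,
                 seed = as.integer(seed),
                 max_neighbors = as.integer(max_neighbors)),
            class = "embedding_config")
}

#' Train skip-gram word embeddings on a cleaned corpus
#'
#' @param token_lists list of character vectors, one per post (e.g. the
#'   `tokens` column of a cleaned corpus)
#' @param cfg an [embedding_config()]
#' @return a `pain_embedding` object: `vocab` (character, ordered by corpus
#'   frequency descending, ties alphabetical), `vectors` (matrix, one row
#'   per vocabulary word) and the config used
#' @export
train_embeddings <- function(token_lists, cfg = embedding_config()) {
  stopifnot(is.list(token_lists), inherits(cfg, "embedding_config"))
  counts <- table(unlist(token_lists, use.names = FALSE))
  counts <- counts[counts >= cfg$min_count]
  if (length(counts) == 0L) {
    stop("empty vocabulary after min_count pruning; corpus too small",
         call. = FALSE)
  }
  ord <- order(-as.integer(counts), names(counts))
  vocab <- names(counts)[ord]
  vocab_counts <- as.integer(counts)[ord]
  index <- seq_along(vocab)
  names(index) <- vocab
  sentences <- lapply(token_lists, function(toks) {
    ids <- index[toks]
    as.integer(ids[!is.na(ids)]) - 1L # 0-based for C++
  })
  sentences <- sentences[lengths(sentences) > 0L]
  if (length(sentences) == 0L) {
    stop("no post retains any in-vocabulary token", call. = FALSE)
  }
  vec <- sgns_train_cpp(sentences, vocab_counts, cfg$dimension,
                        cfg$context_window, cfg$negative_samples,
                        cfg$epochs, cfg$alpha, cfg$min_alpha, cfg$seed)
  if (any(!is.finite(vec))) stop("non-finite embedding entries", call. = FALSE)
  rownames(vec) <- vocab
  structure(list(vocab = vocab, vectors = vec, config = cfg),
            class = "pain_embedding")
}

#' @export
print.pain_embedding <- function(x, ...) {
  cat(sprintf("<pain_embedding: %d words x %d dims>\n",
              length(x$vocab), ncol(x$vectors)))
  invisible(x)
}

#' Cosine similarity between two vocabulary words
#'
#' @param model a `pain_embedding`
#' @param w1,w2 vocabulary words
#' @return cosine similarity in \[-1, 1\]
#' @export
similarity <- function(model, w1, w2) {
  stopifnot(inherits(model, "pain_embedding"))
  for (w in c(w1, w2)) {
    if (!(w %in% model$vocab)) {
      stop(sprintf("word '%s' not in embedding vocabulary", w), call. = FALSE)
    }
  }
  a <- model$vectors[w1, ]; b <- model$vectors[w2, ]
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Extract associated words for a keyword
#'
#' Returns up to `cfg$max_neighbors` vocabulary words with strictly
#' positive cosine similarity to the keyword, ranked by similarity
#' descending (alphabetical tie-break), the keyword itself excluded. An
#' out-of-vocabulary keyword yields an empty result with a warning rather
#' than an error: rare keywords legitimately fall below `min_count`.
#'
#' @param model a `pain_embedding`
#' @param keyword query word
#' @param cfg an [embedding_config()] (only `max_neighbors` is used)
#' @return data.frame with columns keyword, word, similarity, rank
#' @export
associated_words <- function(model, keyword, cfg = embedding_config()) {
  stopifnot(inherits(model, "pain_embedding"))
  empty <- data.frame(keyword = character(0), word = character(0),
                      similarity = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE)
  if (!(keyword %in% model$vocab)) {
    warning(sprintf("keyword '%s' not in vocabulary (too rare in corpus?)",
                    keyword))
    return(empty)
  }
  q <- model$vectors[keyword, ]
  norms <- sqrt(rowSums(model$vectors^2))
  sims <- as.numeric(model$vectors %*% q) / (norms * sqrt(sum(q^2)))
  names(sims) <- model$vocab
  sims <- sims[names(sims) != keyword]
  sims <- sims[sims > 0] # positive-similarity rule
  if (length(sims) == 0L) return(empty)
  ord <- order(-sims, names(sims))
  sims <- sims[ord]
  n <- min(length(sims), cfg$max_neighbors)
  data.frame(keyword = keyword, word = names(sims)[seq_len(n)],
             similarity = as.numeric(sims[seq_len(n)]),
             rank = seq_len(n), stringsAsFactors = FALSE)
}

#' Prune association candidates by the three exclusion rules
#'
#' Removes candidates that (1) share a stem with any root descriptor
#' (`same_root`), (2) form a configured antonym pair with their keyword
#' (`contrast`, e.g. hot vs cold), or (3) sit on the configured stoplist of
#' words judged irrelevant to pain description (`irrelevant`). Order is
#' preserved and nothing is ever added.
#'
#' @param candidates data.frame from [associated_words()] (possibly several
#'   keywords row-bound)
#' @param root_descriptors character vector whose stems define the
#'   same-root rule
#' @param antonym_map data.frame with columns `keyword`, `word` listing
#'   contrasting pairs (direction-insensitive)
#' @param stoplist character vector of irrelevant words
#' @return list with `kept` (pruned candidate data.frame) and `log`
#'   (data.frame keyword, word, rule for each removal)
#' @export
prune_candidates <- function(candidates, root_descriptors,
                             antonym_map = NULL, stoplist = character(0)) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0L) {
    return(list(kept = candidates,
                log = data.frame(keyword = character(0), word = character(0),
                                 rule = character(0), stringsAsFactors = FALSE)))
  }
  root_stems <- unique(stem_words(unlist(lapply(root_descriptors,
                                                phrase_tokens))))
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  anto <- character(0)
  if (!is.null(antonym_map) && nrow(antonym_map) > 0L) {
    anto <- pair_key(tolower(antonym_map$keyword), tolower(antonym_map$word))
  }
  stoplist <- tolower(stoplist)
  rule <- rep(NA_character_, nrow(candidates))
  w <- tolower(candidates$word)
  k <- tolower(candidates$keyword)
  is_root <- stem_words(w) %in% root_stems
  rule[is_root] <- "same_root"
  is_anto <- is.na(rule) & pair_key(k, w) %in% anto
  rule[is_anto] <- "contrast"
  is_stop <- is.na(rule) & w %in% stoplist
  rule[is_stop] <- "irrelevant"
  keep <- is.na(rule)
  list(kept = candidates[keep, , drop = FALSE],
       log = data.frame(keyword = candidates$keyword[!keep],
                        word = candidates$word[!keep],
                        rule = rule[!keep], stringsAsFactors = FALSE))
}

#' Merge per-keyword candidates and tag provenance
#'
#' Deduplicates candidate words discovered under several keywords and tags
#' each with its provenance: discovered under original questionnaire
#' keywords only, under thesaurus-derived keywords only, or under both.
#' The three groups partition the deduplicated list.
#'
#' @param candidates data.frame with columns `keyword`, `word` (pruned
#'   candidates from all keywords)
#' @param mpq_keywords,thesaurus_keywords character vectors labelling each
#'   keyword's class; every candidate keyword must belong to exactly one
#' @return list with `words` (data.frame word, provenance) and `counts`
#'   (named integer: MPQ_only, thesaurus_only, both)
#' @export
merge_and_tag_provenance <- function(candidates, mpq_keywords,
                                     thesaurus_keywords) {
  stopifnot(is.data.frame(candidates))
  mpq_keywords <- tolower(mpq_keywords)
  thesaurus_keywords <- tolower(thesaurus_keywords)
  overlap <- intersect(mpq_keywords, thesaurus_keywords)
  if (length(overlap) > 0L) {
    stop(sprintf("keyword class labels overlap: %s",
                 paste(overlap, collapse = ", ")), call. = FALSE)
  }
  if (nrow(candidates) == 0L) {
    return(list(words = data.frame(word = character(0),
                                   provenance = character(0),
                                   stringsAsFactors = FALSE),
                counts = c(MPQ_only = 0L, thesaurus_only = 0L, both = 0L)))
  }
  k <- tolower(candidates$keyword)
  unk <- setdiff(unique(k), c(mpq_keywords, thesaurus_keywords))
  if (length(unk) > 0L) {
    stop(sprintf("keyword(s) with no class label: %s",
                 paste(unk, collapse = ", ")), call. = FALSE)
  }
  w <- tolower(candidates$word)
  from_mpq <- tapply(k %in% mpq_keywords, w, any)
  from_thes <- tapply(k %in% thesaurus_keywords, w, any)
  words <- names(from_mpq)
  prov <- ifelse(from_mpq & from_thes, "both",
                 ifelse(from_mpq, "MPQ_only", "thesaurus_only"))
  # preserve first-appearance order of words
  first <- match(unique(w), w)
  ordered_words <- w[first]
  prov <- prov[match(ordered_words, words)]
  out <- data.frame(word = ordered_words, provenance = as.character(prov),
                    stringsAsFactors = FALSE)
  counts <- c(MPQ_only = sum(out$provenance == "MPQ_only"),
              thesaurus_only = sum(out$provenance == "thesaurus_only"),
              both = sum(out$provenance == "both"))
  list(words = out, counts = counts)
}

# ---- embedding I/O ----------------------------------------------------------

#' Save an embedding in word2vec text format
#'
#' First line "vocab_size dimension", then one line per word: the word
#' followed by its vector components.
#'
#' @param model a `pain_embedding`
#' @param path output path
#' @return `path`, invisibly
#' @export
save_embedding <- function(model, path) {
  stopifnot(inherits(model, "pain_embedding"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(model$vocab), ncol(model$vectors)), con)
  for (i in seq_along(model$vocab)) {
    writeLines(paste(model$vocab[i],
                     paste(format(model$vectors[i, ], digits = 17,
                                  scientific = TRUE, trim = TRUE),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Load an embedding from word2vec text format
#' @param path input path
#' @return a `pain_embedding`
#' @export
load_embedding <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  v <- hdr[1]; d <- hdr[2]
  vocab <- character(v)
  vec <- matrix(0, nrow = v, ncol = d)
  for (i in seq_len(v)) {
    parts <- strsplit(lines[i + 1L], " ")[[1]]
    vocab[i] <- parts[1]
    vec[i, ] <- as.numeric(parts[-1])
  }
  rownames(vec) <- vocab
  structure(list(vocab = vocab, vectors = vec,
                 config = embedding_config(dimension = d)),
            class = "pain_embedding")
}

#' Write candidate tables as CSV
#' @param candidates candidate data.frame (any of the shapes produced by
#'   [associated_words()], [prune_candidates()] or
#'   [merge_and_tag_provenance()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_candidates_csv <- function(candidates, path) {
  utils::write.csv(candidates, path, row.names = FALSE)
  invisible(path)
}
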