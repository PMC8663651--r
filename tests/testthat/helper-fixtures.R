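# Shared test fixtures, all generated in code.

toy_lexicon <- function() {
  planted_lexicon(
    root_descriptors = c("stabbing", "burning", "aching"),
    associates = list(stabbing = c(puncturing = 0.5),
                      burning = c(slicing = 0.0)),
    conditions = c("migraine", "arthritis"),
    emotion_words = list(fear = c(terrified = 0.8),
                         sadness = c(heartbroken = 0.6),
                         joy = c(delighted = 0.7),
                         valence = c(awful = 0.2)),
    sarcasm_markers = c("yeah right", "totally fun"))
}

toy_config <- function(n = 500, seed = 101, ...) {
  corpus_config(n, lexicon = toy_lexicon(), seed = seed, ...)
}

toy_corpus <- function(n = 500, seed = 101, ...) {
  generate_corpus(toy_config(n, seed, ...))
}

# small hand-built corpus data.frame
posts_df <- function(texts, ids = sprintf("t%03d", seq_along(texts))) {
  data.frame(id = ids, platform = "twitter",
             timestamp = "2019-06-01T12:00:00Z", text = texts,
             stringsAsFactors = FALSE)
}

# independent BFS oracle (plain matrix Floyd-Warshall over an edge list)
floyd_warshall_oracle <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  if (nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      i <- edges$from[r]; j <- edges$to[r]
      d[i, j] <- 1; d[j, i] <- 1
    }
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    dk <- d[i, k] + d[k, ]
    lower <- dk < d[i, ]
    d[i, lower] <- dk[lower]
  }
  d
}

random_token_seq <- function(n_tokens, vocab_size, seed) {
  set.seed(seed)
  sprintf("v%02d", sample.int(vocab_size, n_tokens, replace = TRUE))
}

fixture_candidate_stats <- function(fx = revision_fixture()) {
  counts <- unlist(fx$counts)
  intens <- unlist(fx$intensities)
  data.frame(descriptor = names(counts), count = as.integer(counts),
             intensity = as.numeric(intens[names(counts)]),
             stringsAsFactors = FALSE)
}
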