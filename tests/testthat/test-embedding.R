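test_that("min_count prunes rare tokens; empty vocabulary errors", {
  toks <- c(rep(list(c("common", "words", "here")), 6), list(c("rare")))
  m <- train_embeddings(toks, embedding_config(dimension = 8, min_count = 5,
                                               epochs = 1))
  expect_setequal(m$vocab, c("common", "words", "here"))
  expect_false("rare" %in% m$vocab)
  expect_error(train_embeddings(list(c("a", "b")),
                                embedding_config(min_count = 5)),
               "vocabulary")
})

test_that("training is deterministic given the seed", {
  corp <- toy_corpus(300, seed = 5)
  cl <- clean_posts(corp$posts)
  cfg <- embedding_config(dimension = 16, epochs = 2, seed = 9)
  m1 <- train_embeddings(cl$tokens, cfg)
  m2 <- train_embeddings(cl$tokens, cfg)
  expect_identical(m1$vocab, m2$vocab)
  expect_identical(m1$vectors, m2$vectors)
  nb1 <- associated_words(m1, "pain", cfg)
  nb2 <- associated_words(m2, "pain", cfg)
  expect_identical(nb1, nb2)
  # a different seed changes the vectors
  m3 <- train_embeddings(cl$tokens,
                         embedding_config(dimension = 16, epochs = 2,
                                          seed = 10))
  expect_false(identical(m1$vectors, m3$vectors))
})

test_that("similarity is cosine: identity, orthogonality, hand computation", {
  vec <- rbind(a = c(1, 0), b = c(0, 1), c = c(3, 4), d = c(6, 8))
  m <- structure(list(vocab = rownames(vec), vectors = vec,
                      config = embedding_config(dimension = 2)),
                 class = "pain_embedding")
  expect_equal(similarity(m, "a", "a"), 1.0)
  expect_equal(similarity(m, "a", "b"), 0.0)
  expect_equal(similarity(m, "c", "d"), 1.0)
  expect_equal(similarity(m, "a", "c"), 3 / 5) # hand: (3)/(1*5)
  expect_error(similarity(m, "a", "zzz"), "zzz")
})

test_that("associated_words: positive-similarity rule, cap, brute force", {
  # all-opposed vectors give an empty list
  vec <- rbind(q = c(1, 0), x = c(-1, 0), y = c(0, 1), z = c(-0.5, 0))
  m <- structure(list(vocab = rownames(vec), vectors = vec,
                      config = embedding_config(dimension = 2)),
                 class = "pain_embedding")
  res <- associated_words(m, "q", embedding_config(max_neighbors = 20))
  expect_identical(res$word, character(0))
  expect_warning(associated_words(m, "missing"), "vocabulary")

  # brute-force oracle on a random 150-word model; 25+ positive sims cap at 20
  set.seed(42)
  v <- matrix(rnorm(150 * 10), nrow = 150)
  rownames(v) <- sprintf("word%03d", 1:150)
  m2 <- structure(list(vocab = rownames(v), vectors = v,
                       config = embedding_config(dimension = 10)),
                  class = "pain_embedding")
  cfg <- embedding_config(max_neighbors = 20)
  for (kw in c("word001", "word077", "word150")) {
    got <- associated_words(m2, kw, cfg)
    # independent brute force: plain loops over the vocabulary
    sims <- vapply(rownames(v), function(w) {
      a <- v[kw, ]; b <- v[w, ]
      sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }, numeric(1))
    sims <- sims[names(sims) != kw]
    sims <- sort(sims[sims > 0], decreasing = TRUE)
    want <- head(names(sims), 20)
    expect_identical(got$word, want)
    expect_identical(got$rank, seq_along(want))
    expect_true(all(diff(got$similarity) <= 0))
    expect_false(kw %in% got$word)
    expect_false(anyDuplicated(got$word) > 0)
  }
})

test_that("planted associate is recovered as a top-20 neighbour", {
  # single-run version of the recovery contract (the 50-run Monte Carlo
  # lives in the acceptance suite)
  lex <- planted_lexicon(
    root_descriptors = c("stabbing", "burning", "aching"),
    associates = list(stabbing = c(puncturing = 0.9, slicing = 0.0)),
    conditions = "migraine", sarcasm_markers = "yeah right")
  corp <- generate_corpus(corpus_config(4000, lexicon = lex, seed = 314))
  cl <- clean_posts(corp$posts)
  cfg <- embedding_config(dimension = 24, epochs = 15, context_window = 1,
                          seed = 315)
  m <- train_embeddings(cl$tokens, cfg)
  nb <- associated_words(m, "stabbing", cfg)
  expect_true("puncturing" %in% nb$word)
  expect_false("slicing" %in% m$vocab) # propensity 0 never appears
})

test_that("pruning applies the three rules with a removal log", {
  cand <- data.frame(
    keyword = c("burn", "hot", "sharp", "sharp", "dull"),
    word = c("burning", "cold", "keen", "paperwork", "blunt"),
    similarity = c(0.9, 0.8, 0.7, 0.6, 0.5),
    rank = c(1L, 1L, 1L, 2L, 1L), stringsAsFactors = FALSE)
  anto <- data.frame(keyword = "hot", word = "cold",
                     stringsAsFactors = FALSE)
  res <- prune_candidates(cand, root_descriptors = c("burn", "sharp", "dull"),
                          antonym_map = anto, stoplist = "paperwork")
  expect_identical(res$kept$word, c("keen", "blunt"))
  expect_identical(res$log$rule[res$log$word == "burning"], "same_root")
  expect_identical(res$log$rule[res$log$word == "cold"], "contrast")
  expect_identical(res$log$rule[res$log$word == "paperwork"], "irrelevant")
  # identity case: nothing to prune
  res2 <- prune_candidates(cand[3:5, ], root_descriptors = "unrelatedroot")
  expect_identical(res2$kept, cand[3:5, ])
  # order-preserving, never adds
  expect_true(all(res$kept$word %in% cand$word))
})

test_that("provenance tagging partitions the deduplicated words", {
  cand <- data.frame(
    keyword = c("sharp", "ache", "sharp", "twinge", "dull"),
    word = c("keen", "keen", "pointy", "spasmy", "blunt"),
    stringsAsFactors = FALSE)
  res <- merge_and_tag_provenance(cand, mpq_keywords = c("sharp", "dull"),
                                  thesaurus_keywords = c("ache", "twinge"))
  got <- setNames(res$words$provenance, res$words$word)
  expect_identical(got[["keen"]], "both")
  expect_identical(got[["pointy"]], "MPQ_only")
  expect_identical(got[["spasmy"]], "thesaurus_only")
  expect_identical(sum(res$counts), nrow(res$words))
  # conservation on random inputs
  set.seed(8)
  for (i in 1:10) {
    kws <- sprintf("k%02d", 1:10)
    cand <- data.frame(keyword = sample(kws, 40, replace = TRUE),
                       word = sprintf("w%02d", sample.int(15, 40, TRUE)),
                       stringsAsFactors = FALSE)
    res <- merge_and_tag_provenance(cand, kws[1:5], kws[6:10])
    expect_identical(unname(sum(res$counts)), nrow(res$words))
    expect_identical(nrow(res$words), length(unique(cand$word)))
  }
  expect_error(merge_and_tag_provenance(cand, "k01", "k01"), "overlap")
})

test_that("embedding save/load round trip preserves neighbours", {
  corp <- toy_corpus(200, seed = 55)
  cl <- clean_posts(corp$posts)
  cfg <- embedding_config(dimension = 8, epochs = 2, seed = 1)
  m <- train_embeddings(cl$tokens, cfg)
  f <- withr::local_tempfile(fileext = ".txt")
  save_embedding(m, f)
  m2 <- load_embedding(f)
  expect_identical(m2$vocab, m$vocab)
  expect_equal(m2$vectors, m$vectors, tolerance = 1e-12)
  expect_identical(associated_words(m2, "pain", cfg)$word,
                   associated_words(m, "pain", cfg)$word)
})
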