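test_that("clean_text applies the removal rules", {
  expect_identical(clean_text("@bob my back pain is UNBEARABLE http://t.co/x"),
                   c("my", "back", "pain", "is", "unbearable"))
  expect_identical(clean_text(""), character(0))
  expect_identical(clean_text("   "), character(0))
  expect_identical(clean_text("#chronicpain flare :( !!!"),
                   c("chronicpain", "flare"))
  expect_identical(clean_text("see www.example.com and t.co/abc now"),
                   c("see", "and", "now"))
})

test_that("clean_text is idempotent and strips all mentions/URLs", {
  corp <- toy_corpus(1000, seed = 7, p_username = 0.8, p_url = 0.8)
  for (i in seq_len(nrow(corp$posts))) {
    toks <- clean_text(corp$posts$text[i])
    expect_false(any(startsWith(toks, "@")))
    expect_false(any(grepl("^(https?://|www\\.|t\\.co/)", toks)))
    expect_false(any(toks == ""))
    # idempotence
    expect_identical(clean_text(paste(toks, collapse = " ")), toks)
  }
})

test_that("round-1 filter: pain plus descriptor within hop limit", {
  cfg <- filter_config(descriptor_list = c("sharp", "stabbing"))
  expect_true(relevance_filter_round1(c("pain", "is", "sharp"), cfg))
  expect_false(relevance_filter_round1(c("sharp", "knife"), cfg))
  expect_false(relevance_filter_round1(c("pain", "a", "b", "c", "sharp"), cfg))
  expect_true(relevance_filter_round1(c("pain", "a", "b", "sharp"), cfg))
  # hop limit -> infinity reduces to co-occurrence
  cfg_inf <- filter_config(descriptor_list = "sharp", hop_limit = 10000)
  expect_true(relevance_filter_round1(c("pain", "a", "b", "c", "sharp"),
                                      cfg_inf))
})

test_that("round-1 filter matches a brute-force BFS oracle on 500 posts", {
  corp <- toy_corpus(500, seed = 31)
  cl <- clean_posts(corp$posts)
  lex <- toy_lexicon()
  cfg <- filter_config(descriptor_list = lex$root_descriptors)
  for (i in seq_len(nrow(cl))) {
    toks <- cl$tokens[[i]]
    got <- relevance_filter_round1(toks, cfg)
    # oracle: Floyd-Warshall over the same graph definition
    want <- FALSE
    if ("pain" %in% toks) {
      g <- build_word_graph(toks)
      d <- floyd_warshall_oracle(g$nodes, graph_edges(g))
      for (dsc in lex$root_descriptors) {
        if (dsc %in% toks && d["pain", dsc] <= 3) want <- TRUE
      }
    }
    expect_identical(got, want)
  }
  # filter decisions recover the generator's hidden relevance labels
  got_all <- vapply(cl$tokens, relevance_filter_round1, logical(1), cfg = cfg)
  expect_identical(got_all, corp$labels$relevant)
})

test_that("round-2 filter needs both a descriptor and a condition", {
  cfg <- filter_config(descriptor_list = "excruciating",
                       condition_list = "migraine")
  expect_true(relevance_filter_round2(
    c("my", "migraine", "is", "excruciating"), cfg))
  expect_false(relevance_filter_round2(
    c("excruciating", "wait", "at", "the", "dmv"), cfg))
  # phrase-aware conditions
  cfg2 <- filter_config(descriptor_list = "sharp",
                        condition_list = "back pain")
  expect_true(relevance_filter_round2(c("sharp", "back", "pain"), cfg2))
  expect_false(relevance_filter_round2(c("sharp", "pain", "back"), cfg2))
})

test_that("round-2 kept fraction matches the analytic expectation", {
  n <- 10000
  corp <- toy_corpus(n, seed = 77)
  cl <- clean_posts(corp$posts)
  lex <- toy_lexicon()
  cfg <- filter_config(descriptor_list = lex$root_descriptors,
                       condition_list = lex$conditions)
  kept <- sum(vapply(cl$tokens, relevance_filter_round2, logical(1),
                     cfg = cfg))
  # descriptor always present in relevant posts; condition with p_condition
  p <- 0.35 * 0.5
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(kept / n - p), 3 * se + 1e-9)
})

test_that("manual exclusions partition the corpus and log patterns", {
  posts <- posts_df(c("aaa", "bbb", "ccc", "ddd"))
  cfg0 <- filter_config()
  res0 <- apply_manual_exclusions(posts, cfg0)
  expect_identical(res0$kept$id, posts$id)
  expect_identical(nrow(res0$removed), 0L)

  cfg1 <- filter_config(manual_exclusions = "^t002$")
  res1 <- apply_manual_exclusions(posts, cfg1)
  expect_identical(res1$removed$id, "t002")
  expect_identical(res1$log$pattern, "^t002$")

  cfg_bad <- filter_config(manual_exclusions = "([")
  expect_error(apply_manual_exclusions(posts, cfg_bad), "malformed")

  # property: partition, disjoint, order-preserving
  for (seed in 1:5) {
    corp <- toy_corpus(60, seed = seed)
    cfg <- filter_config(manual_exclusions = c("3$", "7$"))
    res <- apply_manual_exclusions(corp$posts, cfg)
    expect_identical(sort(c(res$kept$id, res$removed$id)),
                     sort(corp$posts$id))
    expect_length(intersect(res$kept$id, res$removed$id), 0)
    expect_identical(res$kept$id,
                     corp$posts$id[corp$posts$id %in% res$kept$id])
  }
})

test_that("JSONL round trip preserves posts byte for byte", {
  corp <- toy_corpus(40, seed = 5)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_posts_jsonl(corp$posts, f1)
  back <- read_posts_jsonl(f1)
  expect_identical(back, corp$posts)
  write_posts_jsonl(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # CSV round trip
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_posts_csv(corp$posts, f3)
  expect_identical(read_posts_csv(f3), corp$posts)
})

test_that("stage manifests enforce conservation", {
  m <- stage_manifest("clean", 100, 90, c(noise = 10))
  expect_identical(m$n_removed, 10L)
  expect_error(stage_manifest("x", 10, 12), "exceeds")
  expect_error(stage_manifest("x", 10, 8, c(a = 1)), "breakdown")
})
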