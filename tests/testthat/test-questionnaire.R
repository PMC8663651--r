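test_that("bundled questionnaire has 20 subclasses and 78 descriptors", {
  q <- mpq_questionnaire()
  expect_length(q$subclasses, 20)
  expect_length(all_descriptors(q), 78)
  expect_false(anyDuplicated(all_descriptors(q)) > 0)
})

test_that("count_descriptors is post-level and phrase-aware", {
  posts <- posts_df(c("sharp sharp sharp", "dull and sharp",
                      "i feel hopeless today", "hopeless feel"))
  posts <- clean_posts(posts)
  cnt <- count_descriptors(posts, c("sharp", "feel hopeless", "absent"))
  expect_identical(cnt[["sharp"]], 2L)        # twice in one post counts once
  expect_identical(cnt[["feel hopeless"]], 1L) # consecutive only
  expect_identical(cnt[["absent"]], 0L)
})

test_that("counts on a generated corpus match expected_counts (3 SE)", {
  n <- 10000
  corp <- toy_corpus(n, seed = 606)
  cl <- clean_posts(corp$posts)
  words <- c("pain", "stabbing", "puncturing", "migraine")
  got <- count_descriptors(cl, words)
  want <- expected_counts(toy_config(n), words)
  for (w in words) {
    p <- want[[w]] / n
    se <- sqrt(p * (1 - p) * n)
    expect_lt(abs(got[[w]] - want[[w]]), 3 * se)
  }
})

test_that("derive_threshold: worked example, ceiling rule, degeneracies", {
  # 78 counts where the 8 lowest are <110 and the 9th lowest is 110
  fx <- revision_fixture()
  counts <- unlist(fx$counts)[all_descriptors(mpq_questionnaire())]
  thr <- derive_threshold(counts, decile = 0.10)
  expect_identical(thr$threshold, 110L)
  expect_length(thr$bottom_set, 8)
  expect_setequal(thr$bottom_set, unlist(fx$low_use_removed))

  # all-tied input: warning and threshold = count + 1
  tied <- setNames(rep(5, 10), letters[1:10])
  expect_warning(res <- derive_threshold(tied), "tied")
  expect_identical(res$threshold, 6L)
  expect_length(res$bottom_set, 0)
  expect_error(derive_threshold(numeric(0)), "non-empty")
})

test_that("derive_threshold agrees with a brute-force sort oracle", {
  set.seed(99)
  for (i in 1:400) {
    n <- sample(5:200, 1)
    counts <- setNames(sample.int(10000, n, replace = TRUE),
                       sprintf("d%03d", seq_len(n)))
    if (length(unique(counts)) == 1L) next
    decile <- 0.10
    thr <- derive_threshold(counts, decile)
    # oracle: brute-force sort
    k <- ceiling(decile * n)
    sorted <- sort(counts) # ties: names order irrelevant for count logic
    boundary <- unname(sorted[k])
    bottom_counts <- counts[counts <= boundary]
    above <- counts[counts > boundary]
    want_thr <- if (length(above)) min(above) else boundary + 1
    expect_identical(thr$threshold, as.integer(want_thr))
    expect_setequal(thr$bottom_set, names(bottom_counts))
    # distinct counts: exactly ceil(decile * n) fall below the threshold
    if (!anyDuplicated(counts)) {
      expect_identical(sum(counts < thr$threshold), as.integer(k))
    }
  }
})

test_that("removal rules: fixture yields 11 removals; set algebra holds", {
  fx <- revision_fixture()
  orig <- mpq_questionnaire()
  counts <- unlist(fx$counts)
  rules <- fixture_revision_rules()
  rem <- apply_removal_rules(orig, counts, 110, rules)
  expect_identical(nrow(rem$removals), 11L)
  expect_setequal(rem$removals$descriptor[rem$removals$rule == "low_use"],
                  unlist(fx$low_use_removed))
  expect_setequal(rem$removals$descriptor[rem$removals$rule == "context"],
                  c("beating", "punishing", "drawing"))
  # survivors + removals partition the original descriptors
  expect_setequal(c(all_descriptors(rem$survivors), rem$removals$descriptor),
                  all_descriptors(orig))
  expect_length(intersect(all_descriptors(rem$survivors),
                          rem$removals$descriptor), 0)
  # no removals when nothing is low and no context list
  hi <- setNames(rep(1000, 78), all_descriptors(orig))
  rem2 <- apply_removal_rules(orig, hi, 110, revision_rules())
  expect_identical(nrow(rem2$removals), 0L)
  # unknown context descriptor errors
  bad <- revision_rules(context_removals = data.frame(
    descriptor = "notaword", reason = "x"))
  expect_error(apply_removal_rules(orig, counts, 110, bad), "unknown")
})

test_that("addition rules enforce the prevalence precondition", {
  stats <- fixture_candidate_stats()
  rules <- fixture_revision_rules()
  add <- apply_addition_rules(stats, 110, rules)
  expect_identical(nrow(add), 13L)
  expect_true(all(add$count >= 110))
  expect_identical(nrow(apply_addition_rules(stats, 110, revision_rules())),
                   0L)
  # a below-threshold assignment errors
  stats_low <- stats
  stats_low$count[stats_low$descriptor == "puncturing"] <- 50L
  expect_error(apply_addition_rules(stats_low, 110, rules),
               "prevalence violation")
})

test_that("psychological subclass: selection, envelope, empties", {
  fx <- revision_fixture()
  stats <- fixture_candidate_stats()
  rules <- fixture_revision_rules()
  ps <- build_psychological_subclass(stats, rules,
                                     envelope = fx$psychological_envelope)
  expect_identical(ps$descriptors,
                   c("worried", "angry", "fearful", "sad", "depressed",
                     "nervous", "anxious", "feel hopeless", "suicidal"))
  expect_warning(build_psychological_subclass(stats, revision_rules()),
                 "empty")
  # out-of-envelope intensity triggers a validation warning
  stats_bad <- stats
  stats_bad$intensity[stats_bad$descriptor == "worried"] <- 0.9
  expect_warning(build_psychological_subclass(
    stats_bad, rules, envelope = fx$psychological_envelope), "envelope")
  expect_error(build_psychological_subclass(
    stats[stats$descriptor != "worried", ], rules), "missing")
})

test_that("reorder_subclass: stability, direction, reference sort", {
  intens <- c(cutting = 0.45, sharp = 0.49)
  ro <- reorder_subclass(c("sharp", "cutting"), intens)
  expect_identical(ro$ordered, c("cutting", "sharp"))
  expect_true(ro$changed)
  ro2 <- reorder_subclass(c("cutting", "sharp"), intens)
  expect_false(ro2$changed)
  expect_error(reorder_subclass(c("a", "b"), c(a = 0.5)), "b")
  # ties preserve input order
  ro3 <- reorder_subclass(c("x", "y", "z"), c(x = 0.5, y = 0.5, z = 0.1))
  expect_identical(ro3$ordered, c("z", "x", "y"))
  # random vectors: equals a reference stable sort, both directions
  set.seed(123)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    vals <- setNames(round(runif(n), 2), sprintf("w%02d", seq_len(n)))
    descs <- sample(names(vals))
    up <- reorder_subclass(descs, vals, "ascending")
    expect_identical(up$ordered, descs[order(vals[descs])])
    down <- reorder_subclass(descs, vals, "descending")
    expect_identical(down$ordered, descs[order(-vals[descs])])
  }
})

test_that("full revision reproduces the bundled suggested questionnaire", {
  fx <- revision_fixture()
  orig <- mpq_questionnaire()
  counts <- unlist(fx$counts)
  intens <- unlist(fx$intensities)
  res <- revise_questionnaire(orig, counts[all_descriptors(orig)],
                              fixture_candidate_stats(), intens,
                              fixture_revision_rules(),
                              envelope = fx$psychological_envelope)
  expect_identical(res$report$threshold_used, 110L)
  expect_identical(nrow(res$report$removed), 11L)
  expect_identical(nrow(res$report$added), 13L)
  expect_identical(res$report$new_subclasses, "Psychological")
  expect_length(res$report$reordered_subclasses, 6)
  # descriptor-for-descriptor, order-for-order agreement, plus flags
  got_by_name <- setNames(res$revised$subclasses,
                          vapply(res$revised$subclasses, `[[`, "", "name"))
  for (e in fx$suggested_questionnaire) {
    g <- got_by_name[[e$name]]
    expect_false(is.null(g))
    expect_identical(g$descriptors, unlist(e$descriptors))
    if (!is.null(e$reordered) && !is.na(e$reordered)) {
      expect_identical(e$name %in% res$report$reordered_subclasses,
                       e$reordered)
    }
  }
})

test_that("no-op assembly returns the original questionnaire", {
  orig <- mpq_questionnaire()
  # intensities already consistent with the current within-subclass order
  intens <- unlist(lapply(orig$subclasses, function(s)
    setNames(seq(0.1, 0.9, length.out = length(s$descriptors)),
             s$descriptors)))
  no_rem <- data.frame(descriptor = character(0), subclass = character(0),
                       rule = character(0), stringsAsFactors = FALSE)
  no_add <- data.frame(word = character(0), subclass = character(0),
                       count = integer(0), stringsAsFactors = FALSE)
  res <- assemble_and_report(orig, orig, no_rem, no_add, NULL, intens,
                             revision_rules(), threshold = 1L)
  expect_identical(lapply(res$revised$subclasses, `[[`, "descriptors"),
                   lapply(orig$subclasses, `[[`, "descriptors"))
  expect_identical(nrow(res$report$removed), 0L)
  expect_length(res$report$reordered_subclasses, 0)
})

test_that("conservation holds on random revision scenarios", {
  orig <- mpq_questionnaire()
  desc <- all_descriptors(orig)
  set.seed(77)
  for (i in 1:15) {
    counts <- setNames(sample.int(5000, 78) + 200L, desc) # all above bar
    drop_ctx <- sample(desc, sample(0:4, 1))
    ctx <- if (length(drop_ctx)) data.frame(descriptor = drop_ctx,
                                            reason = "ctx") else NULL
    intens <- setNames(runif(78), desc)
    rules <- revision_rules(context_removals = ctx)
    stats <- data.frame(descriptor = desc, count = counts,
                        intensity = intens, stringsAsFactors = FALSE)
    res <- revise_questionnaire(orig, counts, stats, intens, rules)
    thr <- derive_threshold(counts, 0.10)
    n_low <- sum(counts < thr$threshold)
    expect_identical(length(all_descriptors(res$revised)),
                     78L - nrow(res$report$removed))
  }
})

test_that("questionnaire JSON round trip and duplicate detection", {
  q <- mpq_questionnaire()
  f <- withr::local_tempfile(fileext = ".json")
  write_questionnaire_json(q, f)
  q2 <- read_questionnaire_json(f)
  expect_identical(lapply(q2$subclasses, `[[`, "descriptors"),
                   lapply(q$subclasses, `[[`, "descriptors"))
  expect_error(questionnaire(list(list(name = "X", class_label = "sensory",
                                       descriptors = c("a", "a")))),
               "duplicate")
  md <- render_questionnaire_md(q)
  expect_true(any(grepl("^## Temporal", md)))
})
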