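#' Round 1: gather, clean, filter, de-sarcasm, embed, associate, prune
#'
#' Executes the preliminary half of the two-round workflow on an in-memory
#' corpus: cleaning, the hop-limited "pain within k hops of a descriptor"
#' relevance filter, sarcasm removal, embedding training, per-keyword
#' neighbour extraction and pruning, and provenance tagging. Keywords are
#' supplied in two classes (original questionnaire vs thesaurus-derived) so
#' discovered candidates can be attributed to either or both.
#'
#' @param posts corpus data.frame (id, platform, timestamp, text)
#' @param mpq_keywords,thesaurus_keywords the two keyword classes
#' @param filter_cfg a [filter_config()] (descriptor_list defaults to the
#'   union of the keyword classes when empty)
#' @param sarcasm_cfg a [sarcasm_config()]
#' @param embed_cfg an [embedding_config()]
#' @param antonym_map,stoplist passed to [prune_candidates()]
#' @return list: `kept` (surviving posts), `candidates` (data.frame word,
#'   provenance), `candidate_table` (per-keyword rows with similarities),
#'   `prune_log`, `provenance_counts`, `model`, `manifest` (list of
#'   [stage_manifest()] entries)
#' @export
run_round1 <- function(posts, mpq_keywords, thesaurus_keywords = character(0),
                       filter_cfg = NULL, sarcasm_cfg = sarcasm_config(),
                       embed_cfg = embedding_config(),
                       antonym_map = NULL, stoplist = character(0)) {
  mpq_keywords <- tolower(mpq_keywords)
  thesaurus_keywords <- tolower(thesaurus_keywords)
  keywords <- unique(c(mpq_keywords, thesaurus_keywords))
  if (is.null(filter_cfg)) filter_cfg <- filter_config(descriptor_list = keywords)
  if (length(filter_cfg$descriptor_list) == 0L) {
    filter_cfg$descriptor_list <- keywords
  }
  manifest <- list()
  in_hash <- object_hash(posts$id)

  cleaned <- clean_posts(posts)
  manifest$clean <- stage_manifest("clean", nrow(posts), nrow(cleaned),
                                   input_hash = in_hash)

  rel <- vapply(cleaned$tokens, relevance_filter_round1, logical(1),
                cfg = filter_cfg)
  kept1 <- cleaned[rel, , drop = FALSE]
  manifest$relevance <- stage_manifest(
    "relevance_round1", nrow(cleaned), nrow(kept1),
    rule_breakdown = c(no_pain_within_hops = nrow(cleaned) - nrow(kept1)),
    input_hash = object_hash(cleaned$id))
  if (nrow(kept1) == 0L) {
    stop("empty pipeline: no post passed the round-1 relevance filter ",
         "(does the corpus mention 'pain'?)", call. = FALSE)
  }

  sar <- filter_sarcastic(kept1, sarcasm_cfg)
  manifest$sarcasm <- stage_manifest(
    "sarcasm", nrow(kept1), nrow(sar$kept),
    rule_breakdown = c(sarcastic = nrow(kept1) - nrow(sar$kept)),
    input_hash = object_hash(kept1$id))
  if (nrow(sar$kept) == 0L) {
    stop("empty pipeline: every relevant post was removed as sarcastic",
         call. = FALSE)
  }

  model <- train_embeddings(sar$kept$tokens, embed_cfg)
  cand_rows <- list()
  for (kw in keywords) {
    if (kw %in% model$vocab) {
      cand_rows[[kw]] <- associated_words(model, kw, embed_cfg)
    }
  }
  cand <- if (length(cand_rows) > 0L) do.call(rbind, cand_rows) else
    data.frame(keyword = character(0), word = character(0),
               similarity = numeric(0), rank = integer(0),
               stringsAsFactors = FALSE)
  pruned <- prune_candidates(cand, root_descriptors = keywords,
                             antonym_map = antonym_map, stoplist = stoplist)
  prov <- merge_and_tag_provenance(pruned$kept, mpq_keywords,
                                   thesaurus_keywords)
  list(kept = sar$kept, candidates = prov$words,
       candidate_table = pruned$kept, prune_log = pruned$log,
       provenance_counts = prov$counts, model = model,
       manifest = manifest)
}

#' Round 2: refilter with the expanded list, score, count, revise
#'
#' Executes the final half of the workflow: cleaning, the
#' descriptor-plus-condition relevance filter, sarcasm removal,
#' per-descriptor counting and intensity scoring, and the questionnaire
#' revision.
#'
#' @param posts corpus data.frame for the second gathering round
#' @param expanded_descriptors original descriptors plus round-1 candidates
#' @param conditions pain-condition list (must be non-empty)
#' @param original the original `questionnaire`
#' @param rules a [revision_rules()]
#' @param lexicon an [emotion_lexicon()] for intensity scoring
#' @param filter_cfg optional [filter_config()]; built from the descriptor
#'   and condition lists when NULL
#' @param sarcasm_cfg a [sarcasm_config()]
#' @param intensity_mode passed to [pain_intensity()]
#' @return list: `final` (posts), `stats` (descriptor, count, intensity),
#'   `revised`, `report`, `manifest`
#' @export
run_round2 <- function(posts, expanded_descriptors, conditions, original,
                       rules, lexicon,
                       filter_cfg = NULL, sarcasm_cfg = sarcasm_config(),
                       intensity_mode = "neg_max") {
  if (length(conditions) == 0L) {
    stop("empty condition list: the round-2 filter would reject every post; ",
         "configure `conditions`", call. = FALSE)
  }
  expanded_descriptors <- tolower(expanded_descriptors)
  if (is.null(filter_cfg)) {
    filter_cfg <- filter_config(descriptor_list = expanded_descriptors,
                                condition_list = tolower(conditions))
  }
  manifest <- list()
  cleaned <- clean_posts(posts)
  manifest$clean <- stage_manifest("clean", nrow(posts), nrow(cleaned),
                                   input_hash = object_hash(posts$id))
  rel <- vapply(cleaned$tokens, relevance_filter_round2, logical(1),
                cfg = filter_cfg)
  kept <- cleaned[rel, , drop = FALSE]
  manifest$relevance <- stage_manifest(
    "relevance_round2", nrow(cleaned), nrow(kept),
    rule_breakdown = c(no_descriptor_and_condition = nrow(cleaned) - nrow(kept)),
    input_hash = object_hash(cleaned$id))
  if (nrow(kept) == 0L) {
    stop("empty pipeline: no post contains both a descriptor and a condition",
         call. = FALSE)
  }
  sar <- filter_sarcastic(kept, sarcasm_cfg)
  manifest$sarcasm <- stage_manifest(
    "sarcasm", nrow(kept), nrow(sar$kept),
    rule_breakdown = c(sarcastic = nrow(kept) - nrow(sar$kept)),
    input_hash = object_hash(kept$id))
  final <- sar$kept

  orig_desc <- all_descriptors(original)
  all_words <- unique(c(orig_desc, expanded_descriptors,
                        rules$psychological_selection))
  stats <- descriptor_stats(final, all_words, lexicon, mode = intensity_mode)

  original_counts <- stats$count[match(orig_desc, stats$descriptor)]
  names(original_counts) <- orig_desc
  intensities <- stats$intensity
  names(intensities) <- stats$descriptor
  intensities[is.na(intensities)] <- 0 # unseen words sort lowest

  revision <- revise_questionnaire(original, original_counts,
                                   candidate_stats = stats,
                                   intensities = intensities, rules = rules)
  list(final = final, stats = stats, revised = revision$revised,
       report = revision$report, manifest = manifest)
}
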