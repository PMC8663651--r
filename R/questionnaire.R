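#' Construct a questionnaire
#'
#' A questionnaire is an ordered list of subclasses, each with a name, a
#' class label (sensory, affective, evaluative, supplementary or
#' psychological) and an ordered descriptor list. Within a subclass no
#' descriptor may repeat; descriptors are ranked by the pain intensity they
#' connote.
#'
#' @param subclasses list of lists with fields `name`, `class_label`,
#'   `descriptors`
#' @return a `questionnaire` object
#' @export
questionnaire <- function(subclasses) {
  labels <- c("sensory", "affective", "evaluative", "supplementary",
              "psychological")
  subclasses <- lapply(subclasses, function(s) {
    s$descriptors <- as.character(unlist(s$descriptors))
    s
  })
  for (s in subclasses) {
    stopifnot(is.character(s$name), nzchar(s$name),
              s$class_label %in% labels)
    if (anyDuplicated(s$descriptors)) {
      stop(sprintf("duplicate descriptor within subclass '%s'", s$name),
           call. = FALSE)
    }
  }
  if (anyDuplicated(vapply(subclasses, `[[`, character(1), "name"))) {
    stop("duplicate subclass names", call. = FALSE)
  }
  structure(list(subclasses = subclasses), class = "questionnaire")
}

#' @export
print.questionnaire <- function(x, ...) {
  cat(sprintf("<questionnaire: %d subclasses, %d descriptors>\n",
              length(x$subclasses), length(all_descriptors(x))))
  invisible(x)
}

#' All descriptors of a questionnaire, in subclass order
#' @param q a `questionnaire`
#' @return character vector (a descriptor present in two subclasses appears
#'   twice)
#' @export
all_descriptors <- function(q) {
  stopifnot(inherits(q, "questionnaire"))
  unlist(lapply(q$subclasses, `[[`, "descriptors"), use.names = FALSE)
}

#' The bundled original multidimensional pain questionnaire
#'
#' Loads the package's copy of the classic 78-descriptor, 20-subclass pain
#' questionnaire. Its structure is validated on load: exactly 20 subclasses
#' and 78 descriptors.
#' @return a `questionnaire`
#' @export
mpq_questionnaire <- function() {
  path <- system.file("extdata", "mpq_original.json", package = "painlex",
                      mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  q <- questionnaire(raw$subclasses)
  stopifnot(length(q$subclasses) == 20L, length(all_descriptors(q)) == 78L)
  q
}

#' The bundled revision fixture
#'
#' A complete reference scenario for the revision engine: per-descriptor
#' counts and intensities (reported prevalence values mixed with synthetic
#' fill-ins; see its `value_source` field), the configured context
#' removals, subclass assignments for new words, the psychological
#' selection, and the expected revised questionnaire. Used to test the
#' revision engine independently of any corpus or scorer.
#' @return a list (see the fixture's `comment` field)
#' @export
revision_fixture <- function() {
  path <- system.file("extdata", "revision_fixture.json", package = "painlex",
                      mustWork = TRUE)
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Revision rule configuration
#'
#' @param decile fraction of lowest-count original descriptors defining the
#'   prevalence threshold (default 0.10)
#' @param context_removals data.frame (descriptor, reason) of words removed
#'   because their usage context drifted away from pain description; a
#'   human judgment supplied as configuration
#' @param additions_assignment data.frame (word, subclass) placing new
#'   descriptors into subclasses
#' @param psychological_selection ordered character vector for the new
#'   psychological subclass
#' @param sentence_frame completion frame the psychological words fit
#'   (default "My pain makes me ___")
#' @param reorder_direction "ascending" (default) or "descending" intensity
#'   within each subclass
#' @return a `revision_rules` list
#' @export
revision_rules <- function(decile = 0.10,
                           context_removals = NULL,
                           additions_assignment = NULL,
                           psychological_selection = character(0),
                           sentence_frame = "My pain makes me ___",
                           reorder_direction = c("ascending", "descending")) {
  stopifnot(decile > 0, decile < 1)
  reorder_direction <- match.arg(reorder_direction)
  structure(list(decile = decile,
                 context_removals = context_removals,
                 additions_assignment = additions_assignment,
                 psychological_selection = tolower(psychological_selection),
                 sentence_frame = sentence_frame,
                 reorder_direction = reorder_direction),
            class = "revision_rules")
}

#' Revision rules preloaded from the bundled fixture
#' @return a `revision_rules` with the fixture's removals, assignments and
#'   psychological selection
#' @export
fixture_revision_rules <- function() {
  fx <- revision_fixture()
  ctx <- do.call(rbind, lapply(fx$context_removals, function(x)
    data.frame(descriptor = x$descriptor, reason = x$reason,
               stringsAsFactors = FALSE)))
  add <- do.call(rbind, lapply(fx$additions, function(x)
    data.frame(word = x$word, subclass = x$subclass,
               stringsAsFactors = FALSE)))
  revision_rules(context_removals = ctx, additions_assignment = add,
                 psychological_selection = unlist(fx$psychological_selection),
                 sentence_frame = fx$sentence_frame)
}

#' Post-level descriptor counts over a corpus
#'
#' A post contributes at most 1 to a descriptor's count no matter how often
#' the descriptor occurs inside it; multiword descriptors match as
#' consecutive tokens.
#'
#' @param posts cleaned corpus data.frame (with `tokens`)
#' @param descriptors character vector
#' @return named integer vector of counts
#' @export
count_descriptors <- function(posts, descriptors) {
  stopifnot(is.data.frame(posts), "tokens" %in% names(posts),
            length(descriptors) > 0L)
  out <- vapply(descriptors, function(d) {
    sum(vapply(posts$tokens, contains_phrase, logical(1), phrase = d))
  }, integer(1))
  names(out) <- tolower(descriptors)
  out
}

#' Derive the prevalence threshold from original-descriptor counts
#'
#' The bottom `decile` of the original descriptors (by count; size
#' `ceiling(decile * n)`, alphabetical tie-break, extended to include all
#' members tied with the boundary count) defines the prevalence bar: the
#' threshold is the smallest count strictly greater than every bottom-set
#' count, and words with `count < threshold` fail the prevalence criterion.
#' With all counts equal the bottom set would swallow the whole
#' questionnaire; that degenerate input yields an empty bottom set, a
#' warning, and `threshold = count + 1`.
#'
#' @param original_counts named numeric/integer vector (descriptor ->
#'   count), non-empty
#' @param decile fraction in (0,1), default 0.10
#' @return list with `threshold` (integer) and `bottom_set` (character,
#'   lowest counts first)
#' @export
derive_threshold <- function(original_counts, decile = 0.10) {
  n <- length(original_counts)
  if (n == 0L) stop("original_counts must be non-empty", call. = FALSE)
  stopifnot(!is.null(names(original_counts)), decile > 0, decile < 1)
  cnt <- as.numeric(original_counts)
  nm <- names(original_counts)
  if (length(unique(cnt)) == 1L) {
    warning("all counts tied; threshold set to count + 1, empty bottom set")
    return(list(threshold = as.integer(cnt[1] + 1), bottom_set = character(0)))
  }
  ord <- order(cnt, nm) # count ascending, alphabetical tie-break
  k <- as.integer(ceiling(decile * n))
  boundary <- cnt[ord][k]
  while (k < n && cnt[ord][k + 1L] == boundary) k <- k + 1L # tie extension
  bottom <- nm[ord][seq_len(k)]
  above <- cnt[cnt > boundary]
  threshold <- if (length(above) > 0L) min(above) else boundary + 1
  list(threshold = as.integer(threshold), bottom_set = bottom)
}

#' Apply the removal rules to the original questionnaire
#'
#' Removes descriptors whose count falls below the prevalence threshold
#' (rule `low_use`) and the configured context removals (rule `context`).
#' Survivors keep their subclass and order.
#'
#' @param original a `questionnaire`
#' @param counts named vector covering every original descriptor
#' @param threshold prevalence threshold (from [derive_threshold()])
#' @param rules a [revision_rules()]
#' @return list with `removals` (data.frame descriptor, subclass, rule) and
#'   `survivors` (a `questionnaire`)
#' @export
apply_removal_rules <- function(original, counts, threshold, rules) {
  stopifnot(inherits(original, "questionnaire"),
            inherits(rules, "revision_rules"))
  desc <- all_descriptors(original)
  missing <- setdiff(desc, names(counts))
  if (length(missing) > 0L) {
    stop(sprintf("counts missing for: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  ctx <- rules$context_removals
  ctx_words <- if (is.null(ctx)) character(0) else tolower(ctx$descriptor)
  unknown <- setdiff(ctx_words, desc)
  if (length(unknown) > 0L) {
    stop(sprintf("context removal names unknown descriptor(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  removals <- data.frame(descriptor = character(0), subclass = character(0),
                         rule = character(0), stringsAsFactors = FALSE)
  survivors <- list()
  for (s in original$subclasses) {
    keep <- character(0)
    for (d in s$descriptors) {
      if (counts[[d]] < threshold) {
        removals <- rbind(removals, data.frame(
          descriptor = d, subclass = s$name, rule = "low_use",
          stringsAsFactors = FALSE))
      } else if (d %in% ctx_words) {
        removals <- rbind(removals, data.frame(
          descriptor = d, subclass = s$name, rule = "context",
          stringsAsFactors = FALSE))
      } else {
        keep <- c(keep, d)
      }
    }
    survivors <- c(survivors, list(list(name = s$name,
                                        class_label = s$class_label,
                                        descriptors = keep)))
  }
  list(removals = removals, survivors = questionnaire(survivors))
}

#' Validate and apply the addition rules
#'
#' Every word in `rules$additions_assignment` must meet the prevalence
#' threshold in `candidate_stats`; a below-threshold assignment is an error
#' (the prevalence criterion is machine-checked, not trusted).
#'
#' @param candidate_stats data.frame with columns descriptor, count (and
#'   optionally intensity), e.g. from [descriptor_stats()]
#' @param threshold prevalence threshold
#' @param rules a [revision_rules()]
#' @return data.frame word, subclass, count of the validated additions (in
#'   assignment order)
#' @export
apply_addition_rules <- function(candidate_stats, threshold, rules) {
  stopifnot(inherits(rules, "revision_rules"))
  add <- rules$additions_assignment
  if (is.null(add) || nrow(add) == 0L) {
    return(data.frame(word = character(0), subclass = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  add$word <- tolower(add$word)
  idx <- match(add$word, tolower(candidate_stats$descriptor))
  if (anyNA(idx)) {
    stop(sprintf("no candidate stats for: %s",
                 paste(add$word[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  cnt <- candidate_stats$count[idx]
  low <- cnt < threshold
  if (any(low)) {
    stop(sprintf(
      "prevalence violation: %s below threshold %d (count %s)",
      paste(add$word[low], collapse = ", "), as.integer(threshold),
      paste(cnt[low], collapse = ", ")), call. = FALSE)
  }
  data.frame(word = add$word, subclass = add$subclass, count = cnt,
             stringsAsFactors = FALSE)
}

#' Build the psychological subclass
#'
#' Takes the configured ordered selection of emotional-state descriptors
#' (already phrased to complete the sentence frame) and validates each
#' against the available stats; when an envelope is supplied, counts and
#' intensities outside it raise a validation warning.
#'
#' @param stats data.frame descriptor, count, intensity covering the
#'   selection
#' @param rules a [revision_rules()] (selection + sentence frame)
#' @param envelope optional list(count = c(lo, hi), intensity = c(lo, hi))
#' @return subclass list (name, class_label, descriptors); empty selection
#'   gives an empty subclass with a warning
#' @export
build_psychological_subclass <- function(stats, rules, envelope = NULL) {
  stopifnot(inherits(rules, "revision_rules"))
  sel <- rules$psychological_selection
  if (length(sel) == 0L) {
    warning("empty psychological selection; subclass will be empty")
    return(list(name = "Psychological", class_label = "psychological",
                descriptors = character(0)))
  }
  idx <- match(sel, tolower(stats$descriptor))
  if (anyNA(idx)) {
    stop(sprintf("selected word(s) missing from stats: %s",
                 paste(sel[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  if (!is.null(envelope)) {
    cnt <- stats$count[idx]; its <- stats$intensity[idx]
    bad_c <- cnt < envelope$count[1] | cnt > envelope$count[2]
    bad_i <- its < envelope$intensity[1] | its > envelope$intensity[2]
    if (any(bad_c | bad_i)) {
      warning(sprintf("selection outside envelope: %s",
                      paste(sel[bad_c | bad_i], collapse = ", ")))
    }
  }
  list(name = "Psychological", class_label = "psychological",
       descriptors = sel)
}

#' Reorder a subclass by pain intensity
#'
#' Stable sort of the descriptors by intensity in the configured direction;
#' ties preserve input order. `changed` flags whether the output order
#' differs from the input order.
#'
#' @param descriptors character vector, current order
#' @param intensities named numeric covering every descriptor
#' @param direction "ascending" (default) or "descending"
#' @return list with `ordered` (character) and `changed` (logical)
#' @export
reorder_subclass <- function(descriptors, intensities,
                             direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  missing <- setdiff(descriptors, names(intensities))
  if (length(missing) > 0L) {
    stop(sprintf("missing intensity for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  v <- as.numeric(intensities[descriptors])
  ord <- if (direction == "ascending") order(v) else order(-v) # stable
  out <- descriptors[ord]
  list(ordered = out, changed = !identical(out, descriptors))
}

#' Assemble the revised questionnaire and revision report
#'
#' Merges survivors with their assigned additions subclass by subclass,
#' reorders each merged subclass by intensity, appends the psychological
#' subclass (kept in its configured order), and emits a report. A subclass
#' is flagged as reordered when the relative order of its *surviving
#' original* descriptors changed -- insertions of new words between
#' unmoved originals do not count as a reordering. Subclasses emptied by
#' removals are dropped. A descriptor assigned to two subclasses by the
#' additions is an error.
#'
#' @param original the original `questionnaire`
#' @param survivors `questionnaire` from [apply_removal_rules()]
#' @param removals removal data.frame from [apply_removal_rules()]
#' @param additions additions data.frame from [apply_addition_rules()]
#' @param psychological subclass list from
#'   [build_psychological_subclass()] (or NULL to skip)
#' @param intensities named numeric covering every descriptor of the
#'   revised questionnaire
#' @param rules a [revision_rules()] (reorder direction)
#' @param threshold the prevalence threshold used (recorded in the report)
#' @return list with `revised` (a `questionnaire`) and `report` (list:
#'   threshold_used, removed, added, new_subclasses, reordered_subclasses,
#'   per_subclass_diffs)
#' @export
assemble_and_report <- function(original, survivors, removals, additions,
                                psychological, intensities, rules,
                                threshold = NA_integer_) {
  stopifnot(inherits(original, "questionnaire"),
            inherits(survivors, "questionnaire"),
            inherits(rules, "revision_rules"))
  if (anyDuplicated(additions$word)) {
    stop("a descriptor may not be added to two subclasses", call. = FALSE)
  }
  known <- vapply(survivors$subclasses, `[[`, character(1), "name")
  unknown <- setdiff(unique(additions$subclass), known)
  if (length(unknown) > 0L) {
    stop(sprintf("additions reference unknown subclass(es): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  revised <- list()
  reordered <- character(0)
  diffs <- list()
  for (s in survivors$subclasses) {
    added_here <- additions$word[additions$subclass == s$name]
    merged <- c(s$descriptors, added_here)
    if (length(merged) == 0L) next # emptied subclass is dropped
    if (anyDuplicated(merged)) {
      stop(sprintf("addition duplicates a survivor in subclass '%s'", s$name),
           call. = FALSE)
    }
    ro <- reorder_subclass(merged, intensities,
                           direction = rules$reorder_direction)
    surv_out <- ro$ordered[ro$ordered %in% s$descriptors]
    surv_changed <- !identical(surv_out, s$descriptors)
    if (surv_changed) reordered <- c(reordered, s$name)
    orig_sub <- Filter(function(o) o$name == s$name, original$subclasses)[[1]]
    diffs[[s$name]] <- list(
      original = orig_sub$descriptors,
      revised = ro$ordered,
      removed = setdiff(orig_sub$descriptors, s$descriptors),
      added = added_here,
      reordered = surv_changed)
    revised <- c(revised, list(list(name = s$name,
                                    class_label = s$class_label,
                                    descriptors = ro$ordered)))
  }
  new_subclasses <- character(0)
  if (!is.null(psychological) && length(psychological$descriptors) > 0L) {
    revised <- c(revised, list(psychological))
    new_subclasses <- psychological$name
  }
  revised_q <- questionnaire(revised)
  report <- list(
    threshold_used = as.integer(threshold),
    removed = removals,
    added = additions[, c("word", "subclass"), drop = FALSE],
    new_subclasses = new_subclasses,
    reordered_subclasses = reordered,
    per_subclass_diffs = diffs,
    n_original = length(all_descriptors(original)),
    n_revised = length(all_descriptors(revised_q)))
  # conservation: |revised| = |original| - |removed| + |added| + |psych|
  n_psych <- if (is.null(psychological)) 0L else
    length(psychological$descriptors)
  stopifnot(report$n_revised ==
              report$n_original - nrow(removals) + nrow(additions) + n_psych)
  list(revised = revised_q, report = report)
}

#' Run the whole revision workflow
#'
#' Convenience wrapper chaining [derive_threshold()],
#' [apply_removal_rules()], [apply_addition_rules()],
#' [build_psychological_subclass()] and [assemble_and_report()].
#'
#' @param original the original `questionnaire`
#' @param original_counts named counts for the original descriptors
#' @param candidate_stats data.frame descriptor, count, intensity for new
#'   candidate words (and psychological selections)
#' @param intensities named numeric covering all revised descriptors
#' @param rules a [revision_rules()]
#' @param envelope optional psychological validation envelope
#' @return list(revised, report) as in [assemble_and_report()]
#' @export
revise_questionnaire <- function(original, original_counts, candidate_stats,
                                 intensities, rules,
                                 envelope = NULL) {
  thr <- derive_threshold(original_counts, decile = rules$decile)
  rem <- apply_removal_rules(original, original_counts, thr$threshold, rules)
  add <- apply_addition_rules(candidate_stats, thr$threshold, rules)
  psych <- if (length(rules$psychological_selection) > 0L) {
    build_psychological_subclass(candidate_stats, rules, envelope = envelope)
  } else NULL
  assemble_and_report(original, rem$survivors, rem$removals, add, psych,
                      intensities, rules, threshold = thr$threshold)
}

# ---- questionnaire I/O ------------------------------------------------------

#' Write a questionnaire as JSON
#' @param q a `questionnaire`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_questionnaire_json <- function(q, path) {
  stopifnot(inherits(q, "questionnaire"))
  jsonlite::write_json(list(subclasses = q$subclasses), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a questionnaire from JSON
#' @param path input path
#' @return a `questionnaire`
#' @export
read_questionnaire_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  subs <- lapply(raw$subclasses, function(s) {
    s$descriptors <- as.character(unlist(s$descriptors))
    s
  })
  questionnaire(subs)
}

#' Render a questionnaire as Markdown
#' @param q a `questionnaire`
#' @return character vector of Markdown lines
#' @export
render_questionnaire_md <- function(q) {
  stopifnot(inherits(q, "questionnaire"))
  lines <- character(0)
  for (s in q$subclasses) {
    lines <- c(lines, sprintf("## %s (%s)", s$name, s$class_label),
               paste0(seq_along(s$descriptors), ". ", s$descriptors), "")
  }
  lines
}

#' Render a revision report as Markdown
#' @param report the `report` component of [assemble_and_report()]
#' @return character vector of Markdown lines
#' @export
render_report_md <- function(report) {
  lines <- c("# Questionnaire revision report", "",
             sprintf("Prevalence threshold: %d", report$threshold_used),
             sprintf("Descriptors: %d -> %d", report$n_original,
                     report$n_revised), "",
             "## Removed")
  if (nrow(report$removed) > 0L) {
    lines <- c(lines, sprintf("- %s (%s; rule: %s)", report$removed$descriptor,
                              report$removed$subclass, report$removed$rule))
  }
  lines <- c(lines, "", "## Added")
  if (nrow(report$added) > 0L) {
    lines <- c(lines, sprintf("- %s -> %s", report$added$word,
                              report$added$subclass))
  }
  c(lines, "",
    sprintf("New subclasses: %s",
            paste(report$new_subclasses, collapse = ", ")),
    sprintf("Reordered subclasses: %s",
            paste(report$reordered_subclasses, collapse = ", ")))
}
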