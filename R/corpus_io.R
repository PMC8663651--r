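#' Clean raw social-media text into word tokens
#'
#' Applies the cleaning rules used throughout the pipeline: the text is
#' lowercased and split on whitespace; tokens that are @-mentions or URLs
#' (http/https, www., t.co short links) are dropped entirely; a leading
#' hashtag mark is stripped but the word kept; remaining runs of
#' non-alphanumeric symbols are removed. Empty input yields an empty token
#' vector and cleaning is idempotent: cleaning already-cleaned text is a
#' no-op.
#'
#' @param raw a character scalar (possibly empty)
#' @return character vector of lowercase tokens
#' @examples
#' clean_text("@bob my back pain is UNBEARABLE http://t.co/x")
#' @export
clean_text <- function(raw) {
  if (is.null(raw) || length(raw) == 0L || is.na(raw) || !nzchar(raw)) {
    return(character(0))
  }
  pieces <- strsplit(tolower(raw), "\\s+")[[1]]
  pieces <- pieces[nzchar(pieces)]
  if (length(pieces) == 0L) return(character(0))
  drop <- grepl("^@", pieces) |
    grepl("^(https?://|www\\.|t\\.co/)", pieces)
  pieces <- pieces[!drop]
  pieces <- sub("^#", "", pieces)
  # collapse symbol runs; keep letters, digits and internal apostrophes
  pieces <- gsub("[^a-z0-9' ]+", " ", pieces)
  pieces <- gsub("(^|\\s)'+|'+(\\s|$)", " ", pieces) # strip quote marks
  tokens <- unlist(strsplit(pieces, "\\s+"), use.names = FALSE)
  tokens[nzchar(tokens)]
}

#' Clean every post in a corpus
#'
#' @param posts a corpus data.frame with at least columns `id` and `text`
#' @return the same data.frame with a `tokens` list-column added (replacing
#'   any existing one)
#' @export
clean_posts <- function(posts) {
  stopifnot(is.data.frame(posts), all(c("id", "text") %in% names(posts)))
  if (anyDuplicated(posts$id)) stop("post ids must be unique", call. = FALSE)
  posts$tokens <- I(lapply(posts$text, clean_text))
  posts
}

#' Filter configuration for the relevance filters
#'
#' @param descriptor_list character vector of descriptor words/phrases
#' @param condition_list character vector of pain-condition words/phrases
#'   (used by the round-2 filter)
#' @param hop_limit positive integer; a post passes round 1 only if a
#'   descriptor lies within this many hops of "pain" in the post's word
#'   graph (default 3, inclusive)
#' @param manual_exclusions character vector of post ids or regular
#'   expressions matched against post ids/text to emulate manual relevance
#'   screening
#' @param window adjacency window for the per-post word graph (default 1)
#' @return a `filter_config` list
#' @export
filter_config <- function(descriptor_list = character(0),
                          condition_list = character(0),
                          hop_limit = 3L,
                          manual_exclusions = character(0),
                          window = 1L) {
  stopifnot(is.numeric(hop_limit), length(hop_limit) == 1L, hop_limit >= 1)
  structure(list(descriptor_list = tolower(as.character(descriptor_list)),
                 condition_list = tolower(as.character(condition_list)),
                 hop_limit = as.integer(hop_limit),
                 manual_exclusions = as.character(manual_exclusions),
                 window = as.integer(window)),
            class = "filter_config")
}

#' Round-1 relevance filter: "pain" plus a descriptor within k hops
#'
#' A post is relevant when its tokens contain the word "pain" and at least
#' one descriptor lies within `cfg$hop_limit` hops of "pain" in the post's
#' word graph. Multiword descriptors are matched through their head token
#' (the first token of the phrase) for the hop query, and must occur as a
#' consecutive token sequence in the post.
#'
#' @param tokens character vector of cleaned tokens for one post
#' @param cfg a [filter_config()]; `descriptor_list` must be non-empty
#' @return logical scalar
#' @export
relevance_filter_round1 <- function(tokens, cfg) {
  stopifnot(inherits(cfg, "filter_config"))
  if (length(cfg$descriptor_list) == 0L) {
    stop("descriptor_list must be non-empty for the round-1 filter",
         call. = FALSE)
  }
  if (!("pain" %in% tokens)) return(FALSE)
  g <- build_word_graph(tokens, window = cfg$window)
  for (d in cfg$descriptor_list) {
    if (!contains_phrase(tokens, d)) next
    head_tok <- phrase_tokens(d)[1L]
    if (within_hops(g, "pain", head_tok, cfg$hop_limit)) return(TRUE)
  }
  FALSE
}

#' Round-2 relevance filter: a descriptor and a pain condition
#'
#' A post passes when it contains at least one descriptor from the expanded
#' list and at least one pain condition (both phrase-aware, whole-token).
#'
#' @inheritParams relevance_filter_round1
#' @return logical scalar
#' @export
relevance_filter_round2 <- function(tokens, cfg) {
  stopifnot(inherits(cfg, "filter_config"))
  if (length(cfg$descriptor_list) == 0L || length(cfg$condition_list) == 0L) {
    stop("descriptor_list and condition_list must be non-empty for round 2",
         call. = FALSE)
  }
  has_desc <- any(vapply(cfg$descriptor_list, contains_phrase,
                         logical(1), tokens = tokens))
  if (!has_desc) return(FALSE)
  any(vapply(cfg$condition_list, contains_phrase, logical(1),
             tokens = tokens))
}

#' Apply configured manual exclusions
#'
#' Stands in for human relevance screening: each pattern is matched as a
#' regular expression against post ids and raw text; matching posts are
#' removed. The removal log records which pattern fired for each removed
#' post.
#'
#' @param posts corpus data.frame
#' @param cfg a [filter_config()] whose `manual_exclusions` holds the
#'   patterns
#' @return list with `kept`, `removed` (both data.frames, order-preserving,
#'   a partition of the input) and `log` (data.frame id/pattern)
#' @export
apply_manual_exclusions <- function(posts, cfg) {
  stopifnot(is.data.frame(posts), inherits(cfg, "filter_config"))
  pats <- cfg$manual_exclusions
  for (p in pats) { # validate before touching anything
    ok <- tryCatch({ grepl(p, "probe"); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop(sprintf("malformed exclusion pattern: '%s'", p),
                  call. = FALSE)
  }
  hit_pattern <- rep(NA_character_, nrow(posts))
  for (p in pats) {
    m <- grepl(p, posts$id) | grepl(p, posts$text)
    hit_pattern[is.na(hit_pattern) & m] <- p
  }
  removed_idx <- which(!is.na(hit_pattern))
  kept_idx <- which(is.na(hit_pattern))
  list(kept = posts[kept_idx, , drop = FALSE],
       removed = posts[removed_idx, , drop = FALSE],
       log = data.frame(id = posts$id[removed_idx],
                        pattern = hit_pattern[removed_idx],
                        stringsAsFactors = FALSE))
}

# ---- post I/O ---------------------------------------------------------------

#' Write a corpus as JSON-lines
#'
#' One JSON object per line with fields id, platform, timestamp, text.
#' Tokens are never written: cleaning is re-derivable and hidden generator
#' labels live in a separate sidecar file.
#'
#' @param posts corpus data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_posts_jsonl <- function(posts, path) {
  stopifnot(is.data.frame(posts))
  cols <- intersect(c("id", "platform", "timestamp", "text"), names(posts))
  con <- file(path, open = "wb") # binary mode: byte-identical across platforms
  on.exit(close(con))
  for (i in seq_len(nrow(posts))) {
    rec <- as.list(posts[i, cols, drop = FALSE])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a JSON-lines corpus written by [write_posts_jsonl()]
#' @param path input path
#' @return corpus data.frame
#' @export
read_posts_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(id = character(0), platform = character(0),
                      timestamp = character(0), text = character(0),
                      stringsAsFactors = FALSE))
  }
  recs <- lapply(lines, jsonlite::fromJSON)
  as_chr <- function(f) vapply(recs, function(r) as.character(r[[f]] %||% NA),
                               character(1))
  data.frame(id = as_chr("id"), platform = as_chr("platform"),
             timestamp = as_chr("timestamp"), text = as_chr("text"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a corpus as CSV
#' @inheritParams write_posts_jsonl
#' @return `path`, invisibly
#' @export
write_posts_csv <- function(posts, path) {
  cols <- intersect(c("id", "platform", "timestamp", "text"), names(posts))
  utils::write.csv(posts[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV corpus
#' @param path input path
#' @return corpus data.frame
#' @export
read_posts_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character")
}

# ---- stage manifests --------------------------------------------------------

#' Create a stage-manifest entry
#'
#' Records the bookkeeping of one pipeline stage: posts in, posts out,
#' posts removed (with an optional rule breakdown) and a provenance hash of
#' the stage inputs. Conservation (`n_in == n_out + n_removed`) is asserted
#' at construction.
#'
#' @param stage stage name
#' @param n_in,n_out number of posts entering/leaving the stage
#' @param rule_breakdown optional named integer vector of removals per rule
#' @param input_hash provenance hash string of the stage inputs
#' @return a `stage_manifest` row (list)
#' @export
stage_manifest <- function(stage, n_in, n_out, rule_breakdown = NULL,
                           input_hash = NA_character_) {
  n_removed <- n_in - n_out
  if (n_removed < 0L) stop("n_out exceeds n_in", call. = FALSE)
  if (!is.null(rule_breakdown) && sum(rule_breakdown) != n_removed) {
    stop("rule breakdown does not sum to n_removed", call. = FALSE)
  }
  structure(list(stage = stage, n_in = as.integer(n_in),
                 n_out = as.integer(n_out), n_removed = as.integer(n_removed),
                 rule_breakdown = rule_breakdown, input_hash = input_hash),
            class = "stage_manifest")
}

#' Write a list of stage manifests as JSON
#' @param manifests list of [stage_manifest()] entries
#' @param path output path
#' @return `path`, invisibly
#' @export
write_manifest_json <- function(manifests, path) {
  jsonlite::write_json(lapply(manifests, unclass), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
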