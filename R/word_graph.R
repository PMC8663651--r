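#' Build a word co-occurrence graph from a token sequence
#'
#' Nodes are the unique tokens; an undirected edge joins two distinct tokens
#' whenever they occur within `window` positions of each other somewhere in
#' the sequence. With the default `window = 1` only consecutive tokens are
#' joined, so hop distance counts steps along the running text: words
#' immediately next to a root word are one hop away, the next layer two hops,
#' and so on.
#'
#' @param tokens character vector of tokens (an empty vector gives an empty
#'   graph)
#' @param window positive integer co-occurrence window (default 1)
#' @return an object of class `word_graph` with elements `nodes` (character)
#'   and `adj` (named list of character neighbour vectors)
#' @examples
#' g <- build_word_graph(c("pain", "is", "sharp"))
#' hop_distance(g, "pain", "sharp")
#' @export
build_word_graph <- function(tokens, window = 1L) {
  stopifnot(is.numeric(window), length(window) == 1L, window >= 1)
  window <- as.integer(window)
  tokens <- as.character(tokens)
  nodes <- unique(tokens)
  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  n <- length(tokens)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      jmax <- min(n, i + window)
      for (j in (i + 1L):jmax) {
        a <- tokens[i]; b <- tokens[j]
        if (a != b) { # no self-loops
          adj[[a]] <- c(adj[[a]], b)
          adj[[b]] <- c(adj[[b]], a)
        }
      }
    }
    adj <- lapply(adj, function(x) sort(unique(x)))
  }
  structure(list(nodes = nodes, adj = adj, window = window),
            class = "word_graph")
}

#' @export
print.word_graph <- function(x, ...) {
  n_edges <- sum(lengths(x$adj)) / 2
  cat(sprintf("<word_graph: %d nodes, %d edges, window %d>\n",
              length(x$nodes), n_edges, x$window))
  invisible(x)
}

#' Edge list of a word graph
#'
#' @param g a `word_graph`
#' @return data.frame with columns `from`, `to`, one row per undirected edge
#'   (`from < to` lexicographically)
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "word_graph"))
  from <- character(0); to <- character(0)
  for (a in names(g$adj)) {
    for (b in g$adj[[a]]) {
      if (a < b) { from <- c(from, a); to <- c(to, b) }
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Write a word graph as a two-column TSV edge list (debugging aid)
#' @param g a `word_graph`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_graph_tsv <- function(g, path) {
  ed <- graph_edges(g)
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hop distance between two tokens
#'
#' Breadth-first search shortest path, counted in edges. A token's distance
#' to itself is 0. If either token is absent from the graph, or no path
#' exists, the result is `Inf` (unreachable).
#'
#' @param g a `word_graph`
#' @param source,target token strings
#' @return non-negative integer hop count, or `Inf`
#' @export
hop_distance <- function(g, source, target) {
  stopifnot(inherits(g, "word_graph"))
  if (!(source %in% g$nodes) || !(target %in% g$nodes)) return(Inf)
  if (source == target) return(0L)
  dist <- new.env(parent = emptyenv())
  assign(source, 0L, envir = dist)
  frontier <- source
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    nxt <- character(0)
    for (v in frontier) {
      for (w in g$adj[[v]]) {
        if (!exists(w, envir = dist, inherits = FALSE)) {
          if (w == target) return(d)
          assign(w, d, envir = dist)
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  Inf
}

#' Is `target` within `k` hops of `source`?
#'
#' The bound is inclusive: a token exactly `k` hops away counts as within
#' `k` hops.
#'
#' @inheritParams hop_distance
#' @param k non-negative integer hop limit
#' @return logical scalar
#' @export
within_hops <- function(g, source, target, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  hop_distance(g, source, target) <= k
}
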