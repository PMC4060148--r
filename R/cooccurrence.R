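# The core statistic: for an unordered word pair, the number of distinct
# accounts in which the pair co-occurs on at least one tweet line. Counting
# accounts rather than raw co-occurrences suppresses hyper-active single
# accounts, so one account repeating a pair on every line still contributes
# exactly 1. Plus top-K edge selection and graph construction.

#' Word pairs co-occurring within one account
#'
#' The union over the account's noun lines of all unordered pairs of
#' distinct lemmas on the same line. Set semantics: however often a pair
#' repeats within the account, it appears once. Self-pairs (a lemma
#' repeated on a line) are excluded — a combination needs two distinct
#' words.
#'
#' @param noun_lines a [noun_lines()] object.
#' @return two-column character matrix (`word1`, `word2`), each row a
#'   lexicographically sorted pair, rows sorted and unique.
#' @export
account_pair_set <- function(noun_lines) {
  stopifnot(inherits(noun_lines, "noun_lines"))
  keys <- .account_pair_keys(noun_lines)
  .split_pair_keys(keys)
}

.account_pair_keys <- function(noun_lines) {
  keys <- character(0)
  for (line in noun_lines$lines) {
    u <- unique(line)
    if (length(u) < 2L) next
    u <- sort(u, method = "radix")
    pr <- utils::combn(u, 2L)
    keys <- c(keys, paste(pr[1L, ], pr[2L, ], sep = .PAIR_SEP))
  }
  sort(unique(keys), method = "radix")
}

#' Account-level pair counts
#'
#' For every unordered word pair that co-occurs anywhere, the number of
#' distinct accounts in which it co-occurs on at least one line. This is
#' the edge weight of the co-occurrence network; pairs occurring in no
#' account are absent.
#'
#' @param all_noun_lines list of [noun_lines()] with distinct account ids.
#' @return data frame of class `pair_counts` with columns `word1`, `word2`,
#'   `account_count`, sorted by decreasing count then lexicographically.
#' @export
count_pair_accounts <- function(all_noun_lines) {
  ok <- vapply(all_noun_lines, inherits, logical(1), what = "noun_lines")
  if (length(all_noun_lines) && !all(ok)) {
    .stopf("all elements must be noun_lines objects")
  }
  ids <- vapply(all_noun_lines, `[[`, character(1), "account_id")
  if (anyDuplicated(ids)) {
    .stopf("duplicate account_id '%s'", ids[duplicated(ids)][1L])
  }
  keys <- unlist(lapply(all_noun_lines, .account_pair_keys),
                 use.names = FALSE)
  if (!length(keys)) {
    out <- data.frame(word1 = character(0), word2 = character(0),
                      account_count = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("pair_counts", "data.frame")
    return(out)
  }
  tab <- table(keys)
  words <- .split_pair_keys(names(tab))
  out <- data.frame(word1 = words[, 1L], word2 = words[, 2L],
                    account_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  ord <- order(-out$account_count, out$word1, out$word2, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_counts", "data.frame")
  out
}

#' Select the top-K heaviest pairs
#'
#' Pairs are ranked by account count (descending) with lexicographic
#' tie-breaks, and the first `min(k, n)` become network edges (default
#' K = 100). Ties straddling the rank-k boundary are cut deterministically
#' by the lexicographic order; `ties = "include"` instead keeps every pair
#' tied with the rank-k count, possibly returning more than `k` edges.
#'
#' @param counts a [count_pair_accounts()] result (or data frame with the
#'   same columns).
#' @param k positive integer, default 100.
#' @param ties `"cut"` (exactly `min(k, n)` edges) or `"include"`.
#' @return data frame `word1`, `word2`, `account_count` in selection order,
#'   with attributes `k` and `ties`.
#' @export
select_top_k <- function(counts, k = 100L, ties = c("cut", "include")) {
  ties <- match.arg(ties)
  if (!.is_count(k)) .stopf("k must be a positive integer")
  counts <- as.data.frame(counts, stringsAsFactors = FALSE)
  stopifnot(all(c("word1", "word2", "account_count") %in% names(counts)))
  ord <- order(-counts$account_count, counts$word1, counts$word2,
               method = "radix")
  counts <- counts[ord, , drop = FALSE]
  n_keep <- min(k, nrow(counts))
  if (ties == "include" && n_keep > 0L && n_keep < nrow(counts)) {
    thresh <- counts$account_count[n_keep]
    n_keep <- max(which(counts$account_count >= thresh))
  }
  out <- counts[seq_len(n_keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- as.integer(k)
  attr(out, "ties") <- ties
  out
}

#' Build the co-occurrence graph
#'
#' Words become nodes, selected pairs become undirected weighted edges
#' (weight = account count). The graph is simple: no self-loops, no
#' duplicate edges, every node incident to at least one edge.
#'
#' @param edges edge list from [select_top_k()].
#' @param k selection threshold recorded in the graph (defaults to the
#'   `k` attribute of `edges`).
#' @return object of class `cooc_graph`: `list(nodes, edges, k, ties)`,
#'   `nodes` sorted lexicographically.
#' @export
build_graph <- function(edges, k = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  k <- as.integer(k %||% attr(edges, "k") %||% max(1L, nrow(edges)))
  ties <- attr(edges, "ties") %||% "cut"
  if (nrow(edges)) {
    stopifnot(all(c("word1", "word2", "account_count") %in% names(edges)))
    if (any(edges$word1 == edges$word2)) .stopf("self-loop edge in input")
    key <- .pair_key(edges$word1, edges$word2)
    if (anyDuplicated(key)) .stopf("duplicate pair in edge list")
  }
  nodes <- sort(unique(c(edges$word1, edges$word2)), method = "radix")
  structure(list(nodes = nodes,
                 edges = edges[c("word1", "word2", "account_count")],
                 k = k, ties = ties),
            class = "cooc_graph")
}

#' @export
print.cooc_graph <- function(x, ...) {
  cat(sprintf("<cooc_graph> %d nodes, %d edges (k = %d, ties = %s)\n",
              length(x$nodes), nrow(x$edges), x$k, x$ties))
  invisible(x)
}

#' Write an edge list as TSV
#'
#' `word1<TAB>word2<TAB>account_count`, in selection order, with a header.
#'
#' @param edges edge list (from [select_top_k()] or a `cooc_graph$edges`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_edge_list <- function(edges, path) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c("word1\tword2\taccount_count",
             sprintf("%s\t%s\t%d", edges$word1, edges$word2,
                     as.integer(edges$account_count)))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}
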