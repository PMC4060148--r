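# Text processing: period line-splitting, dictionary tokenization behind a
# pluggable tokenizer contract, noun extraction in lemma form, and synonym
# integration — producing per-account noun lines.

#' Build a term dictionary
#'
#' Maps surface forms to `(lemma, pos)`, with `pos` one of `noun`, `verb`,
#' `adjective`, `other`. Lookup is NFKC-normalized and case-folded, and the
#' default tokenizer matches surfaces greedily longest-first, so multi-word
#' or multi-character surfaces take priority over their prefixes.
#'
#' @param entries data frame with character columns `surface`, `lemma`,
#'   `pos`.
#' @return object of class `term_dictionary`.
#' @seealso [read_term_dictionary()], [tokenize()]
#' @export
term_dictionary <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries) == 0L) {
    entries <- data.frame(surface = character(0), lemma = character(0),
                          pos = character(0), stringsAsFactors = FALSE)
  }
  if (!all(c("surface", "lemma", "pos") %in% names(entries))) {
    .stopf("dictionary needs surface, lemma, pos columns")
  }
  pos_ok <- entries$pos %in% c("noun", "verb", "adjective", "other")
  if (!all(pos_ok)) {
    .stopf("invalid pos tag '%s' (allowed: noun, verb, adjective, other)",
           entries$pos[which(!pos_ok)[1L]])
  }
  if (any(!nzchar(entries$lemma))) .stopf("dictionary lemmas must be non-empty")
  entries$surface <- normalize_text(entries$surface)
  if (anyDuplicated(entries$surface)) {
    .stopf("duplicate dictionary surface '%s'",
           entries$surface[duplicated(entries$surface)][1L])
  }
  # longest-match priority: per first character, surfaces sorted by
  # decreasing length (ties lexicographic for determinism)
  ord <- order(-nchar(entries$surface), entries$surface, method = "radix")
  entries <- entries[ord, , drop = FALSE]
  rownames(entries) <- NULL
  first <- substr(entries$surface, 1L, 1L)
  index <- split(seq_len(nrow(entries)), first)
  structure(list(entries = entries, index = index),
            class = "term_dictionary")
}

#' Read a term dictionary from TSV
#'
#' Format: `surface<TAB>lemma<TAB>pos`, UTF-8, `#` comments and blank lines
#' allowed.
#'
#' @param path file path.
#' @return a [term_dictionary()].
#' @export
read_term_dictionary <- function(path) {
  df <- .read_tsv(path, c("surface", "lemma", "pos"))
  term_dictionary(df)
}

.read_tsv <- function(path, cols) {
  if (!file.exists(path)) .stopf("file does not exist: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols), stringsAsFactors = FALSE)
    return(df)
  }
  parts <- stringi::stri_split_fixed(lines, "\t")
  bad <- which(vapply(parts, length, integer(1)) < length(cols))
  if (length(bad)) .stopf("malformed TSV line in %s: '%s'", path,
                          lines[bad[1L]])
  df <- as.data.frame(
    stats::setNames(lapply(seq_along(cols), function(i) {
      trimws(vapply(parts, `[[`, character(1), i))
    }), cols),
    stringsAsFactors = FALSE)
  df
}

#' Build a synonym map
#'
#' Maps variant lemmas to a canonical lemma. The map must be flat: a
#' canonical form never maps elsewhere, so applying the map is idempotent.
#' Chains (`a -> b`, `b -> c`) and cycles are rejected at construction.
#'
#' @param entries data frame with character columns `variant`, `canonical`,
#'   or NULL for the empty map.
#' @return object of class `synonym_map`.
#' @export
synonym_map <- function(entries = NULL) {
  if (is.null(entries) || NROW(entries) == 0L) {
    return(structure(list(map = character(0)), class = "synonym_map"))
  }
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!all(c("variant", "canonical") %in% names(entries))) {
    .stopf("synonym map needs variant, canonical columns")
  }
  variant <- normalize_text(entries$variant)
  canonical <- normalize_text(entries$canonical)
  keep <- variant != canonical  # self-entries are no-ops
  variant <- variant[keep]
  canonical <- canonical[keep]
  if (anyDuplicated(variant)) {
    .stopf("variant '%s' mapped more than once",
           variant[duplicated(variant)][1L])
  }
  chained <- canonical %in% variant
  if (any(chained)) {
    .stopf("synonym chain/cycle: canonical '%s' is itself remapped",
           canonical[which(chained)[1L]])
  }
  map <- stats::setNames(canonical, variant)
  structure(list(map = map), class = "synonym_map")
}

#' Read a synonym map from TSV
#'
#' Format: `variant<TAB>canonical`, UTF-8, `#` comments allowed. Chains and
#' cycles are a validation error at load time.
#'
#' @param path file path.
#' @return a [synonym_map()].
#' @export
read_synonym_map <- function(path) {
  synonym_map(.read_tsv(path, c("variant", "canonical")))
}

#' Split a tweet into lines at sentence-final periods
#'
#' Splits on the ASCII period `"."` and the ideographic full stop
#' `"。"`; delimiters are dropped and whitespace-only segments removed.
#'
#' @param text tweet text.
#' @param delimiters characters to split on; override to restrict or extend
#'   the delimiter set.
#' @return character vector of line strings (possibly empty).
#' @export
#' @examples
#' split_lines("a b. c d.")  # c("a b", "c d")
split_lines <- function(text, delimiters = c(".", "。")) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) return(character(0))
  # inside a character class "." is literal; delimiters must not include
  # class metacharacters
  pat <- paste0("[", paste0(delimiters, collapse = ""), "]")
  segs <- stringi::stri_split_regex(text, pat)[[1]]
  segs <- trimws(segs)
  segs[nzchar(segs)]
}

.empty_tokens <- function() {
  data.frame(surface = character(0), lemma = character(0),
             pos = character(0), stringsAsFactors = FALSE)
}

#' Tokenize a line against a term dictionary
#'
#' The default tokenizer backend: the normalized line is scanned left to
#' right, whitespace skipped, and at each position the longest dictionary
#' surface starting there is consumed as one token carrying its dictionary
#' lemma and part of speech. Where no surface matches, the maximal
#' whitespace-delimited chunk becomes a fallback token with
#' `lemma = surface` and `pos = "other"`. A morphological-analyzer backend
#' can replace this function anywhere a tokenizer is accepted, provided it
#' returns the same token shape.
#'
#' @param line a single line string (from [split_lines()]).
#' @param dict a [term_dictionary()].
#' @return data frame with columns `surface`, `lemma`, `pos`, one row per
#'   token in line order.
#' @export
tokenize <- function(line, dict) {
  stopifnot(is.character(line), length(line) == 1L,
            inherits(dict, "term_dictionary"))
  nline <- normalize_text(line)
  n <- nchar(nline)
  if (n == 0L) return(.empty_tokens())
  surfaces <- dict$entries$surface
  slen <- nchar(surfaces)
  surf_v <- character(0); lem_v <- character(0); pos_v <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- substr(nline, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    cand <- dict$index[[ch]]
    hit <- 0L
    for (j in cand) {
      end <- i + slen[j] - 1L
      if (end <= n && substr(nline, i, end) == surfaces[j]) { hit <- j; break }
    }
    if (hit > 0L) {
      surf_v <- c(surf_v, surfaces[hit])
      lem_v <- c(lem_v, dict$entries$lemma[hit])
      pos_v <- c(pos_v, dict$entries$pos[hit])
      i <- i + slen[hit]
    } else {
      rest <- substr(nline, i, n)
      m <- stringi::stri_locate_first_regex(rest, "\\s")[1L, 1L]
      end <- if (is.na(m)) n else i + m - 2L
      chunk <- substr(nline, i, end)
      surf_v <- c(surf_v, chunk)
      lem_v <- c(lem_v, chunk)
      pos_v <- c(pos_v, "other")
      i <- end + 1L
    }
  }
  data.frame(surface = surf_v, lemma = lem_v, pos = pos_v,
             stringsAsFactors = FALSE)
}

#' Extract noun lemmas from tokens
#'
#' Keeps the lemmas of noun tokens only, in order, duplicates preserved.
#' Verbs, adjectives and unmatched (`other`) tokens are discarded.
#'
#' @param tokens token data frame from [tokenize()].
#' @return character vector of noun lemmas.
#' @export
extract_nouns <- function(tokens) {
  stopifnot(is.data.frame(tokens),
            all(c("lemma", "pos") %in% names(tokens)))
  tokens$lemma[tokens$pos == "noun"]
}

#' Merge synonym lemmas into canonical forms
#'
#' Each lemma found in the map is replaced by its canonical form; others
#' pass through unchanged. Because the map is validated flat, the operation
#' is idempotent.
#'
#' @param nouns character vector of (normalized) lemmas.
#' @param syn a [synonym_map()].
#' @return character vector of canonical lemmas, same length.
#' @export
merge_synonyms <- function(nouns, syn) {
  stopifnot(inherits(syn, "synonym_map"))
  if (!length(nouns) || !length(syn$map)) return(nouns)
  mapped <- unname(syn$map[nouns])
  ifelse(is.na(mapped), nouns, mapped)
}

#' Reduce an account's tweets to noun lines
#'
#' Composition of the per-tweet stages: [split_lines()] at periods,
#' [tokenize()] against the dictionary, [extract_nouns()], lemma
#' normalization, and [merge_synonyms()]. Lines left empty after noun
#' extraction are dropped.
#'
#' @param account a [account()].
#' @param dict a [term_dictionary()].
#' @param syn a [synonym_map()] (default empty).
#' @param tokenizer tokenizer backend, `function(line, dict)` returning the
#'   [tokenize()] token shape; defaults to the dictionary tokenizer.
#' @return object of class `noun_lines`: `list(account_id, lines)` where
#'   `lines` is a list of character vectors of canonical noun lemmas, one
#'   per surviving tweet line.
#' @export
process_account <- function(account, dict, syn = synonym_map(),
                            tokenizer = tokenize) {
  stopifnot(inherits(account, "cooc_account"))
  lines_out <- list()
  for (text in account$tweets$text) {
    for (line in split_lines(text)) {
      nouns <- extract_nouns(tokenizer(line, dict))
      if (!length(nouns)) next
      nouns <- merge_synonyms(normalize_text(nouns), syn)
      lines_out[[length(lines_out) + 1L]] <- nouns
    }
  }
  noun_lines(account$account_id, lines_out)
}

#' Construct a noun-lines object
#'
#' @param account_id account identifier.
#' @param lines list of character vectors of canonical noun lemmas.
#' @return object of class `noun_lines`.
#' @export
noun_lines <- function(account_id, lines = list()) {
  stopifnot(is.character(account_id), length(account_id) == 1L)
  lines <- lapply(lines, as.character)
  lines <- lines[vapply(lines, length, integer(1)) > 0L]
  structure(list(account_id = account_id, lines = lines),
            class = "noun_lines")
}

#' Process every account of a corpus
#'
#' @param corpus a [corpus()].
#' @inheritParams process_account
#' @return list of [noun_lines()], one per account, in corpus order.
#' @export
process_corpus <- function(corpus, dict, syn = synonym_map(),
                           tokenizer = tokenize) {
  stopifnot(inherits(corpus, "cooc_corpus"))
  lapply(unname(corpus$accounts), process_account, dict = dict, syn = syn,
         tokenizer = tokenizer)
}
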