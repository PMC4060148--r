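# Corpus data model: accounts with profile text and capped tweet lists,
# JSON-Lines serialization, profile search, and the per-account tweet cap.

#' Construct an account
#'
#' An account is the unit over which co-occurrence is counted: a unique id,
#' a free-text profile, and an ordered list of tweets. Tweets are always
#' stored newest-first; ties in `posted_at` keep their original record
#' order, so capping is deterministic.
#'
#' @param account_id single non-empty string, unique within a corpus.
#' @param profile_text free-text user profile (searched by
#'   [search_profiles()]).
#' @param tweets data frame with character columns `text` (non-empty after
#'   stripping) and `posted_at` (ISO-8601 UTC, e.g.
#'   `"2012-08-20T14:40:00Z"`), or an empty/NULL value for no tweets.
#' @return an object of class `cooc_account`.
#' @export
account <- function(account_id, profile_text = "", tweets = NULL) {
  if (!is.character(account_id) || length(account_id) != 1L ||
      !nzchar(account_id)) {
    .stopf("account_id must be a single non-empty string")
  }
  if (!is.character(profile_text) || length(profile_text) != 1L) {
    .stopf("profile_text must be a single string (account '%s')", account_id)
  }
  if (is.null(tweets) || NROW(tweets) == 0L) {
    tweets <- data.frame(text = character(0), posted_at = character(0),
                         stringsAsFactors = FALSE)
  } else {
    tweets <- as.data.frame(tweets, stringsAsFactors = FALSE)
    if (!all(c("text", "posted_at") %in% names(tweets))) {
      .stopf("tweets need 'text' and 'posted_at' columns (account '%s')",
             account_id)
    }
    tweets <- tweets[c("text", "posted_at")]
    tweets$text <- as.character(tweets$text)
    tweets$posted_at <- as.character(tweets$posted_at)
    if (any(!nzchar(trimws(tweets$text)))) {
      .stopf("tweet text must be non-empty after stripping (account '%s')",
             account_id)
    }
    ts <- .parse_time(tweets$posted_at,
                      where = sprintf("account '%s'", account_id))
    # newest first; stable on ties (radix keeps original order)
    ord <- order(-as.numeric(ts), seq_len(nrow(tweets)), method = "radix")
    tweets <- tweets[ord, , drop = FALSE]
    rownames(tweets) <- NULL
  }
  structure(
    list(account_id = account_id, profile_text = profile_text,
         tweets = tweets),
    class = "cooc_account"
  )
}

#' Construct a corpus
#'
#' @param accounts list of [account()] objects with distinct ids.
#' @param metadata free-form named list (generation seed, query used, ...).
#' @return an object of class `cooc_corpus`.
#' @export
corpus <- function(accounts = list(), metadata = list()) {
  if (!is.list(accounts)) .stopf("accounts must be a list")
  ok <- vapply(accounts, inherits, logical(1), what = "cooc_account")
  if (length(accounts) && !all(ok)) {
    .stopf("all elements of accounts must be cooc_account objects")
  }
  ids <- vapply(accounts, `[[`, character(1), "account_id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) .stopf("duplicate account_id: '%s'", dup[1L])
  names(accounts) <- ids
  structure(list(accounts = accounts, metadata = metadata),
            class = "cooc_corpus")
}

#' @export
print.cooc_corpus <- function(x, ...) {
  nt <- sum(vapply(x$accounts, function(a) nrow(a$tweets), integer(1)))
  cat(sprintf("<cooc_corpus> %d accounts, %d tweets\n",
              length(x$accounts), nt))
  invisible(x)
}

#' @export
length.cooc_corpus <- function(x) length(x$accounts)

.account_to_json <- function(a) {
  rec <- list(
    account_id = a$account_id,
    profile = a$profile_text,
    tweets = lapply(seq_len(nrow(a$tweets)), function(i) {
      list(text = a$tweets$text[i], posted_at = a$tweets$posted_at[i])
    })
  )
  jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
}

#' Write a corpus as JSON-Lines
#'
#' One account per line, UTF-8, deterministic field order
#' (`account_id`, `profile`, `tweets[{text, posted_at}]`). If the corpus
#' carries metadata, it is written first as a single
#' `{"corpus_metadata": ...}` line. [read_corpus()] inverts the format, and
#' the same corpus always serializes to byte-identical files.
#'
#' @param corpus a `cooc_corpus`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "cooc_corpus"))
  lines <- character(0)
  if (length(corpus$metadata)) {
    lines <- as.character(jsonlite::toJSON(
      list(corpus_metadata = corpus$metadata),
      auto_unbox = TRUE, digits = NA))
  }
  lines <- c(lines,
             vapply(corpus$accounts, function(a) as.character(.account_to_json(a)),
                    character(1), USE.NAMES = FALSE))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) {
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a JSON-Lines corpus
#'
#' @param path file written by [write_corpus()] (or conforming to the same
#'   one-account-per-line schema).
#' @return a `cooc_corpus`. Tweet lists are re-sorted newest-first on read.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) .stopf("corpus file does not exist: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  metadata <- list()
  accounts <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    rec <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = FALSE),
      error = function(e) .stopf("malformed corpus record at line %d: %s",
                                 i, conditionMessage(e))
    )
    if (i == 1L && !is.null(rec$corpus_metadata)) {
      metadata <- rec$corpus_metadata
      next
    }
    if (is.null(rec$account_id) || is.null(rec$profile)) {
      .stopf("malformed corpus record at line %d: missing account_id/profile",
             i)
    }
    tweets <- NULL
    if (length(rec$tweets)) {
      tweets <- data.frame(
        text = vapply(rec$tweets, function(t) as.character(t$text),
                      character(1)),
        posted_at = vapply(rec$tweets, function(t) as.character(t$posted_at),
                           character(1)),
        stringsAsFactors = FALSE
      )
    }
    a <- tryCatch(account(rec$account_id, rec$profile, tweets),
                  error = function(e) .stopf(
                    "malformed corpus record at line %d: %s",
                    i, conditionMessage(e)))
    if (a$account_id %in% names(accounts)) {
      .stopf("duplicate account_id '%s' at line %d", a$account_id, i)
    }
    accounts[[a$account_id]] <- a
  }
  corpus(unname(accounts), metadata)
}

#' Construct a query term set
#'
#' A disease name plus its script/spelling variants. Matching is substring
#' containment after NFKC normalization and case folding, so full-width or
#' mixed-case variants do not need separate entries.
#'
#' @param canonical_name label for the query (e.g. `"breast cancer"`).
#' @param variants non-empty character vector of search variants.
#' @return object of class `query_term_set`.
#' @export
query_term_set <- function(canonical_name, variants) {
  variants <- as.character(variants)
  variants <- variants[nzchar(trimws(variants))]
  if (!length(variants)) .stopf("query '%s' needs >= 1 variant",
                                canonical_name)
  structure(list(canonical_name = canonical_name, variants = variants),
            class = "query_term_set")
}

#' Read query term variants from a plain-text file
#'
#' One variant per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @param canonical_name query label; defaults to the first variant.
#' @return a [query_term_set()].
#' @export
read_query_terms <- function(path, canonical_name = NULL) {
  if (!file.exists(path)) .stopf("query file does not exist: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  query_term_set(canonical_name %||% lines[1L], lines)
}

#' Select accounts whose profile mentions a disease name
#'
#' Keeps exactly the accounts whose normalized profile text contains any
#' normalized query variant as a substring, preserving corpus order. This
#' is the account-selection step of the pipeline: per-disease networks are
#' built from the accounts matched by that disease's query set.
#'
#' @param corpus a `cooc_corpus`.
#' @param query a [query_term_set()].
#' @return a `cooc_corpus` containing the matching accounts; its metadata
#'   records the query's canonical name. Idempotent: searching the result
#'   again returns the same accounts.
#' @export
search_profiles <- function(corpus, query) {
  stopifnot(inherits(corpus, "cooc_corpus"),
            inherits(query, "query_term_set"))
  pats <- normalize_text(query$variants)
  profs <- normalize_text(vapply(corpus$accounts, `[[`, character(1),
                                 "profile_text"))
  hit <- rep(FALSE, length(profs))
  for (p in pats) {
    hit <- hit | stringi::stri_detect_fixed(profs, p)
  }
  meta <- corpus$metadata
  meta$query <- query$canonical_name
  corpus(unname(corpus$accounts[hit]), meta)
}

#' Keep only the newest tweets of an account
#'
#' Emulates the harvest cap: at most `cap` tweets, the newest by
#' `posted_at`, are retained per account (default 200). Ties are broken by
#' the account's original record order, so the result is deterministic.
#'
#' @param account a `cooc_account`.
#' @param cap positive integer, default 200.
#' @return the account with at most `cap` tweets. Idempotent.
#' @export
cap_latest_tweets <- function(account, cap = 200L) {
  stopifnot(inherits(account, "cooc_account"))
  if (!.is_count(cap)) .stopf("cap must be a positive integer")
  if (nrow(account$tweets) > cap) {
    account$tweets <- account$tweets[seq_len(cap), , drop = FALSE]
  }
  account
}

#' Cap every account of a corpus
#'
#' @param corpus a `cooc_corpus`.
#' @param cap per-account tweet cap, default 200.
#' @return corpus with each account capped via [cap_latest_tweets()].
#' @export
cap_corpus <- function(corpus, cap = 200L) {
  stopifnot(inherits(corpus, "cooc_corpus"))
  corpus$accounts <- lapply(corpus$accounts, cap_latest_tweets, cap = cap)
  corpus
}
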