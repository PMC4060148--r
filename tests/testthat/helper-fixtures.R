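# Shared fixtures and independent oracles for the test suite.

# --- tiny hand dictionaries -------------------------------------------------

demo_dictionary <- function() {
  term_dictionary(data.frame(
    surface = c("went", "ct", "scan", "home", "nice"),
    lemma = c("go", "CT", "scan", "home", "nice"),
    pos = c("verb", "noun", "noun", "noun", "adjective"),
    stringsAsFactors = FALSE))
}

demo_synonyms <- function() {
  synonym_map(data.frame(variant = "tumour", canonical = "tumor",
                         stringsAsFactors = FALSE))
}

# Account with one line of noun lemmas per entry of `lines`.
nl <- function(id, ...) noun_lines(id, list(...))

make_account <- function(id, profile = "", texts = character(0),
                         base = "2013-08-18T12:00:00Z") {
  if (!length(texts)) return(account(id, profile))
  t0 <- as.POSIXct(base, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  stamps <- format(t0 - (seq_along(texts) - 1) * 60,
                   "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  account(id, profile, data.frame(text = texts, posted_at = stamps,
                                  stringsAsFactors = FALSE))
}

# --- independent oracles ----------------------------------------------------

# Naive triple-loop account-level pair counting: accounts x lines x pairs,
# no set tricks. The reference for count_pair_accounts().
oracle_pair_counts <- function(all_noun_lines) {
  env <- new.env(parent = emptyenv())
  for (nlx in all_noun_lines) {
    seen <- character(0)
    for (line in nlx$lines) {
      u <- unique(line)
      if (length(u) < 2) next
      for (i in seq_len(length(u) - 1)) {
        for (j in (i + 1):length(u)) {
          a <- min(u[i], u[j]); b <- max(u[i], u[j])
          key <- paste(a, b, sep = "\u001f")
          if (!key %in% seen) seen <- c(seen, key)
        }
      }
    }
    for (key in seen) {
      env[[key]] <- (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
    }
  }
  keys <- sort(ls(env))
  counts <- vapply(keys, function(k) env[[k]], integer(1))
  parts <- do.call(rbind, strsplit(keys, "\u001f", fixed = TRUE))
  if (is.null(parts)) {
    return(data.frame(word1 = character(0), word2 = character(0),
                      account_count = integer(0), stringsAsFactors = FALSE))
  }
  data.frame(word1 = parts[, 1], word2 = parts[, 2],
             account_count = unname(counts), stringsAsFactors = FALSE,
             row.names = NULL)
}

# Canonicalize a pair-count data frame for comparison.
sort_counts <- function(df) {
  df <- as.data.frame(df)[c("word1", "word2", "account_count")]
  df <- df[order(df$word1, df$word2), , drop = FALSE]
  rownames(df) <- NULL
  df$account_count <- as.integer(df$account_count)
  df
}

# Random noun-lines corpora for property tests.
random_noun_lines <- function(n_accounts, max_lines = 10, max_words = 6,
                              vocab = letters[1:8]) {
  lapply(seq_len(n_accounts), function(i) {
    n_lines <- sample.int(max_lines, 1)
    noun_lines(sprintf("acc%03d", i), lapply(seq_len(n_lines), function(l) {
      sample(vocab, sample.int(max_words, 1), replace = TRUE)
    }))
  })
}

# Root of the two-node force balance k_s d^3 - k_s L d^2 - k_r = 0:
# the independent closed-form oracle for the spring-layout equilibrium.
two_node_equilibrium <- function(ks, L, kr) {
  stats::uniroot(function(d) ks * d^3 - ks * L * d^2 - kr,
                 c(1e-9, 1e3), tol = 1e-12)$root
}

# Small generator configuration for fast end-to-end tests.
small_config <- function(seed = 11, topics = NULL, ...) {
  topics <- topics %||% list(
    topic_spec("alpha", "alpha disease", c("apple", "berry", "cherry")),
    topic_spec("beta", "beta disease", c("delta", "echo", "fox")))
  generator_config(topics = topics, accounts_per_topic = 10,
                   tweets_per_account = c(5, 10), noise_vocab_size = 20,
                   seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
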