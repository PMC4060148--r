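# Seeded synthetic corpus generator with planted topical co-occurrence
# structure. Stands in for a live-harvested tweet collection so every
# downstream stage is testable offline.

#' Define a synthetic topic
#'
#' A topic emulates one disease population: member profiles embed one of
#' `profile_variants`, and member tweets carry lines drawn from the topic's
#' keyword vocabulary at an elevated rate, planting co-occurrence between
#' every pair of topic keywords.
#'
#' @param name topic label (used in account ids and in per-topic queries).
#' @param profile_variants character vector; one is embedded into each
#'   member profile. Also serve as the topic's query variants.
#' @param keywords character vector of at least 2 topical words (canonical
#'   lemma form; ASCII-safe, no internal whitespace).
#' @param weights positive sampling weights, one per keyword (default
#'   uniform).
#' @param keyword_line_rate probability in `[0, 1]` that a generated tweet
#'   line is topical rather than pure noise (default 0.8).
#' @return object of class `topic_spec`.
#' @export
topic_spec <- function(name, profile_variants, keywords, weights = NULL,
                       keyword_line_rate = 0.8) {
  keywords <- as.character(keywords)
  if (length(keywords) < 2L) .stopf("topic '%s' needs >= 2 keywords", name)
  if (anyDuplicated(keywords)) .stopf("topic '%s' has duplicate keywords",
                                      name)
  if (any(grepl("[[:space:].]", keywords))) {
    .stopf("topic '%s': keywords must not contain whitespace or periods",
           name)
  }
  profile_variants <- as.character(profile_variants)
  if (!length(profile_variants)) .stopf("topic '%s' needs profile variants",
                                        name)
  weights <- weights %||% rep(1, length(keywords))
  if (length(weights) != length(keywords) || any(weights <= 0)) {
    .stopf("topic '%s': weights must be positive, one per keyword", name)
  }
  if (!.is_prob(keyword_line_rate)) {
    .stopf("keyword_line_rate must be in [0, 1]")
  }
  structure(list(name = name, profile_variants = profile_variants,
                 keywords = keywords, weights = weights,
                 keyword_line_rate = keyword_line_rate),
            class = "topic_spec")
}

#' Generator configuration
#'
#' Bundles everything [generate_corpus()] needs. All randomness derives
#' from `seed`, so a configuration is a complete, reproducible description
#' of a corpus.
#'
#' Tweet text is assembled as 1+ period-terminated lines of space-delimited
#' words and must fit the 140-character platform limit; configurations
#' whose longest possible line cannot fit are rejected up front.
#'
#' @param topics list of [topic_spec()] objects.
#' @param accounts_per_topic accounts generated per topic (default 50).
#' @param tweets_per_account integer range `c(min, max)`, max <= 200
#'   (default `c(10, 30)`).
#' @param lines_per_tweet integer range `c(min, max)` (default `c(1, 3)`).
#' @param words_per_line integer range `c(min, max)` (default `c(2, 4)`);
#'   topical lines always carry at least 2 topic keywords.
#' @param noise_vocab_size size of the shared background vocabulary
#'   (default 80).
#' @param noise_rate probability in `[0, 1]` that a word slot beyond the
#'   two guaranteed keywords of a topical line is a noise word; pure noise
#'   lines ignore it (default 0.3).
#' @param synonym_variants named list: canonical keyword ->
#'   `list(variants = <chr>, prob = <num>)`. Each occurrence of the
#'   canonical keyword is replaced by a random surface variant with the
#'   given probability, so synonym merging has real work to undo.
#' @param seed integer generation seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(topics,
                             accounts_per_topic = 50L,
                             tweets_per_account = c(10L, 30L),
                             lines_per_tweet = c(1L, 3L),
                             words_per_line = c(2L, 4L),
                             noise_vocab_size = 80L,
                             noise_rate = 0.3,
                             synonym_variants = list(),
                             seed = 1L) {
  if (inherits(topics, "topic_spec")) topics <- list(topics)
  ok <- vapply(topics, inherits, logical(1), what = "topic_spec")
  if (!length(topics) || !all(ok)) .stopf("topics must be topic_spec objects")
  if (!.is_count(accounts_per_topic, min = 0L)) {
    .stopf("accounts_per_topic must be a non-negative integer")
  }
  .check_range <- function(r, nm, lo = 1L, hi = Inf) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1L] > r[2L] ||
        r[1L] < lo || r[2L] > hi || any(r != as.integer(r))) {
      .stopf("%s must be an integer range c(min, max) within [%s, %s]",
             nm, lo, hi)
    }
  }
  .check_range(tweets_per_account, "tweets_per_account", 1L, 200L)
  .check_range(lines_per_tweet, "lines_per_tweet", 1L)
  .check_range(words_per_line, "words_per_line", 1L)
  if (!.is_count(noise_vocab_size, min = 0L)) {
    .stopf("noise_vocab_size must be a non-negative integer")
  }
  if (!.is_prob(noise_rate)) .stopf("noise_rate must be in [0, 1]")
  for (nm in names(synonym_variants)) {
    sv <- synonym_variants[[nm]]
    if (is.null(sv$variants) || !length(sv$variants) || !.is_prob(sv$prob)) {
      .stopf("synonym_variants[['%s']] needs variants and prob in [0, 1]",
             nm)
    }
  }
  cfg <- structure(
    list(topics = topics, accounts_per_topic = as.integer(accounts_per_topic),
         tweets_per_account = as.integer(tweets_per_account),
         lines_per_tweet = as.integer(lines_per_tweet),
         words_per_line = as.integer(words_per_line),
         noise_vocab_size = as.integer(noise_vocab_size),
         noise_rate = noise_rate,
         synonym_variants = synonym_variants,
         seed = as.integer(seed)),
    class = "generator_config")
  # Feasibility: the widest line (max words of the longest word) must fit
  # in a 140-character tweet together with its terminating period.
  vocab <- c(.generator_vocabulary(cfg), .noise_vocab(cfg$noise_vocab_size))
  wmax <- max(nchar(vocab))
  nmax <- max(cfg$words_per_line[2L], 2L)
  if (nmax * wmax + (nmax - 1L) + 1L > 140L) {
    .stopf(paste0("infeasible configuration: %d words of up to %d chars ",
                  "per line cannot fit a 140-character tweet"), nmax, wmax)
  }
  cfg
}

# Every surface form the generator can emit for topical words.
.generator_vocabulary <- function(config) {
  kw <- unique(unlist(lapply(config$topics, `[[`, "keywords")))
  vars <- unique(unlist(lapply(config$synonym_variants, `[[`, "variants")))
  c(kw, vars)
}

.noise_vocab <- function(n) {
  if (n == 0L) return(character(0))
  sprintf("noise%03d", seq_len(n))
}

#' Planted word pairs per topic
#'
#' The ground truth for recovery tests: for each topic, every unordered
#' pair of its keywords (the pairs the generator co-occurs at elevated
#' rate).
#'
#' @param config a [generator_config()].
#' @return named list (one element per topic) of two-column character
#'   matrices `word1`/`word2`, each row a lexicographically sorted pair.
#' @export
planted_pairs <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  out <- lapply(config$topics, function(tp) {
    kw <- sort(tp$keywords)
    pairs <- t(utils::combn(kw, 2L))
    colnames(pairs) <- c("word1", "word2")
    pairs
  })
  names(out) <- vapply(config$topics, `[[`, character(1), "name")
  out
}

# One generated line: a character vector of surface words.
.gen_line <- function(tp, config, noise) {
  nw <- sample(config$words_per_line[1L]:config$words_per_line[2L], 1L)
  topical <- stats::runif(1) < tp$keyword_line_rate
  if (topical) {
    nw <- max(nw, 2L)
    nkw <- min(length(tp$keywords), nw)
    kw <- sample(tp$keywords, nkw, prob = tp$weights)
    extra <- nw - nkw
    words <- kw
    if (extra > 0L && length(noise)) {
      # slots beyond the guaranteed keywords: noise with prob noise_rate
      take_noise <- stats::runif(extra) < config$noise_rate
      fill <- character(extra)
      fill[take_noise] <- sample(noise, sum(take_noise), replace = TRUE)
      fill[!take_noise] <- sample(tp$keywords, sum(!take_noise),
                                  replace = TRUE, prob = tp$weights)
      words <- c(words, fill)
    }
  } else {
    if (!length(noise)) return(character(0))
    words <- sample(noise, nw, replace = TRUE)
  }
  # synonym injection: canonical surfaces swapped for variants
  for (canon in names(config$synonym_variants)) {
    idx <- which(words == canon)
    if (!length(idx)) next
    sv <- config$synonym_variants[[canon]]
    swap <- stats::runif(length(idx)) < sv$prob
    if (any(swap)) {
      words[idx[swap]] <- sample(sv$variants, sum(swap), replace = TRUE)
    }
  }
  words
}

#' Generate a synthetic corpus
#'
#' Produces a seeded corpus in which each account belongs to one topic,
#' its profile embeds one of the topic's profile variants, and each tweet
#' is one or more period-terminated lines of space-delimited words. Topical
#' lines carry >= 2 topic keywords (planting pair co-occurrence); noise
#' lines draw from a shared background vocabulary. Timestamps are strictly
#' decreasing within each account, so tweet capping is deterministic.
#' Identical `(config, seed)` yields an identical corpus.
#'
#' @param config a [generator_config()].
#' @param seed overrides `config$seed` when given.
#' @return a [corpus()] whose metadata records the seed and topic names.
#' @export
generate_corpus <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  seed <- as.integer(seed %||% config$seed)
  noise <- .noise_vocab(config$noise_vocab_size)
  base_time <- as.POSIXct("2012-08-20 17:24:00", tz = "UTC")
  accounts <- withr::with_seed(seed, {
    acc <- vector("list", length(config$topics) * config$accounts_per_topic)
    ai <- 0L
    for (tp in config$topics) {
      for (i in seq_len(config$accounts_per_topic)) {
        ai <- ai + 1L
        variant <- tp$profile_variants[
          ((i - 1L) %% length(tp$profile_variants)) + 1L]
        profile <- sprintf("day by day living with %s | diary and notes",
                           variant)
        ntw <- sample(config$tweets_per_account[1L]:
                        config$tweets_per_account[2L], 1L)
        texts <- character(ntw)
        for (j in seq_len(ntw)) {
          nl <- sample(config$lines_per_tweet[1L]:
                         config$lines_per_tweet[2L], 1L)
          segs <- character(0)
          for (l in seq_len(nl)) {
            words <- .gen_line(tp, config, noise)
            if (!length(words)) next
            segs <- c(segs, paste0(paste(words, collapse = " "), "."))
          }
          if (!length(segs)) {
            # degenerate draw (noise line with empty noise vocab): fall
            # back to a minimal topical line
            kw <- sample(tp$keywords, 2L, prob = tp$weights)
            segs <- paste0(paste(kw, collapse = " "), ".")
          }
          # respect the platform limit by dropping trailing lines
          text <- segs[1L]
          for (s in segs[-1L]) {
            cand <- paste(text, s)
            if (nchar(cand) > 140L) break
            text <- cand
          }
          if (nchar(text) > 140L) {
            .stopf("infeasible configuration: generated line exceeds 140 chars")
          }
          texts[j] <- text
        }
        # strictly decreasing timestamps, newest first; offset per account
        stamps <- .format_time(base_time - (ai - 1L) * 86400 -
                                 (seq_len(ntw) - 1L) * 61)
        acc[[ai]] <- account(
          sprintf("%s_%03d", tp$name, i), profile,
          data.frame(text = texts, posted_at = stamps,
                     stringsAsFactors = FALSE))
      }
    }
    acc
  })
  corpus(accounts,
         metadata = list(
           generator = "coocnet synthetic corpus",
           seed = seed,
           topics = vapply(config$topics, `[[`, character(1), "name")))
}

#' Query term sets matching the generator's topics
#'
#' One [query_term_set()] per topic, whose variants are the topic's profile
#' variants — the queries that select exactly that topic's accounts from a
#' generated corpus.
#'
#' @param config a [generator_config()].
#' @return named list of query term sets.
#' @export
generator_queries <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  out <- lapply(config$topics, function(tp) {
    query_term_set(tp$name, tp$profile_variants)
  })
  names(out) <- vapply(config$topics, `[[`, character(1), "name")
  out
}

#' Term dictionary and synonym map for a generated corpus
#'
#' Builds the analysis-side resources that make the pipeline run end-to-end
#' on a synthetic corpus: every generator surface form (keywords, synonym
#' variants, noise words) is a noun whose lemma is itself, plus a small set
#' of function verbs/adjectives that noun extraction must discard; the
#' synonym map sends every injected variant back to its canonical keyword.
#'
#' @param config a [generator_config()].
#' @return `list(dictionary = <term_dictionary>, synonyms = <synonym_map>)`.
#' @export
generator_dictionaries <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  surfaces <- c(.generator_vocabulary(config),
                .noise_vocab(config$noise_vocab_size))
  surfaces <- unique(surfaces)
  dict_df <- data.frame(surface = surfaces, lemma = surfaces,
                        pos = "noun", stringsAsFactors = FALSE)
  syn_var <- character(0)
  syn_can <- character(0)
  for (canon in names(config$synonym_variants)) {
    vs <- config$synonym_variants[[canon]]$variants
    syn_var <- c(syn_var, vs)
    syn_can <- c(syn_can, rep(canon, length(vs)))
  }
  list(dictionary = term_dictionary(dict_df),
       synonyms = synonym_map(data.frame(variant = syn_var,
                                         canonical = syn_can,
                                         stringsAsFactors = FALSE)))
}

#' Topic specifications emulating six cancer populations
#'
#' Ready-made topics named after the six cancer groups of the motivating
#' study (breast, leukemia, uterine/cervical, lung, colon/colorectal,
#' stomach), with keyword vocabularies drawn from the shipped keyword
#' category dictionary (diagnosis, symptom, treatment and social terms).
#'
#' @param keyword_line_rate per-topic topical-line probability, default 0.8.
#' @return list of [topic_spec()] objects.
#' @export
cancer_topics <- function(keyword_line_rate = 0.8) {
  mk <- function(name, variants, kw) {
    topic_spec(name, variants, kw, keyword_line_rate = keyword_line_rate)
  }
  list(
    mk("breast_cancer",
       c("breast cancer", "乳がん"),
       c("self_diagnosis", "metastasis", "lymphedema", "chemotherapy",
         "hormone_therapy", "palliative_care", "pink_ribbon")),
    mk("leukemia",
       c("leukemia", "白血病"),
       c("liver_test", "foot_pain", "immunosuppression", "gvhd",
         "chemotherapy", "steroid", "transfusion", "platelet", "aml",
         "stem_cell_transplant")),
    mk("uterine_cervical_cancer",
       c("uterine cancer", "cervical cancer"),
       c("lymphedema", "education", "screening", "insurance",
         "vaccination", "official_support")),
    mk("lung_cancer",
       c("lung cancer", "肺がん"),
       c("ct", "metastasis", "shoulder_pain", "back_pain", "iressa",
         "side_effects", "anticancer_drug", "tarceva", "palliative_care")),
    mk("colon_colorectal_cancer",
       c("colon cancer", "colorectal cancer"),
       c("ct", "pet", "elplat", "side_effects", "chemotherapy", "diet",
         "nursing_care")),
    mk("stomach_cancer",
       c("stomach cancer", "胃がん"),
       c("ct", "mri", "tumor_marker", "lumbago", "ts1", "side_effects",
         "anticancer_drug", "iron"))
  )
}

#' Default generator configuration
#'
#' The reference study conditions used throughout the package's tests and
#' examples: six cancer-themed topics, 50 accounts per topic, 10–30 tweets
#' per account, 1–3 lines of 2–4 words per tweet, an 80-word background
#' vocabulary, topical-line rate 0.8, noise rate 0.3, and synonym variants
#' injected for three keywords.
#'
#' @param seed generation seed, default 1.
#' @param accounts_per_topic default 50.
#' @param keyword_line_rate default 0.8.
#' @param noise_rate default 0.3.
#' @param ... further overrides passed to [generator_config()].
#' @return a [generator_config()].
#' @export
default_generator_config <- function(seed = 1L, accounts_per_topic = 50L,
                                     keyword_line_rate = 0.8,
                                     noise_rate = 0.3, ...) {
  generator_config(
    topics = cancer_topics(keyword_line_rate = keyword_line_rate),
    accounts_per_topic = accounts_per_topic,
    noise_rate = noise_rate,
    synonym_variants = list(
      chemotherapy = list(variants = c("chemo", "kagakuryoho"), prob = 0.3),
      tumor_marker = list(variants = "tumour_marker", prob = 0.3),
      metastasis   = list(variants = "mets", prob = 0.3)
    ),
    seed = seed,
    ...)
}
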