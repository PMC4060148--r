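test_that("account_pair_set takes distinct pairs with set semantics", {
  expect_identical(account_pair_set(nl("a1", c("a", "b", "c"))),
                   matrix(c("a", "a", "b", "b", "c", "c"), ncol = 2,
                          dimnames = list(NULL, c("word1", "word2"))))
  # self-pairs excluded
  expect_identical(nrow(account_pair_set(nl("a2", c("a", "a")))), 0L)
  # union over lines, repeats collapse
  got <- account_pair_set(nl("a3", c("a", "b"), c("a", "b"), c("b", "c")))
  expect_identical(got, matrix(c("a", "b", "b", "c"), ncol = 2, byrow = TRUE,
                               dimnames = list(NULL, c("word1", "word2"))))
  # pair storage is order-free: (b, a) and (a, b) are the same pair
  expect_identical(account_pair_set(nl("a4", c("b", "a"))),
                   account_pair_set(nl("a4", c("a", "b"))))
})

test_that("count_pair_accounts counts accounts, not occurrences", {
  one <- count_pair_accounts(list(nl("x", c("a", "b"))))
  expect_identical(sort_counts(one),
                   data.frame(word1 = "a", word2 = "b", account_count = 1L,
                              stringsAsFactors = FALSE))

  # one account repeating a pair on 50 lines still counts once
  spam <- noun_lines("spam", rep(list(c("a", "b")), 50))
  expect_identical(count_pair_accounts(list(spam))$account_count, 1L)

  # the worked three-account example
  got <- count_pair_accounts(list(
    nl("A1", c("a", "b"), c("b", "c")),
    nl("A2", c("a", "b")),
    nl("A3", c("c", "d"))))
  expect_identical(sort_counts(got), data.frame(
    word1 = c("a", "b", "c"), word2 = c("b", "c", "d"),
    account_count = c(2L, 1L, 1L), stringsAsFactors = FALSE))

  expect_error(count_pair_accounts(list(nl("A", "a"), nl("A", "b"))),
               "duplicate")
  expect_identical(nrow(count_pair_accounts(list())), 0L)
})

test_that("count_pair_accounts equals the naive triple-loop oracle", {
  set.seed(71)
  for (rep in 1:60) {
    nls <- random_noun_lines(sample.int(20, 1))
    expect_identical(sort_counts(count_pair_accounts(nls)),
                     sort_counts(oracle_pair_counts(nls)))
  }
})

test_that("counts obey the account-level bounds and increment semantics", {
  set.seed(72)
  for (rep in 1:20) {
    nls <- random_noun_lines(sample.int(15, 1))
    counts <- count_pair_accounts(nls)
    if (!nrow(counts)) next
    # bound: count(p) <= accounts containing each member word
    word_acc <- table(unlist(lapply(nls, function(x)
      unique(unlist(x$lines)))))
    for (i in seq_len(nrow(counts))) {
      expect_lte(counts$account_count[i],
                 min(word_acc[[counts$word1[i]]], word_acc[[counts$word2[i]]]))
      expect_lte(counts$account_count[i], length(nls))
    }
    # duplicating every line within each account changes nothing
    doubled <- lapply(nls, function(x)
      noun_lines(x$account_id, c(x$lines, x$lines)))
    expect_identical(sort_counts(count_pair_accounts(doubled)),
                     sort_counts(counts))
    # a new account containing a pair increments it by exactly 1
    p <- counts[1, ]
    grown <- c(nls, list(nl("fresh", c(p$word1, p$word2))))
    counts2 <- count_pair_accounts(grown)
    row <- counts2[counts2$word1 == p$word1 & counts2$word2 == p$word2, ]
    expect_identical(row$account_count, p$account_count + 1L)
  }
})

test_that("select_top_k returns min(k, n) edges in deterministic order", {
  counts <- data.frame(word1 = c("a", "a", "b"), word2 = c("b", "c", "c"),
                       account_count = c(3L, 1L, 2L))
  expect_identical(nrow(select_top_k(counts, 100)), 3L)
  expect_identical(select_top_k(counts, 100)$account_count, c(3L, 2L, 1L))

  # 150 distinct counts, k = 100: the 100 largest, full-sort oracle
  set.seed(5)
  w <- sprintf("w%03d", 1:150)
  big <- data.frame(word1 = w, word2 = "zzz",
                    account_count = sample(1000L, 150L))
  top <- select_top_k(big, 100)
  expect_identical(nrow(top), 100L)
  expect_identical(top$account_count,
                   sort(big$account_count, decreasing = TRUE)[1:100])

  # lexicographic tie-break at the boundary
  ties <- data.frame(word1 = c("a", "a"), word2 = c("c", "b"),
                     account_count = c(5L, 5L))
  expect_identical(select_top_k(ties, 1)$word2, "b")
  # ... unless ties are included on request
  expect_identical(nrow(select_top_k(ties, 1, ties = "include")), 2L)
})

test_that("build_graph validates and assembles the network", {
  empty <- build_graph(select_top_k(
    count_pair_accounts(list()), 100))
  expect_length(empty$nodes, 0)
  expect_identical(nrow(empty$edges), 0L)

  g <- build_graph(data.frame(word1 = "a", word2 = "b",
                              account_count = 2L), k = 100)
  expect_identical(g$nodes, c("a", "b"))
  expect_identical(g$edges$account_count, 2L)

  dup <- data.frame(word1 = c("a", "b"), word2 = c("b", "a"),
                    account_count = c(1L, 1L))
  expect_error(build_graph(dup, k = 10), "duplicate")
  expect_error(build_graph(data.frame(word1 = "a", word2 = "a",
                                      account_count = 1L), k = 1),
               "self-loop")

  # node set is the union of edge endpoints
  set.seed(6)
  pairs <- t(combn(sprintf("n%02d", 1:60), 2))
  pick <- pairs[sample(nrow(pairs), 100), ]
  el <- data.frame(word1 = pmin(pick[, 1], pick[, 2]),
                   word2 = pmax(pick[, 1], pick[, 2]),
                   account_count = sample(50L, 100L, TRUE))
  g60 <- build_graph(select_top_k(el, 100))
  expect_identical(nrow(g60$edges), 100L)
  expect_setequal(g60$nodes, unique(c(el$word1, el$word2)))
  # every node incident to >= 1 edge
  expect_setequal(g60$nodes, unique(c(g60$edges$word1, g60$edges$word2)))
})

test_that("planted pairs out-rank noise pairs in a seeded synthetic corpus", {
  cfg <- small_config(seed = 31)
  co <- generate_corpus(cfg)
  dicts <- generator_dictionaries(cfg)
  counts <- count_pair_accounts(
    process_corpus(co, dicts$dictionary, dicts$synonyms))
  planted <- do.call(rbind, planted_pairs(cfg))
  pk <- paste(planted[, 1], planted[, 2])
  ck <- paste(counts$word1, counts$word2)
  noise_pair <- grepl("^noise", counts$word1) & grepl("^noise", counts$word2)
  expect_gt(min(counts$account_count[ck %in% pk]),
            max(counts$account_count[noise_pair]))
})
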