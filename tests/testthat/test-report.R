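demo_graph <- function() {
  build_graph(data.frame(word1 = c("ct", "ct"), word2 = c("mri", "scan"),
                         account_count = c(5L, 2L)), k = 100)
}

test_that("GraphML export round-trips through an independent parser", {
  skip_if_not_installed("igraph")
  g <- demo_graph()
  lay <- relax(g, layout_params(seed = 1, max_iterations = 500))
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(g, lay, path)

  ig <- igraph::read_graph(path, format = "graphml")
  expect_false(igraph::is_directed(ig))
  expect_identical(as.integer(igraph::vcount(ig)), 3L)
  expect_identical(as.integer(igraph::ecount(ig)), 2L)
  ids <- igraph::vertex_attr(ig, "id")
  expect_setequal(ids, g$nodes)
  el <- igraph::as_edgelist(ig, names = FALSE)
  from <- ids[el[, 1]]
  to <- ids[el[, 2]]
  got <- data.frame(
    word1 = pmin(from, to), word2 = pmax(from, to),
    account_count = as.integer(igraph::edge_attr(ig, "account_count")),
    stringsAsFactors = FALSE)
  got <- got[order(got$word1, got$word2), ]
  rownames(got) <- NULL
  want <- g$edges[order(g$edges$word1, g$edges$word2), ]
  rownames(want) <- NULL
  expect_identical(got, want)
  # coordinates survive
  xs <- igraph::vertex_attr(ig, "x")
  expect_equal(sort(xs), sort(unname(lay$positions[, 1])), tolerance = 1e-6)
})

test_that("GraphML export handles the empty graph and counts edge elements", {
  empty <- build_graph(data.frame(word1 = character(0),
                                  word2 = character(0),
                                  account_count = integer(0)), k = 100)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(empty, NULL, path)
  doc <- xml2::read_xml(path)
  expect_identical(xml2::xml_length(xml2::xml_find_first(doc, ".//d1:graph",
                                                         xml2::xml_ns(doc))),
                   0L)

  # an n-edge graph writes exactly n <edge> elements
  set.seed(8)
  el <- data.frame(word1 = sprintf("a%02d", rep(1:10, each = 3)),
                   word2 = sprintf("b%02d", 1:30),
                   account_count = sample(9L, 30L, TRUE))
  g <- build_graph(select_top_k(el, 100))
  lay <- initial_placement(g$nodes, 1)
  export_graphml(g, lay, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, ".//d1:edge", ns), 30)
  expect_length(xml2::xml_find_all(doc, ".//d1:node", ns), 40)
})

test_that("the shipped category dictionary reproduces the printed columns", {
  cats <- read_category_dictionary()
  g <- demo_graph()  # nodes ct, mri, scan
  rep_stomach <- categorize_keywords(g, cats, cancer = "stomach_cancer")
  expect_identical(
    rep_stomach$category[rep_stomach$keyword == "ct"],
    factor("diagnosis", levels = levels(rep_stomach$category)))
  expect_identical(
    as.character(rep_stomach$category[rep_stomach$keyword == "scan"]),
    "unclassified")

  gb <- build_graph(data.frame(word1 = "lymphedema", word2 = "metastasis",
                               account_count = 3L), k = 10)
  rep_breast <- categorize_keywords(gb, cats, cancer = "breast_cancer")
  expect_identical(as.character(rep_breast$category),
                   c("symptoms", "symptoms"))

  # every fixture keyword lands in its printed column for its cancer
  for (cancer in unique(cats$cancer)) {
    rows <- cats[cats$cancer == cancer, ]
    gg <- build_graph(data.frame(word1 = unique(rows$keyword),
                                 word2 = "zzz_probe",
                                 account_count = 1L), k = 1000)
    got <- categorize_keywords(gg, cats, cancer = cancer)
    for (i in seq_len(nrow(rows))) {
      expect_true(any(got$keyword == rows$keyword[i] &
                        as.character(got$category) ==
                          as.character(rows$category[i])),
                  label = sprintf("%s/%s -> %s", cancer, rows$keyword[i],
                                  rows$category[i]))
    }
  }
})

test_that("category report groups rows in report column order", {
  cats <- read_category_dictionary()
  g <- build_graph(data.frame(
    word1 = c("pink_ribbon", "chemotherapy", "self_diagnosis"),
    word2 = c("metastasis", "metastasis", "metastasis"),
    account_count = c(1L, 2L, 3L)), k = 10)
  rep <- categorize_keywords(g, cats, cancer = "breast_cancer")
  expect_identical(as.character(unique(rep$category)),
                   c("diagnosis", "symptoms", "treatments", "others"))
  smry <- summarize_categories(rep)
  expect_identical(smry$keywords[smry$category == "others"], "pink_ribbon")
})

test_that("run_pipeline equals manual stage composition and writes exports", {
  cfg <- small_config(seed = 41)
  co <- generate_corpus(cfg)
  dicts <- generator_dictionaries(cfg)
  out <- withr::local_tempdir()
  rc <- run_config(co, generator_queries(cfg), dicts$dictionary,
                   dicts$synonyms, k = 25, tweet_cap = 200,
                   layout = layout_params(max_iterations = 800),
                   out_dir = out, seed = 5)
  res <- run_pipeline(rc)

  # manual composition for one topic
  q <- generator_queries(cfg)$alpha
  sub <- cap_corpus(search_profiles(co, q), 200)
  counts <- count_pair_accounts(
    process_corpus(sub, dicts$dictionary, dicts$synonyms))
  edges <- select_top_k(counts, 25)
  expect_identical(res$alpha$graph, build_graph(edges))
  lp <- layout_params(max_iterations = 800)
  lp$seed <- 5 + 1
  lay <- reduce_overlap(relax(res$alpha$graph, lp), res$alpha$graph, 0.05)
  expect_identical(res$alpha$layout$positions, lay$positions)

  # exports and manifest exist and are internally consistent
  expect_true(file.exists(file.path(out, "alpha_edges.tsv")))
  expect_true(file.exists(file.path(out, "alpha.graphml")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  man <- jsonlite::fromJSON(file.path(out, "manifest.json"),
                            simplifyVector = TRUE)
  for (qn in names(man$queries)) {
    st <- man$queries[[qn]]
    expect_lte(st$accounts_with_noun_lines, st$accounts_matched)
    expect_lte(st$edges, rc$k)
    expect_identical(st$edges, res[[qn]]$stats$edges)
  }
})

test_that("run_pipeline warns but succeeds when nothing matches", {
  cfg <- small_config(seed = 42)
  co <- generate_corpus(cfg)
  dicts <- generator_dictionaries(cfg)
  rc <- run_config(co, query_term_set("ghost", "no such profile"),
                   dicts$dictionary, dicts$synonyms, seed = 1)
  expect_warning(res <- run_pipeline(rc), "empty network")
  expect_length(res$ghost$graph$nodes, 0)
})

test_that("seeded pipeline runs are byte-identical", {
  cfg <- small_config(seed = 43)
  co <- generate_corpus(cfg)
  dicts <- generator_dictionaries(cfg)
  outs <- character(2)
  for (i in 1:2) {
    out <- file.path(withr::local_tempdir(), paste0("run", i))
    rc <- run_config(co, generator_queries(cfg), dicts$dictionary,
                     dicts$synonyms, k = 25,
                     layout = layout_params(max_iterations = 500),
                     out_dir = out, seed = 9)
    run_pipeline(rc)
    outs[i] <- out
  }
  for (f in list.files(outs[1])) {
    b1 <- readBin(file.path(outs[1], f), "raw", file.size(file.path(outs[1], f)))
    b2 <- readBin(file.path(outs[2], f), "raw", file.size(file.path(outs[2], f)))
    expect_identical(b1, b2, label = f)
  }
})
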