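# Pipeline driver, GraphML/TSV export, and the keyword category report.

.CATEGORY_LEVELS <- c("diagnosis", "symptoms", "treatments", "others")

#' Read a keyword category dictionary
#'
#' TSV with columns `cancer`, `keyword`, `category`, `label` (`#` comments
#' allowed): per cancer type, the assignment of canonical keyword lemmas to
#' one of the four report columns `diagnosis`, `symptoms`, `treatments`,
#' `others`. A keyword may legitimately appear under more than one category
#' (e.g. a drug listed both as a symptom context and a treatment). The
#' package ships a fixture at
#' `system.file("extdata", "keyword_categories.tsv", package = "coocnet")`
#' covering the six cancer topics of [cancer_topics()].
#'
#' @param path TSV path; default the shipped fixture.
#' @return object of class `category_dictionary` (a data frame with an
#'   ordered `category` factor).
#' @export
read_category_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "keyword_categories.tsv",
                                package = "coocnet")
  df <- .read_tsv(path, c("cancer", "keyword", "category", "label"))
  bad <- !df$category %in% .CATEGORY_LEVELS
  if (any(bad)) .stopf("invalid category '%s' (allowed: %s)",
                       df$category[which(bad)[1L]],
                       paste(.CATEGORY_LEVELS, collapse = ", "))
  df$keyword <- normalize_text(df$keyword)
  df$category <- factor(df$category, levels = .CATEGORY_LEVELS)
  class(df) <- c("category_dictionary", "data.frame")
  df
}

#' Categorize the nodes of a co-occurrence network
#'
#' Each graph node is looked up (NFKC-normalized, case-folded) in the
#' category dictionary, optionally restricted to one cancer type. Nodes
#' absent from the dictionary are reported as `unclassified`; nodes listed
#' under several categories yield one row per category.
#'
#' @param graph a [build_graph()] result.
#' @param cats a [read_category_dictionary()] result.
#' @param cancer optional cancer label restricting the lookup to that
#'   cancer's rows.
#' @return data frame `keyword`, `category`, rows grouped by category in
#'   report column order (`diagnosis`, `symptoms`, `treatments`, `others`,
#'   then `unclassified`), keywords sorted within a category.
#' @export
categorize_keywords <- function(graph, cats = read_category_dictionary(),
                                cancer = NULL) {
  stopifnot(inherits(graph, "cooc_graph"),
            inherits(cats, "category_dictionary"))
  if (!is.null(cancer)) cats <- cats[cats$cancer == cancer, , drop = FALSE]
  nodes <- normalize_text(graph$nodes)
  rows <- list()
  for (node in nodes) {
    hit <- cats[cats$keyword == node, , drop = FALSE]
    if (nrow(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        keyword = node, category = as.character(unique(hit$category)),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        keyword = node, category = "unclassified", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(keyword = character(0), category = character(0),
               stringsAsFactors = FALSE)
  out$category <- factor(out$category,
                         levels = c(.CATEGORY_LEVELS, "unclassified"))
  out <- out[order(out$category, out$keyword), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a category report into one row per category
#'
#' @param report a [categorize_keywords()] result.
#' @return data frame `category`, `n`, `keywords` (comma-joined).
#' @export
summarize_categories <- function(report) {
  sp <- split(report$keyword, report$category)
  data.frame(
    category = names(sp),
    n = vapply(sp, length, integer(1)),
    keywords = vapply(sp, function(x) paste(sort(unique(x)), collapse = ", "),
                      character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Export a laid-out network as GraphML
#'
#' Writes schema-conformant GraphML (graphml.graphdrawing.org): an
#' undirected graph whose nodes carry decimal attributes `x`, `y` and whose
#' edges carry the integer attribute `account_count`. Output is
#' byte-deterministic for identical inputs; re-importing (e.g. with igraph)
#' yields an isomorphic weighted graph.
#'
#' @param graph a [build_graph()] result.
#' @param layout a `cooc_layout` covering all graph nodes (NULL only for
#'   the empty graph).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
export_graphml <- function(graph, layout, path) {
  stopifnot(inherits(graph, "cooc_graph"))
  n <- length(graph$nodes)
  if (n > 0L) {
    stopifnot(inherits(layout, "cooc_layout"),
              all(graph$nodes %in% rownames(layout$positions)))
  }
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  for (key in list(c("d_x", "node", "x", "double"),
                   c("d_y", "node", "y", "double"),
                   c("d_w", "edge", "account_count", "int"))) {
    xml2::xml_add_child(doc, "key", id = key[1L], "for" = key[2L],
                        attr.name = key[3L], attr.type = key[4L])
  }
  g <- xml2::xml_add_child(doc, "graph", id = "cooc",
                           edgedefault = "undirected")
  for (node in graph$nodes) {
    nd <- xml2::xml_add_child(g, "node", id = node)
    xml2::xml_add_child(nd, "data", key = "d_x",
                        sprintf("%.8f", layout$positions[node, 1L]))
    xml2::xml_add_child(nd, "data", key = "d_y",
                        sprintf("%.8f", layout$positions[node, 2L]))
  }
  if (nrow(graph$edges)) {
    for (e in seq_len(nrow(graph$edges))) {
      ed <- xml2::xml_add_child(g, "edge",
                                source = graph$edges$word1[e],
                                target = graph$edges$word2[e])
      xml2::xml_add_child(ed, "data", key = "d_w",
                          sprintf("%d", as.integer(graph$edges$account_count[e])))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param corpus a `cooc_corpus` or a JSON-Lines corpus path.
#' @param queries named list of [query_term_set()] (one network is built
#'   per query set, from the accounts it matches).
#' @param dictionary a [term_dictionary()].
#' @param synonyms a [synonym_map()].
#' @param categories a [read_category_dictionary()] result, or NULL to skip
#'   category reports.
#' @param k top-K edge threshold, default 100.
#' @param ties `"cut"` or `"include"`, see [select_top_k()].
#' @param tweet_cap per-account cap on the newest tweets, default 200.
#' @param layout a [layout_params()].
#' @param min_separation node separation target of [reduce_overlap()].
#' @param out_dir output directory (created if missing), or NULL to skip
#'   all file exports.
#' @param seed run seed; per-query layout seeds are derived from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(corpus, queries, dictionary,
                       synonyms = synonym_map(), categories = NULL,
                       k = 100L, ties = c("cut", "include"),
                       tweet_cap = 200L, layout = layout_params(),
                       min_separation = 0.05, out_dir = NULL, seed = 1L) {
  ties <- match.arg(ties)
  if (is.character(corpus)) corpus <- read_corpus(corpus)
  stopifnot(inherits(corpus, "cooc_corpus"),
            inherits(dictionary, "term_dictionary"),
            inherits(synonyms, "synonym_map"),
            inherits(layout, "layout_params"))
  if (inherits(queries, "query_term_set")) queries <- list(queries)
  ok <- vapply(queries, inherits, logical(1), what = "query_term_set")
  if (!length(queries) || !all(ok)) {
    .stopf("queries must be query_term_set objects")
  }
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    names(queries) <- vapply(queries, `[[`, character(1), "canonical_name")
  }
  if (!.is_count(k)) .stopf("k must be a positive integer")
  if (!.is_count(tweet_cap)) .stopf("tweet_cap must be a positive integer")
  structure(list(corpus = corpus, queries = queries,
                 dictionary = dictionary, synonyms = synonyms,
                 categories = categories, k = as.integer(k), ties = ties,
                 tweet_cap = as.integer(tweet_cap), layout = layout,
                 min_separation = min_separation, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

.safe_name <- function(x) gsub("[^A-Za-z0-9_.-]+", "_", x)

#' Run the full pipeline
#'
#' For each query set: profile search, tweet capping, noun-line extraction,
#' account-level pair counting, top-K selection, graph construction, spring
#' relaxation and overlap reduction — then TSV/GraphML/category exports and
#' a machine-readable run manifest. Deterministic for a given seed. Query
#' sets matching no profile produce an empty network with a warning.
#'
#' @param config a [run_config()].
#' @return invisibly, a named list with one element per query:
#'   `list(graph, layout, counts, report, stats)`, plus the manifest under
#'   the attribute `"manifest"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  results <- list()
  manifest <- list(seed = config$seed, k = config$k, ties = config$ties,
                   tweet_cap = config$tweet_cap,
                   layout = unclass(config$layout), queries = list())
  qi <- 0L
  for (qname in names(config$queries)) {
    qi <- qi + 1L
    query <- config$queries[[qname]]
    matched <- search_profiles(config$corpus, query)
    capped <- cap_corpus(matched, config$tweet_cap)
    nls <- process_corpus(capped, config$dictionary, config$synonyms)
    counts <- count_pair_accounts(nls)
    edges <- select_top_k(counts, k = config$k, ties = config$ties)
    graph <- build_graph(edges)
    if (length(graph$nodes) == 0L) {
      warning(sprintf("query '%s': no co-occurring pairs; empty network",
                      qname), call. = FALSE)
      lay <- NULL
    } else {
      lp <- config$layout
      lp$seed <- config$seed + qi   # distinct but derived layout seed
      lay <- relax(graph, lp)
      lay <- reduce_overlap(lay, graph, config$min_separation)
    }
    report <- if (!is.null(config$categories)) {
      categorize_keywords(graph, config$categories, cancer = qname)
    }
    n_contrib <- sum(vapply(nls, function(x) length(x$lines) > 0L,
                            logical(1)))
    stats <- list(
      accounts_matched = length(matched$accounts),
      accounts_with_noun_lines = n_contrib,
      distinct_pairs = nrow(counts),
      edges = nrow(graph$edges),
      nodes = length(graph$nodes),
      layout_iterations = if (is.null(lay)) 0L else lay$iterations_used,
      layout_residual = if (is.null(lay)) NA else lay$residual)
    manifest$queries[[qname]] <- stats
    if (!is.null(out_dir)) {
      stem <- file.path(out_dir, .safe_name(qname))
      write_edge_list(graph$edges, paste0(stem, "_edges.tsv"))
      export_graphml(graph, lay, paste0(stem, ".graphml"))
      if (!is.null(report)) {
        utils::write.table(report, paste0(stem, "_categories.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           fileEncoding = "UTF-8")
      }
    }
    results[[qname]] <- list(graph = graph, layout = lay, counts = counts,
                             report = report, stats = stats)
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(results, "manifest") <- manifest
  invisible(results)
}
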