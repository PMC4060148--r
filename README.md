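# coocnet

Keyword co-occurrence networks from per-account collections of short
messages (tweets), for infodemiology and health social-media mining: given
accounts selected because their free-text profile mentions a disease, the
package distils their tweets into the keyword pairs patients actually
discuss together — diagnoses, symptoms, treatments — and draws them as a
weighted network.

## The statistic and the model

The pipeline turns each account's tweets into *noun lines*: tweets are
split into lines at sentence-final periods (`.` and `。`), each line is
tokenized against a term dictionary (a pluggable contract; the default is
a greedy longest-match dictionary tokenizer, and a morphological analyzer
for Japanese can be plugged in), tokens are reduced to noun lemmas —
verbs and adjectives are deliberately discarded — and synonymous lemmas
are merged to one canonical form.

The edge weight is an **account-level co-occurrence count**. For an
unordered word pair {w₁, w₂},

> count(w₁, w₂) = #{ accounts in which w₁ and w₂ appear together on at
> least one tweet line }

— the number of *accounts*, not the number of co-occurrences. An account
that repeats a pair on fifty lines contributes exactly 1, so a single
hyper-active account cannot push its private vocabulary into the network.
The K pairs with the largest counts (default K = 100; ties at the
boundary cut lexicographically, or kept with `ties = "include"`) become
the links of an undirected network whose nodes are the words themselves.

The drawing is a **spring model** computed from scratch: every edge is a
spring obeying Hooke's law with force magnitude k_s·(d − L) at length d,
every node pair repels with Coulomb magnitude k_r/d², and the layout is
the equilibrium reached by damped relaxation (adaptive step halving on
overshoot). For two connected nodes the equilibrium distance is the real
root of k_s·d³ − k_s·L·d² − k_r = 0, which the test suite uses as a
closed-form oracle.

Because the original data came from a live service, the package ships a
seeded synthetic corpus generator that emulates the relevant structure:
per-disease account populations whose profiles embed the disease name,
at most 200 tweets per account, tweets of at most 140 characters, topical
keyword vocabularies whose pairs co-occur on tweet lines at an elevated
rate against a noise vocabulary, and injected synonym variants for the
merge step to undo. Planted pairs are known exactly, so recovery is
testable end to end.

## Worked example

```r
library(coocnet)

cfg   <- default_generator_config(seed = 1)   # 6 topics x 50 accounts
corp  <- generate_corpus(cfg)
corp
#> <cooc_corpus> 300 accounts, 6266 tweets

dicts  <- generator_dictionaries(cfg)
nls    <- process_corpus(corp, dicts$dictionary, dicts$synonyms)
counts <- count_pair_accounts(nls)
head(counts, 5)
#>             word1           word2 account_count
#> 1              ct    side_effects           145
#> 2 anticancer_drug              ct            97
#> 3      metastasis palliative_care           97
#> 4 anticancer_drug    side_effects           96
#> 5 anticancer_drug       back_pain           50

net <- build_graph(select_top_k(counts))      # top 100 pairs
net
#> <cooc_graph> 33 nodes, 100 edges (k = 100, ties = cut)

lay <- relax(net, layout_params(seed = 2))
lay
#> <cooc_layout> 33 nodes, residual 0.000549 after 10000 iterations
```

`ct` and `side_effects` co-occur in 145 of the 300 accounts: both words
belong to several topics, so their account count exceeds any single
topic's population — exactly the behavior the account-level count is
designed to expose. The relaxed layout can be exported together with the
network (`export_graphml(net, lay, "net.graphml")`), and the node
vocabulary summarized with the shipped keyword category dictionary:

```r
cats <- read_category_dictionary()
summarize_categories(categorize_keywords(net, cats))
#>     category  n  keywords
#> 1  diagnosis  6  ct, liver_test, mri, pet, self_diagnosis, tumor_marker
#> 2   symptoms 11  back_pain, elplat, immunosuppression, iressa, ...
#> 3 treatments  9  anticancer_drug, chemotherapy, diet, hormone_therapy, ...
#> 4     others 10  aml, education, insurance, nursing_care, ...
```

The full per-disease pipeline — profile search, tweet capping, noun
lines, counting, top-K, layout, exports and a JSON run manifest — is one
call: `run_pipeline(run_config(...))`, or from a shell via the thin
driver `inst/cli/cooc_tweets.R` (verbs `simulate`, `network`, `run`).

## Corpus file dialect

Corpora are JSON-Lines (UTF-8, one account per line):

```json
{"account_id":"breast_cancer_001","profile":"...","tweets":[{"text":"ct scan.","posted_at":"2012-08-20T17:24:00Z"}]}
```

An optional first line `{"corpus_metadata": {...}}` carries free-form
metadata (seed, query, retrieval window). Tweets are re-sorted
newest-first on read; timestamps are ISO-8601 UTC. Term dictionaries
(`surface<TAB>lemma<TAB>pos`), synonym maps (`variant<TAB>canonical`),
query variant lists and keyword categories are plain UTF-8 TSV/text with
`#` comments.

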