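---
title: "Account-level keyword co-occurrence networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Account-level keyword co-occurrence networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coocnet)
```

## The problem

Patients discuss their disease on microblogging platforms in short,
noisy, colloquial messages. Given a set of accounts selected because
their public profile mentions a disease name, we want a compact picture
of *what these accounts talk about together*: which examinations,
symptoms and treatments co-occur in the same breath. `coocnet`
implements that as a reusable pipeline — text normalization to noun
lines, an account-level pair statistic, top-K edge selection, and a
physical spring-model drawing — plus a synthetic corpus generator that
makes every stage testable without access to any live service.

## From tweets to noun lines

Each tweet is treated as a sequence of *lines*, split at sentence-final
periods. Both the ASCII period `"."` and the ideographic full stop
`"。"` delimit lines: Japanese text overwhelmingly uses the ideographic
stop, so restricting the rule to ASCII would make line-splitting vacuous
on the very data the method is aimed at. The delimiter set is a
parameter of `split_lines()` for corpora with other conventions.

Tokenization is a *contract*, not a fixed algorithm. The default backend
(`tokenize()`) scans the NFKC-normalized, case-folded line left to
right and consumes the longest dictionary surface starting at each
position; maximal whitespace-delimited chunks with no dictionary match
become fallback tokens tagged `other`. This reproduces the essential
data flow of a morphological analyzer — surface → lemma ("original
form") → part of speech — while remaining dependency-free; a real
analyzer (MeCab, Sudachi, ...) can be plugged in as any function
returning the same token shape. The four-class tag set
`noun/verb/adjective/other` is a deliberate simplification: the pipeline
only ever branches on "noun or not".

Only noun lemmas are kept. Verbs and adjectives are tagged but always
discarded: negation makes their polarity unreliable in 140 characters,
and they are a small minority of extracted terms. Synonym merging is a
flat variant → canonical map applied after lemma normalization; the map
is validated at load time to contain no chains or cycles, which makes
the merge idempotent and order-independent. Within-line duplicate nouns
are preserved at this stage — the downstream statistic makes
deduplication immaterial (see below).

## The account-level co-occurrence count

For an unordered pair of canonical lemmas, the weight is the number of
**accounts** in which the pair co-occurs on at least one line:

```
count(w1, w2) = |{ a : exists line ℓ in account a with {w1, w2} ⊆ ℓ }|
```

Counting accounts instead of raw co-occurrences is the method's central
choice: it bounds any single account's influence at 1, so a prolific
account tweeting about one specialized topic hundreds of times cannot
dominate the network. Two consequences are worth making explicit, and
both are enforced as properties in the test suite:

* duplicating every line inside an account changes no count;
* adding one new account containing a pair raises that pair's count by
  exactly 1.

Self-pairs (a word repeated on one line) are excluded — a combination
requires two distinct words — and whether duplicates within a line are
removed before pairing cannot affect the result, because membership of
the pair in the line is all that matters.

The top K pairs by count (default `k = 100`) become edges. Ranking ties
are broken lexicographically so selection is deterministic; ties
straddling the rank-K boundary are cut by default, and
`ties = "include"` keeps all tied pairs instead, recorded in the graph's
metadata. Word identity is NFKC-normalized and case-folded throughout,
so `CT`, `ct` and full-width `ＣＴ` are one node.

## The spring model

The drawing treats each edge as a spring with Hooke's-law restoring
force `k_s (d − L)` and every node pair as like charges with Coulomb
repulsion `k_r / d²`; the layout is the equilibrium of the summed
forces. Repulsion acts between *all* node pairs, springs only along
edges — the literal physical reading of the model.

No canonical constants exist for this system, so the defaults are
chosen to put the two-node equilibrium on an order-1 scale:
`k_s = 1`, `L = 1`, `k_r = 1`, which places two connected nodes at the
real root of `d³ − d² − 1 = 0 ≈ 1.4656`. That closed form (via
`uniroot` on the force-balance cubic) is the independent oracle for the
relaxation: the suite checks agreement across 20 random
`(k_s, L, k_r)` draws, and a triangle graph — whose symmetric
equilibrium satisfies the *same* cubic pairwise — for symmetry.

Numerical choices:

* **Initialization** is uniform in the unit square from a seeded
  generator; exact collisions are re-jittered. Everything downstream is
  deterministic in `(graph, params, seed)`.
* **Relaxation** is damped Euler: `position += step · force`. The step
  halves when the maximum per-node force grows by more than 5% — a
  genuine overshoot — and recovers by ×1.05 (never beyond the
  configured `step_size`) while the force descends. A literal
  halve-on-any-increase rule turned out to strangle the step during the
  initial transient: max-force jitter on a descending energy path
  triggers halvings about half the time and the step collapses below
  floating-point resolution, freezing the layout far from equilibrium.
  The 5% tolerance leaves the convergence contract intact (overshoot is
  still damped geometrically) while letting a ~100-edge network reach
  the default tolerance of `1e-4` in a few thousand iterations.
* **Termination** is `max force < force_tolerance` (default `1e-4`) or
  `max_iterations` (default 10 000); the returned layout records both
  the residual and the iterations used, and recomputing forces at the
  returned positions reproduces the residual (self-consistency).
* **Degenerate geometry**: inter-node distances are regularized at
  `1e-9` so coincident points exert finite forces; non-finite positions
  abort with a diagnostic rather than silently wandering.
* **Unboundedness**: the pure model has no equilibrium for a
  disconnected graph — components repel forever. A weak centering force
  `−c · position` (default `c = 0.01`) is enabled automatically for
  disconnected graphs only, and is recorded in the layout object. For
  connected graphs the default is no centering, keeping forces
  translation-invariant.
* **Overlap reduction** (`reduce_overlap()`) is a greedy symmetric
  push-apart pass replacing the manual nudging a human would do in a
  network editor; it guarantees a minimum pairwise separation, not any
  aesthetic optimum.

## The synthetic corpus generator

Live social-media data cannot ship with a package, so the generator
*is* the study population for all tests. What it emulates is
structural: per-disease account groups whose profiles embed a disease
name variant (including non-Latin scripts); at most 200 tweets per
account with strictly decreasing timestamps (making the harvest cap
deterministic); tweets of at most 140 characters composed of
period-terminated lines of space-delimited words; topical lines that
carry at least two topic keywords, planting co-occurrence between all
keyword pairs of the topic; a shared noise vocabulary; and synonym
surface variants substituted for canonical keywords at a configured
probability, so the merge step has real work to undo.

The reference conditions (`default_generator_config()`) are six
cancer-themed topics of 50 accounts each, 10–30 tweets per account, 1–3
lines of 2–4 words, an 80-word noise vocabulary, topical-line rate 0.8
and noise rate 0.3. Topic vocabularies (6–10 keywords each) are the
canonical lemmas of the shipped keyword category dictionary, so the
category report exercises realistic content. At these settings a
planted pair co-occurs in most of its topic's 50 accounts while the
busiest noise pair reaches single digits, which is what makes the
planted-vs-noise ranking property a sharp test rather than a
coin flip. Tests and the acceptance script that need full determinism
fix the seed; the properties hold across seeds at these rates because
the margin is wide.

What the generator does **not** model: real tweet language (hashtags,
mentions, URLs, spelling noise), retweets and duplicate texts (every
record is treated as-is — the source procedure is silent on
deduplication, and account-level counting blunts its effect), follower
structure, and any statistical dependence between topics beyond shared
keywords. Passing tests therefore demonstrate that the *pipeline*
is correct and recoverable under controlled structure, not that any
particular real corpus would yield a particular network.

## Scale of the shipped checks

The default suite runs the full pipeline on the 300-account reference
corpus (about 6 000 tweets), 200 randomized oracle-equivalence corpora
of up to 20 accounts × 10 lines × 6 words, 20 random-parameter two-node
layouts and one end-to-end byte-determinism run — a few tens of seconds
in total. These sizes were chosen so the properties under test (exact
oracle agreement, rank separation, closed-form equilibria) are already
at full strength; the statistic itself is linear in total line count
and has been run comfortably on corpora two orders of magnitude larger.

## Known limitations

* The dictionary tokenizer is not a morphological analyzer: on real
  Japanese text it is only as good as its dictionary, and out-of-dictionary
  spans surface as `other` chunks rather than being segmented. The
  tokenizer contract exists precisely so a real analyzer can be dropped
  in.
* Raw account counts carry no significance testing (no PMI, no
  chi-square); the method's premise is that the raw count *is* the
  interpretable quantity.
* The spring model finds *a* local equilibrium from a seeded start, not
  a global optimum; different seeds give different but equally valid
  drawings.
* The category report is a dictionary lookup by design — the
  categorization encodes editorial judgment, and users supply their own
  dictionary for other domains.
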