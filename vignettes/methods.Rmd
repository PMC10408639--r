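---
title: "Methods: PMI co-occurrence networks and Louvain topics for short health-related texts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PMI co-occurrence networks and Louvain topics for short health-related texts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooctopics)
```

## The model

The pipeline detects discussion topics in corpora of short documents
(tweets) that are too small and too sparse for count-matrix topic models.
Its core object is an undirected term graph: nodes are high-frequency
terms, and two terms are linked when they appear together in the same
tweet. Raw co-frequency over-weights globally popular terms, so each link
is weighted by pointwise mutual information computed from **binary**
per-tweet occurrence (a term repeated within one tweet counts once):

$$\mathrm{pmi}(w_1, w_2) \;=\; \ln\frac{P(w_1 w_2)}{P(w_1)\,P(w_2)},
\qquad P(w_1 w_2) = \frac{codf}{n},\quad P(w_i) = \frac{df_i}{n},$$

with $n$ the number of tweets, $df$ the number of tweets containing a
term, and $codf$ the number containing both. PMI is 0 under independence
and positive for associated pairs; only positive-PMI pairs form links,
both because PMI's purpose here is to keep genuine associations and
because modularity is ill-defined for negative weights.

Topics are the communities of this weighted graph under Newman
modularity,

$$Q \;=\; \frac{1}{2m}\sum_{ij}\Big[A_{ij} - \frac{k_i k_j}{2m}\Big]\,
\delta(c_i, c_j),$$

maximized by the two-phase Louvain algorithm: repeated local node moves
(each node joins the neighboring community with the largest positive
gain), then aggregation of communities into super-nodes, iterated until a
whole level yields no improvement. The number of topics is therefore an
output, never a user-set parameter.

Implicit assumptions worth stating: documents are short enough that
whole-document co-occurrence is meaningful (no sliding window); topics
manifest as clusters of mutually associated terms; and a hard one-to-one
assignment of terms to topics is acceptable. Terms genuinely shared
across topics will be forced into one community — this is the method's
main distortion, and the reason the evaluation tracks vocabulary overlap
explicitly.

## Corpus construction

Tweets arrive as JSON-lines in the Twitter API v1.1 shape (`id_str`,
`full_text`, `created_at`, `user.location`, `lang`). Only
English-language records are loaded; malformed lines and unparseable
timestamps are skipped and counted in a diagnostics log rather than
failing the run.

The PEoLC relevance filter is a fixed list of 60 published search terms
(hashtags, fused forms, multiword phrases), shipped verbatim. Matching is
case-insensitive **substring** matching rather than token-boundary
matching: the list mixes `#eol`, `pallcare` and `palliative care`, and a
single substring rule covers all three forms uniformly and
conservatively. Duplicated texts (retweets) are retained by default; a
`dedupe` flag drops exact duplicates keeping the earliest.

Profile locations are free text, so country assignment uses a small
built-in gazetteer (country names and abbreviations, capitals and major
cities, US states with postal codes, UK nations, Canadian provinces) with
two deterministic rules: two-letter postal abbreviations match only in
upper case (so the word "on" never means Ontario, and the ambiguous "CA"
is excluded outright), and hits pointing at different countries resolve
to *no* country. This trades recall for auditability — every assignment
can be traced to a gazetteer row.

The pre/post vaccination split is a 00:00 UTC cutoff at the per-country
program start date (US 2020-12-10, UK 2020-12-02, Canada 2020-12-09); the
start day itself counts as "post", reading "after the start" as inclusive
of the start. Reported shares are `count/total × 100` rounded **half-up**
to 2 decimals (base R's `round()` is half-to-even, which does not
reproduce conventionally formatted percentages).

## Preprocessing

Four steps in fixed order — clean, tokenize, remove stopwords, normalize:

* **Cleaning** removes URLs and emoji (matched by Unicode block ranges,
  not a hand list) and unwraps `@mentions` and `#hashtags` to their
  bodies. Hashtag bodies are kept because topical vocabulary in this
  domain often circulates as hashtags (`hpm`, `hapc`).
* **Tokenization** lowercases and splits on any non-alphanumeric run.
  Tokens shorter than 2 characters and purely numeric tokens are dropped
  (both configurable); alphanumerics like `covid19` survive.
* **Stopword removal** is exact matching against a standard English list
  shipped as a text resource and overridable per call.
* **Normalization** defaults to a noun-default lemmatizer: an
  irregular-form table plus plural-suffix rules, with unknown tokens
  passing through unchanged (`nurses → nurse`, but `died` stays, as a
  noun-default part-of-speech treatment dictates). A suffix-stripping
  stemmer (`-ing`, `-ed`, `-ly`, then the plural rules) and the identity
  are available via `method=`. The lemmatizer is the default because
  topic keywords in this literature are reported as lemmas, not stems.

The chain is idempotent on its own output, and no stage invents tokens:
cleaning and stopword removal only delete, normalization maps 1-to-1.

## Network and optimizer parameters

| Parameter | Default | Role |
|---|---|---|
| `top_n` | 150 | nodes = top-`top_n` terms by document frequency (ties lexicographic) |
| `min_co` | 2 | minimum pair co-document count for an edge |
| `seed` | 0 | Louvain node-visit shuffle |
| `tolerance` | 1e-12 | minimum Q gain counted as improvement |

`top_n = 150` comfortably exceeds the >75-node floor recommended for
co-occurrence topic analysis at corpus sizes of a few hundred to a few
thousand tweets, and `min_co = 2` discards pairs seen only once, whose
PMI is pure noise. A warning (not an error) is raised when fewer than 76
nodes survive. The PMI log base is natural; any base rescales all weights
uniformly and modularity normalizes by total weight, so the choice cannot
affect the detected communities.

Numerical choices in the optimizer: ties between equally good target
communities break to the smallest community id, making runs reproducible;
the node-visit order is a seeded shuffle of the stored node order, so
renaming nodes in place yields the identically relabeled partition;
aggregation turns a community's internal weight into a self-loop counted
twice in its degree. Modularity itself accumulates per-community degree
totals from edge sums (doubling internal contributions) rather than from
per-node degrees, which makes the all-nodes-in-one-community partition
evaluate to exactly 0 rather than 0 up to float rounding. The stopping
rule is "no improvement": no move (and then no level) may gain more than
`tolerance`, defaulted to 1e-12 since the stop rule itself comes with no
numeric threshold.

## Topic reports

Keywords are ranked by within-community weighted degree — the sum of a
term's PMI weights to same-community neighbors — which favors terms
central to their topic rather than merely frequent; raw document
frequency is available as an alternative scorer. Representative documents
are those containing the most of a community's top-10 keywords (ties to
the earlier timestamp). Pre/post topic matching is greedy
maximum-Jaccard on top-20 keyword sets; a post community whose best
Jaccard against the pre side falls below 0.1 is *emergent* (and
symmetrically *vanished*). The 0.1 threshold operationalizes "no evident
difference except an emerging topic": random keyword sets of size 20 over
a 150-term vocabulary essentially never reach it, while any genuinely
persisting topic shares far more. Topic *labels* are deliberately not
generated — naming a community is interpretive work that belongs to the
analyst.

## The synthetic corpus generator

Real tweet corpora cannot be redistributed, so evaluation uses generated
corpora with planted structure. `make_topic_specs(k, vocab_size,
overlap)` builds `k` topic vocabularies of synthetic lowercase terms
(checked to contain no PEoLC filter term as a substring, so the keyword
filter can never fire on topic vocabulary) sharing a
`round(overlap × vocab_size)`-term common pool. Each generated tweet
draws one topic, samples 8–25 tokens from its vocabulary, receives with
probability `peolc_fraction` one verbatim filter term, and gets a
timestamp uniform over the collection window (Oct 2020–Mar 2021 by
default) and a gazetteer-resolvable location with country probabilities
proportional to the observed volumes (4133 US : 2923 UK : 895 CA). A
`noise_fraction` share of tweets (default 0.2) also receives a URL, an
emoji and stopwords so preprocessing has real work to do. The default
`peolc_fraction` is 2e-04, the share observed in the original COVID-19
stream; evaluation scenarios raise it explicitly so that a desk-scale
corpus still yields several hundred filtered tweets.

The generator emulates: document length, the filter-term planting that
makes keyword recall exactly checkable, resolvable/unresolvable
locations, pre/post timing, and controllable cross-topic vocabulary
overlap. It does **not** emulate natural language: no word order
semantics, no Zipfian long tail, no hashtag dynamics, no topic mixtures
within a tweet, no user or retweet structure. Passing the planted-topic
tests therefore demonstrates that the pipeline's machinery — filtering,
counting, weighting, optimization, scoring — is correct, not that topics
in real tweets are as cleanly separable; real corpora have heavier
vocabulary overlap and will yield blurrier communities.

Topic assignment is single-topic per tweet so that recovery has an
unambiguous ground truth: detected document clusters (each document
assigned to the community holding the plurality of its network tokens,
ties to the smallest community id) are scored by purity,
$\sum_c \max_t |c \cap t| / N$, over the documents that map to any
community.

## Problem sizes and determinism

The shipped tests and the acceptance script run: percentage reproduction
on the published count pairs (instant); PMI verified against brute-force
recomputation on 200 seeded micro-corpora of at most 10 documents over at
most 6 terms; modularity against a naive double-loop oracle on fixture
and random graphs of at most 8 nodes, with exhaustive search over all set
partitions certifying the Louvain optimum on the 6-node two-triangle and
8-node planted-two-community fixtures; planted-topic recovery on five
2000-tweet corpora (three topics, overlap 0.1, ≈400 filtered tweets
each); and emergent-topic detection on a 1000-tweet pre / 1400-tweet post
pair with one post-only topic. These sizes keep the whole suite under
half a minute while exercising every code path at the same parameter
settings (`top_n`, `min_co`, seeds) used on full corpora. All randomness
flows through explicit integer seeds (`withr::with_seed`), so every
reported number is bit-reproducible.

## Known limitations

* Substring keyword matching can over-match (any text containing
  "hospice" qualifies, including e.g. "hospicecareweek" — intended — but
  also unrelated compounds).
* The gazetteer is small by design; profile strings like "UK/US expat"
  resolve to no country, and coverage outside the three study countries
  is out of scope.
* The rule-based lemmatizer handles plural nouns and common irregulars
  only; verb inflections pass through (consistent with noun-default
  lemmatization, but a dictionary lemmatizer would normalize more).
* Louvain is order-dependent; the seed pins the order, but different
  seeds can yield different (equally valid) local optima on weakly
  structured graphs.
* Terms shared across topics are hard-assigned to one community; with
  heavy overlap the purity of recovery degrades by construction.
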