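---
title: "Mining contemporary pain descriptors and revising a pain questionnaire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining contemporary pain descriptors and revising a pain questionnaire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`painlex` mines pain vocabulary from short, noisy social-media-style posts
and applies the findings to a multidimensional pain questionnaire of 78
descriptors in 20 subclasses. The workflow is purely lexical: every
operator works on lowercase word tokens, and multiword descriptors
("feel hopeless") act as consecutive token sequences. No parsing, no
sentence segmentation, no language model.

The pipeline has two gather–analyse rounds. Round 1 finds candidate new
descriptors: posts containing `pain` with a known descriptor within a hop
limit are kept, sarcastic posts are dropped, skip-gram embeddings are
trained on the survivors, and each keyword contributes up to 20
positively-similar neighbours, pruned by stem, antonym and stoplist rules.
Round 2 re-gathers with the expanded keyword list, additionally requires a
pain *condition* in the post (for specificity to health contexts), and
computes the per-descriptor statistics — post-level count and mean pain
intensity — that drive the questionnaire revision.

### Word graphs and the hop criterion

A post's word graph joins two distinct tokens whenever they occur within
`window` positions of each other (default 1: consecutive tokens). "Within
*k* hops" is an inclusive shortest-path bound, computed by breadth-first
search; a token three hops from `pain` passes at the default `hop_limit =
3`. The hop criterion is evaluated **per post**, not on a corpus-level
graph: a corpus-level graph would let two tokens that never co-occur in any
post appear close through shared neighbours, which defeats the purpose of a
relevance filter. The head token of a multiword descriptor anchors the hop
query. With `hop_limit = Inf` the filter degenerates to plain
co-occurrence, which the tests assert.

### Sarcasm scoring

The original workflow used a proprietary trained classifier; its model and
training data are unavailable, so the package ships a transparent,
rule-based stand-in behind a one-function plug-in contract
(`sarcasm_config(scorer = ...)`). The default scorer counts surface
features of ironic writing — configured marker phrases, positive-word /
negative-context juxtaposition, interjections, elongated words
("soooo"), punctuation bursts, scare quotes — and squashes the weighted
sum through `2/(1+exp(-x)) - 1`, a scaled logistic that maps zero
activation to exactly 0 and is strictly increasing. Ratings live on
[0, 1]; posts rated **strictly above** 0.7 are removed, so a rating of
exactly 0.70 survives. The default marker weight (2.0) makes any single
configured marker exceed the bar, which is what the synthetic generator's
hidden labels assume. The published accuracy of the original classifier is
*not* a contract of this package; the contract is the scale, the strict
threshold, determinism, and monotonicity in marker evidence.

### Embeddings and candidate discovery

Training is skip-gram with negative sampling, implemented in C++ (Rcpp)
following the classic reference loop: unigram-frequency^0.75 negative
sampling table, dynamic window shrink, linear learning-rate decay, 64-bit
LCG random stream. It is single-threaded and fully determined by the seed;
two runs on the same corpus and configuration are bit-identical, which the
tests assert. "Associated" means **cosine similarity strictly greater than
zero** — distances are non-negative, so a signed "positive distance"
criterion only makes sense as a similarity sign condition. Neighbour lists
exclude the query word, contain no duplicates, are ranked by descending
similarity with an alphabetical tie-break, and cap at `max_neighbors`
(default 20).

Defaults: `dimension = 100`, `context_window = 5`, `min_count = 5`,
`epochs = 5`, `negative_samples = 5` — the conventional skip-gram settings
for large corpora. On small synthetic corpora (≈10⁵ tokens) the relevant
quantity is total training exposure, so the bundled tests use a smaller
dimension (24), window 1 (the planted signal is strictly adjacent) and more
epochs (15–40). An out-of-vocabulary keyword yields an empty neighbour
list with a warning rather than an error, because rare keywords
legitimately fall below `min_count`.

Pruning applies three removal rules, each logged per removal: `same_root`
(candidate's stem equals any root descriptor's stem, via a compact
suffix-stripping stemmer), `contrast` (the keyword–candidate pair appears
in the configured antonym map, direction-insensitive), and `irrelevant`
(candidate on the configured stoplist). The latter two encode what was a
human judgment in the original workflow; they are configuration, not
learned behaviour. No stemming is applied anywhere *else* in the pipeline:
inflections are distinct descriptors by design (e.g. *depress* and
*depression* count separately).

### Emotion intensity

Posts are scored on five channels — anger, fear, sadness, joy, valence —
against a pluggable lexicon (TSV: token, channel, intensity). The per-post
channel score is the **maximum** entry intensity over the post's tokens,
with the whole post as the scoring unit. The mapping from five channels to
one pain intensity is not published for the original engine, so it is
explicit here: default `neg_max` = `max(anger, fear, sadness)`;
alternatives `one_minus_valence` and a weighted blend. A descriptor's
intensity is the arithmetic mean of per-post intensities over the posts
containing it (the aggregate is configurable to median). A descriptor
contained in zero posts has *undefined* intensity — the API errors rather
than returning 0, and the stats table records `NA`. The only place an `NA`
intensity is coerced (to 0, as a sort key) is inside the round-2
orchestrator, and only for words that the count threshold has already
eliminated from the revision.

### Threshold, removals, additions, reordering

The prevalence threshold is derived, never configured: take the bottom
`decile` (default 0.10, so `ceiling(0.10 × 78) = 8` of 78) of the original
descriptors by count — alphabetical tie-break, extended to include every
descriptor tied with the boundary count — and set the threshold to the
smallest count strictly greater than every bottom-set count. Words with
`count < threshold` fail. In the bundled fixture the 9th-lowest original
count is exactly 110, so the derived threshold is 110. Degenerate all-tied
input would make the bottom set the whole questionnaire; that input instead
produces an empty bottom set, a warning, and `threshold = count + 1`.

Removals carry a rule tag: `low_use` (below threshold) or `context`
(configured list of descriptors whose usage drifted away from pain
description — verbs rather than adjectives, for example). Additions are
validated against the threshold: assigning a below-threshold word to a
subclass is an error, so the prevalence criterion is machine-checked.

Reordering is a **stable** sort by intensity within each subclass, ties
preserving input order, ascending by default. Ascending is deliberate: the
published comparison table keeps the minimum-intensity word first in the
Temporal subclass even though its prose says "decreasing"; the direction is
a configuration switch (`reorder_direction`) and the package does not claim
to resolve the ambiguity. A subclass counts as *reordered* only when the
relative order of its surviving original descriptors changed — new words
slotting between unmoved originals do not trip the flag. This matches the
reference table, where a subclass with mid-list insertions is still marked
"not reordered", and it is the only semantics under which the bundled
fixture reproduces all six reordered flags.

The Psychological subclass is an ordered configuration (nine
emotional-state words phrased to complete "My pain makes me ___"),
validated against count/intensity envelopes when supplied; it keeps its
configured order because the reference table assigns it no ranking.

## The synthetic corpus: what it emulates, what it does not

The real corpus (a year of public posts from four platforms) is not
available and not redistributable; the generator stands in for it. Each
post is a bag of noise tokens (uniform over a `noise_vocab_size` vocabulary,
5–12 tokens by default) into which structure is planted:

- with `p_contains_pain` (default 0.35) the post is a *pain post*: a
  `pain <root descriptor>` frame is inserted, so the root is one hop from
  `pain` and the round-1 criterion is satisfiable by construction;
- each associate of that root joins the post with its configured
  propensity, planted as its own `pain <associate>` frame;
- with `p_condition` (0.5) the post names a pain condition, with
  `p_emotion` (0.3) it carries one emotion word;
- with `p_sarcastic` (0.05) the post carries one sarcasm marker;
- mentions, URLs, case noise and punctuation bursts are layered on at
  render time only, so cleaning can be tested as an exact inverse.

Hidden labels (relevant, sarcastic, planted words) travel in a sidecar
table, never in the text. A single integer seed drives one explicit random
stream; the generator saves and restores the caller's RNG state, and
identical (config, seed) pairs are byte-identical on disk.

**Associate placement.** Associates are planted in the same `pain <word>`
construction as their root — *paradigmatic* planting — rather than
directly adjacent to the root token. Embedding similarity is a
second-order statistic: words are close when their context distributions
match. A word that only ever appears glued to its root has a context
distribution unlike the root's own, and pilot runs showed skip-gram then
fails to rank it among the top-20 neighbours at any propensity, while other
root descriptors (which *do* share the root's frame) dominate. Paradigmatic
planting models what association means in real usage — the new word is used
the way the root is used — while preserving the tested invariant that the
associate co-occurs with its root within posts at exactly the stated
propensity.

Corpus composition values are free choices (the source describes none):
0.35 pain posts emulates a keyword-harvested corpus rather than a random
platform sample; 5% sarcasm and the 0.5/0.3 condition/emotion rates are
plausible for health-related posts. They were fixed once, before the
acceptance runs, and are exposed in `corpus_config()`.

What the generator does **not** emulate: grammar and word order beyond the
planted frames, platform markup (threads, retweets), emoji, multilinguality,
topic drift, author effects, or duplicated content. Consequently a green
recovery test establishes that the estimator chain (clean → filter → embed
→ extract → prune → count → revise) is correct *under the stated generative
model* — it does not certify performance on real social-media text, where
context distributions are far richer and the proprietary scorers the
package replaces would matter.

`expected_counts()` gives the analytic expectation of post-level counts
under this model (planting probabilities for lexicon words; the occupancy
probability `1 − (1 − 1/V)^L` averaged over post lengths for noise words),
and the Monte-Carlo tests hold observed counts to within three standard
errors of it.

## Numerical and engineering choices

- All randomness passes through one seeded stream per operation
  (`with_seed`), so library calls never disturb the caller's RNG state.
- Sorting is everywhere stable with documented tie-breaks (alphabetical for
  counts and similarities, input order for intensity ties), making every
  artifact bit-reproducible.
- Stage manifests assert `n_in = n_out + n_removed` at construction; the
  pipeline cannot silently lose or duplicate posts.
- JSON-lines corpus files are written in binary mode with fixed field
  order, so identical corpora are byte-identical across platforms.
- The CLI consumes JSON configuration (not YAML): JSON needs no additional
  dependency beyond `jsonlite`, which the package already imports.
- Provenance hashes in manifests use a compact FNV-style string hash —
  cheap, dependency-free, and adequate for change detection (not
  cryptographic).
- The embedding trainer clamps the logistic argument at ±6 and caps the
  learning rate from below, the standard guards of the reference
  implementation.

## Limitations

- The sarcasm and emotion scorers are transparent stand-ins; absolute
  scores are only meaningful relative to their configured lexicons and
  weights. Plug in a trained scorer or a full affect-intensity lexicon for
  real-text work.
- The bundled revision fixture mixes published values with synthetic
  fill-ins (flagged in `value_source`); the fixture pins the *logic* of the
  revision engine, not the empirical counts of any real corpus.
- Embedding quality on corpora much smaller than ~10⁵ tokens is noisy; the
  package warns rather than errors on out-of-vocabulary keywords, and the
  candidate tables always carry similarities and ranks so downstream users
  can apply their own cut-offs.
- Clinical validity of any revised questionnaire is out of scope: the
  package produces a *suggested* instrument and a machine-readable audit
  trail, not a validated scale.
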