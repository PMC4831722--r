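---
title: "Extracting chemical-induced disease relations: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting chemical-induced disease relations: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cidre` implements a document-level pipeline for chemical-induced disease
(CID) extraction from annotated abstracts, together with the dictionary-based
disease recognition step that feeds it. This vignette explains the models and
procedures, the tunable parameters and their defaults, the synthetic data
the package tests itself on, and the design decisions taken where more than
one reasonable choice existed.

## The task and the data model

A corpus (`pt_corpus`) is an ordered set of documents; a document
(`pt_document`) carries a title, an abstract, entity mentions and
document-level relations. Mentions use 0-based, end-exclusive character
offsets into the string `title + " " + abstract` — the dialect used by
released PubTator corpora — and are validated on construction: an offset
pair that does not slice to the recorded surface text is an error, not a
warning, because every downstream module indexes into that string. A mention
may normalize to several MeSH identifiers (stored as a vector; the file
format joins them with `|`), and the file sentinel `-1` becomes the explicit
`"unmapped"` value. Relations are (chemical MeSH id, disease MeSH id) pairs
without offsets: the annotation standard asserts them at document level, so
evaluation is identifier-based, and relation identifiers that never appear
among the mentions are kept with a warning rather than dropped.

Chemical mentions are consumed as given (in practice they come from a
dedicated chemical recognizer); the package recognizes *diseases* itself.

## Dictionary recognition of diseases

The recognizer is a token-level longest-match engine over a user-supplied
term dictionary:

1. **Tokenization** splits on any non-alphanumeric run and case-folds,
   keeping digits ("Q10" stays a token). This is the simplest reproducible
   rule; offsets always point back into the original text.
2. **Normalization.** Each token is stemmed before matching. The builtin
   normalizer is an S-stemmer (plural suffixes: "ies" → "y", trailing "s"
   dropped unless "ss"/"us"/"is"), chosen over a heavier stemmer because it
   is idempotent — index keys and query tokens reach the same form no matter
   how often the rule runs — and because the recognition mechanism only
   requires that dictionary and text normalize consistently, not that any
   particular stemmer be used. `identity` disables stemming and any function
   can be plugged in.
3. **Indexing and matching.** Dictionary terms are tokenized, stopworded
   (the PubMed stopword list ships in `inst/extdata/`) and normalized; the
   token sequence becomes an index key. Matching is greedy
   leftmost-longest: scanning left to right (skipping stopword tokens in the
   text as well — a flag disables this), the longest indexed sequence at the
   current position wins and matching resumes after it. Ties cannot arise at
   one position; among positions the earlier start wins, making the rule
   deterministic. The test suite checks this engine against a brute-force
   enumerator of all token subsequences on hundreds of random
   dictionary/text pairs.
4. **Abbreviation propagation.** Definitions of the form "long form (SF)"
   are detected with the Schwartz–Hearst right-to-left character alignment
   (short form 2–10 characters, at most two words, must contain a letter;
   the long-form window is min(|SF|+5, 2|SF|) words). If either form of a
   detected pair overlaps a recognized span, every occurrence of both forms
   document-wide receives that concept; on conflict the long form wins with
   a warning. Detection is sentence-local in spirit (the window never
   crosses the parenthesis), propagation is document-wide.
5. **Merging.** Adjacent spans with identical concept sets separated only by
   whitespace/punctuation merge into one span; the rule reaches a fixed
   point in one left-to-right pass. A consequence worth knowing: a
   definition "acute liver failure (ALF" merges with its parenthesized
   abbreviation into a single span once both carry the same concept.
6. **Exclusion filtering.** An exclusion list maps normalized terms to
   (true-positive, false-positive) counts tallied on an annotated corpus
   (`build_exclusion_list`). A span is removed when its term has fp > 0 and
   tp/fp *strictly below* the threshold; the default 0.3 keeps a term at
   exactly 0.3. Threshold 0 is the identity; `Inf` removes every listed
   term with any false positive (the aggressive mode useful when no ratio
   information is trusted). Exclusion keys are stemmed-lowercase token
   sequences, matching what the recognizer emits.
7. **MeSH mapping.** Source-vocabulary concept identifiers translate through
   a two-column table; unmapped concepts are dropped (default) or kept as
   the sentinel, and duplicate targets at one span collapse.

## Knowledge-graph path features

The graph store is a flat edge table: subject, predicate, object, a
directionality flag (one-directional causal vs two-directional
associative), and per-source record counts. Duplicate
(subject, predicate, object, source) rows sum their counts with a warning;
an edge's *total provenance* is the sum across its sources — a deliberate
reading of "total provenance count" (the alternative, a per-source maximum,
discards evidence volume).

For a pair (a, b): **direct** paths are single edges joining a and b in
either role — a one-directional edge counts regardless of orientation, but
the orientation (a → b or b → a) is retained as a feature flag, since a
causal arrow pointing the "wrong" way is plausibly informative downstream.
**Indirect** paths are chains a–x–b through one intermediate where each
one-directional edge must point a → x or x → b; two-directional edges are
unconstrained. If any direct path exists, indirect paths are ignored.
Per-pair features: path type (none/direct/indirect), confidence score,
number of paths, union of predicates (one-hot against the training
vocabulary), and provenance count. A direct path's provenance is its edge
total; an indirect path's is the **minimum** over its two edges; across
paths of the same kind both score and provenance aggregate by **maximum**
("same length" is read as same kind, the only lengths that exist here).

Confidence formulas of commercial graph platforms are unpublished, so the
scorer is pluggable: `log-provenance` (default, Σ log(1+provenance) over a
path's edges — monotone in evidence, dampened like most literature-derived
scores), `raw-provenance`, `constant-1`, or any function. The
knowledge-base baseline predicts a pair positive iff a direct edge with a
non-treatment predicate joins it (`treatment_predicates` defaults to
`treats`/`prevents`); treatment edges are excluded because therapeutic
pairs are precisely the ones annotation guidelines for induced diseases
leave out.

## Linguistic features

Dependency parses arrive as CoNLL-U with `# doc_id` comments and
character-offset MISC fields; the reader validates one root per sentence and
acyclic head chains. Parses are an input artifact: the package never calls a
parser, which keeps every test hermetic.

- A tag counts as a verb if it starts with "VB" (Penn) or equals "VERB"
  (UPOS).
- The **governing verb** walk starts at the token's *head*: a verb is never
  its own governing verb. The **relating word** (lowest common ancestor)
  uses *self-inclusive* ancestor sets: if the chemical dominates the
  disease, the chemical itself is the relating word. This asymmetric pair
  of conventions is the only one under which the worked example
  (`example_dependency_tree()`: disease governed by "produce", chemical by
  "demonstrated", which is also the relating word) and the
  "chemical-is-the-relating-word" identity feature are simultaneously
  coherent.
- Multi-token mentions are represented by their syntactic head token (the
  mention token whose head lies outside the mention).
- **Negation** of a token: a dependent with a negation label (`neg` by
  default) or an adverbial-modifier dependent whose form is in the lexicon
  (`not`, `no`, `never`, `without`).
- The **representative pair** for an identifier pair: same-sentence mention
  pairs precede cross-sentence ones; among same-sentence pairs, those with
  no other chemical–disease pair *lower in the parse tree* precede the rest
  — operationalized as: no other pair's relating word is a strict
  descendant of this pair's relating word, the only concrete reading of
  "lower" that needs nothing beyond the tree itself. Remaining ties break
  by earliest chemical then disease position. With only cross-sentence
  candidates, the last pair (by document order) with the chemical before
  the disease is taken; failing that, the first chemical and first disease
  mentions.
- Per-pair features: the four anchor words (governing verbs of chemical and
  disease, relating word, its governing verb) as nominals; chemical-first
  order; existence of a lower pair; four negation flags; three identity
  flags comparing token positions (chemical vs relating word, disease's
  governing verb vs relating word, both governing verbs vs relating word).
  The identity feature for the chemical is read literally (the chemical
  token itself, not its governing verb). Cross-sentence pairs leave the
  relating word and its derivatives undefined (all-zero one-hot blocks,
  false negation flags) and take the two governing verbs from their two
  different trees.
- The **aggregate** set counts, for every chemical × disease mention pair in
  the document, occurrences of each training-vocabulary word as governing
  verb or relating word — one count per role per pair, so a word serving
  two roles for one pair counts twice. Out-of-vocabulary words are ignored;
  the counts are document-level and shared by all pairs of the document.

## Statistical features

Per identifier pair: mention counts of each identifier, their product (the
number of mention pairs), ratios against document totals of chemical
mentions, disease mentions and all possible mention pairs; the minimal
sentence distance (sentences are the parse units; the title is sentence 0)
and minimal token distance (tokens strictly between the closest mention
boundaries, document-wide positions, 0 for overlapping or adjacent
mentions — "word distance" is counted in tokens, not characters); and
title flags for chemical, disease, and both. The pair's MeSH identifiers
enter as nominal features; unseen identifiers at test time produce all-zero
one-hot blocks rather than hashed collisions.

## Classifier

One instance per document per (unique chemical id × unique disease id),
composite identifiers expanded, sentinels skipped; pairs may cross the
title–abstract border. Gold labels mark a pair positive iff it appears in
the document's relation set.

Numeric features scale to [0, 1] by training min/max (constant features
collapse to 0; test values clip). The SVM is C-SVC with RBF kernel
(`e1071`/libsvm) and class weights 5:1 for the positive class, reflecting
the roughly 1:4 positive:negative imbalance of document-level pair
instances. Cost and gamma come from a grid search — defaults cost
2^−2…2^6, gamma 2^−6…2^2 — under stratified 10-fold cross-validation
(stratified by label; a per-document grouping flag is a possible extension
but label stratification is the standard default at this instance
granularity), selecting on micro-F of the class predictions, i.e. a fixed
0.5 decision threshold. The winner refits on all data.

Probabilities are Platt sigmoid calibrations fitted in-package (a logistic
fit of labels on out-of-fold decision values, folds seeded). The libsvm
built-in calibration is avoided deliberately: its internal shuffling is not
seedable from R, and the package promises byte-identical artifacts for a
fixed seed. The decision threshold is then tuned by sweeping a 0.01-step
grid over the same out-of-fold probabilities, taking the lowest maximizer
of micro-F; a degenerate instance set (single class or a single instance)
falls back to 0.5 with a warning. Single-class training data is an error —
there is nothing to learn.

Evaluation conventions: with zero denominators, precision and recall are 0
(flagged in the result); F is 0 when P + R = 0. Micro counts pool over
documents, so evaluating a concatenated corpus equals summing the parts.

## The synthetic data generator

`generate_fixtures()` builds, from one seed, a mutually consistent corpus,
dictionary, concept-to-MeSH map, knowledge graph, CoNLL-U parses and
relation table. Documents are assembled from sentence templates with
hand-authored dependency trees: related pairs appear in one causal sentence
("X induced Y", or a two-clause "demonstrated … can produce" shape) with
probability `p_same_sentence`, otherwise split across two sentences;
unrelated pairs are negated ("did not cause"), therapeutic ("was treated
with"), or mentioned in separate sentences — half of those cross-sentence
negatives reuse the *same* sentence shapes as cross-sentence positives, so
distant co-mentions carry no syntactic signal and only the knowledge graph
separates them. That confound is what makes the knowledge-feature ablation
test meaningful rather than vacuous.

Defaults and why: `p_relation = 0.2` (annotated corpora of this kind label
roughly a fifth of possible pairs positive); `p_same_sentence = 0.7`
(roughly a quarter to a third of real relations span sentences);
`p_kg_edge_given_rel = 0.9` vs `p_kg_edge_given_unrel = 0.05` with
`p_treat_edge = 0.5` (curated graphs cover most true causal pairs, rarely
assert false ones, and frequently record treatments); vocabulary sizes
`n_chemicals = n_diseases = 150` so that, at the 300–450-document scale the
package tests at, unique identifiers are of the same order as documents —
the sparse regime of real corpora, where a few thousand unique identifiers
cover ~1500 abstracts and a given pair rarely recurs across documents with
conflicting labels. Titles mention a chemical half the time and never a
disease, so sentence-0 co-occurrence cannot contaminate the co-occurrence
baseline's recall, which then estimates `p_same_sentence` directly.

What the generator does **not** emulate: real English (the text is
telegraphic template output), realistic term-frequency distributions,
recognition errors in chemical annotations, composite-identifier mentions
beyond what unit tests construct directly, or annotation noise. Passing
end-to-end tests therefore demonstrates that the machinery — features,
learning, calibration, evaluation — recovers planted structure through the
full file-format round trip; it does not certify performance on real
corpora, where entity errors and vocabulary coverage dominate.

## Problem sizes and numerical choices

The shipped tests run the full pipeline on a 300-document fixture (200
train / 100 test) and the acceptance script on 450 documents (300/150),
with the grid reduced to cost 2^{0,2,4} × gamma 2^{−4,−2,0} — at fixture
scale the F landscape is flat across the wider default grid, and the
reduced grid keeps the oracle-equivalence suites (500 random cases each for
matching, paths and tree anchors) and two full training runs comfortably
inside a few minutes on one CPU. Stratified folds, fold seeds and the
threshold grid step (0.01) are recorded in the model object. Scores are
compared with `all.equal`-style tolerances only where floating point is
involved; counting identities are exact.

## Known limitations

- Recognition quality is bounded by the dictionary: missing synonyms are
  missed mentions, and the exclusion list can only remove, never add.
- The representative-pair heuristic and anchor features assume reasonably
  correct parses; garbage trees yield garbage anchors (validated structure,
  not validated linguistics).
- Paths longer than one intermediate are out of scope, as is querying a
  live graph service; the store is a flat file.
- Anaphora ("this drug … the syndrome") defeats both the co-occurrence
  baseline and the linguistic features; resolving it would require
  machinery beyond dependency trees of single sentences.
- The aggregate linguistic vocabulary is fixed at training time; regime
  shifts in verb usage degrade silently to all-zero blocks.
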