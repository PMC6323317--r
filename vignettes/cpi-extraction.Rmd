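---
title: "Extracting chemical-protein interactions with cpistack"
author: "cpistack authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting chemical-protein interactions with cpistack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpistack)
```

## The problem and the model

Chemical–protein interactions (CPIs) — a drug inhibiting a kinase, a
metabolite acting as a receptor agonist — are reported in abstracts as
free text. With entity mentions already tagged (the ChemProt convention:
`CHEMICAL`, `GENE-Y`, `GENE-N` spans with character offsets into
title-plus-body text), extraction reduces to classifying each
same-sentence chemical–protein pair into one of the evaluated relation
groups CPR:3 (up-regulation), CPR:4 (down-regulation), CPR:5 (agonism),
CPR:6 (antagonism), CPR:9 (substrate) or "other/no interaction".

The model makes three structural assumptions:

* **Sentence-bound relations.** Candidates are built only within
  sentences. Gold relations whose arguments never co-occur in a sentence
  are unreachable by construction; `build_candidates()` counts them
  (`coverage$n_unreachable`) rather than dropping them silently, so the
  recall ceiling is visible.
* **Trigger words carry type information.** A curated dictionary maps
  interaction words to CPR groups. Pairs are augmented into triplets, one
  per interaction-word occurrence; all triplets of a pair share its label,
  which deliberately mislabels some triplets (only one wording usually
  expresses the relation). The stage-II selection step — keep the triplet
  with the highest best-class score — is the model's answer to that noise.
* **Syntax localizes the signal.** The shortest dependency path (SDP)
  between the masked entities tends to carry the relation; short paths
  suggest true interactions, and an appositive (`appos`) edge on the path
  suggests the mentions merely rename each other.

### Candidate construction and masking

Within each sentence, every chemical × protein combination is a CPI pair
(GENE-Y and GENE-N both count as proteins — the distinction is about
normalization, not syntax). For parsing, the focal chemical becomes
`CHEM`, the focal protein `PROT`, and every bystander entity `CPTk`. We
number `k` by the numeric part of the entity's term id (`T10` → `CPT10`):
term ids in ChemProt are assigned per document in reading order, so this
is both stable across the sentence's pairs and literally the "interactor
term identifier". Masking is span-based: a multi-word name collapses into
one token, and an entity strictly inside a longer word is replaced
in place, preserving surrounding characters (`subretinal` with the tagged
span `retinal` → `subCPT10`). Masking keeps a replacement ledger, so it is
exactly invertible (`unmask_entities()`), which the tests exploit.

The offset frame is `title + "\t" + body`, the common ChemProt
convention; the separator is a `sep` argument on `read_chemprot_corpus()`
for corpora that differ, and a `one_based` flag converts 1-based entity
offsets. The sentence splitter is rule-based (terminator + whitespace +
capital/digit lookahead, an abbreviation blacklist, tab/newline as hard
boundaries) and pluggable: pass any `function(text) -> data.frame(start,
end, text)` to match an external preprocessing chain. An entity spanning a
sentence boundary triggers a repair that merges the adjacent sentences —
mis-segmentation must never delete a candidate.

### Features

Semantic-pattern features are computed on the masked token sequence;
`e1` is the first-occurring focal entity (chemical/protein order varies in
text). Token windows of `window = 3` (configurable via
`cpi_feature_config()`) before `e1` and after `e2` are scanned for
"significant*" and substrate cues; because the sources for the substrate
cue list differ slightly, the default is the union
(*product/production, pathway, generate(d), synthetic/synthesis*) matched
as case-insensitive prefixes. Negation and conjunction cues are scanned
over the span from the leftmost to the rightmost candidate element
(including the interaction word for triplets); both lists ship as small,
documented defaults and are user-overridable — cue lists of this kind are
inherently open-ended, so any closure is a judgement call.

Dependency features use the undirected view of the parse (standard SDP
practice; directionality is available in the graph but no feature
consumes it). For each relevant node pair we emit both the edge count and
the word count of the SDP, since "distance" is reported both ways in the
literature; they differ by exactly one, but tree learners are indifferent
and linear learners can pick either. The topology of {e1, iw, e2} is
classified into eight types plus a sentinel:

* types 0–2: one element lies on a shortest path between the other two
  (tested via the distance identity `d(a,m) + d(m,b) = d(a,b)`, so it
  holds for *some* shortest path, not just the tie-broken one);
* types 3–7: no element is between the others; the three pairwise SDPs
  form a star (all pairs of paths share edges), a triangle (all pairwise
  edge-disjoint), or a star with exactly one path edge-disjoint from the
  other two (which path it is distinguishes 5/6/7). A graph where exactly
  one pair of paths is edge-disjoint — possible only through tie-breaking
  artifacts — is conservatively called a star.

This predicate formalization is this package's contract; informal
descriptions of these topology types mix linear order and shape and admit
several readings. An
exhaustive test over all 4-node graphs (and sampled 5–6-node graphs)
re-checks every returned type against an independent implementation.

Numerical conventions: equal-length SDPs are tie-broken to the
lexicographically smallest node sequence, so every downstream feature is
deterministic; a disconnected node pair takes the sentence token count as
its step/word sentinel (an upper bound no connected path can reach) plus a
binary no-path flag, and a disconnected triple takes `sp_type = -1`,
encoded as its own one-hot column. The dependency-label vocabulary for
one-hot encoding is learned at fit time from the training parses — not
hard-coded to one parser's inventory — and frozen in the feature registry;
labels unseen at fit time encode as all-zero one-hots at predict time.

Parsing is behind an adapter contract (`function(tokens) -> dep_graph`,
node count = token count, deterministic). Bundled adapters: a fixture
store (JSON-lines records, with a normalized lookup that maps all entity
placeholders to a generic symbol so one parse serves every focal-pair
masking of a sentence) and a minimal CoNLL-U reader. Nothing in the
package depends on a specific parser's label set.

### The three stages

Every stage uses k = 10 label-stratified folds (classes are dealt
cyclically after shuffling, so a class with at least two rows always
spans at least two folds; a single-row class is an error rather than a
silent leak). A training row's meta-feature always comes from the fold
model that did not train on it; new data takes the average of the k fold
models' scores.

* **Stage I** (binary: evaluated CPR vs not): random forest, extremely
  randomized trees, gradient-boosted trees, per track. OOF scores are
  rank-normalized — `(rank − 1)/(n − 1)` with average ranks for ties,
  0.5 for a single score — which makes the three learners' scores
  comparable regardless of calibration. At predict time the fold-averaged
  raw scores are mapped through the empirical CDF of the training OOF
  scores: this is order-preserving, lands on the same scale, and is
  independent of the prediction batch size (re-ranking within a batch
  would make single-record predictions ill-defined).
* **Stage II** (six classes): the stage-I families plus logistic
  regression, linear discriminant analysis and naive Bayes — six models
  per track by default; `stage2_families = c("lr", "lda", "nb")` drops to
  the three non-tree families alone. Each model contributes 6 class
  scores + 1 argmax code (42 columns per track). The representative
  triplet of a pair maximizes the best evaluated-class score of the
  across-model mean; maximizing `1 − P(other)` is a defensible
  alternative, but the best-evaluated-class rule is the one
  `select_best_triplet()` implements, with ties broken by
  earlier token position then lexicographic word.
* **Stage III**: original pair features + both tracks' stage-II blocks
  (pairs without any triplet get a zero block plus a `no_triplet`
  indicator); logistic regression, random forest, extremely randomized
  trees and gradient-boosted trees, fitted on the full training set (there
  is no later stage to protect from leakage), averaged; argmax wins.
  Which stage-II outputs feed stage III is not fully pinned down in the
  source description; both tracks are included by default ("the outputs at
  stage II"), and `tracks = "pair"` gives the pair-only ablation.

Hyper-parameter defaults are modest (100 trees, depth-4/40-round
boosting, lightly regularized logistic regression) because the stacked
design gains more from out-of-fold diversity than from deep individual
models, and because LDA and naive Bayes need no tuning to serve as
diverse, fast stage-II voices. `randomized_search()` (10 settings, 3-fold
CV, per learner per track — a per-learner granularity, since one setting
rarely suits six families) and `rfe_select()` (drop the least-important
20% per iteration, keep the best CV subset) are available behind
`search = TRUE` / `rfe = TRUE`; naive Bayes exposes no importances and is
skipped by RFE with a pointer to use a surrogate family.

Determinism: the master seed fixes fold splits and every learner seed;
identical seeds give byte-identical prediction files, and a saved bundle
(`save_cpi_stack()`: serialized model + plain-text manifest) reproduces
its predictions exactly after reload.

## What the synthetic generator emulates — and what it does not

`synth_corpus()` writes the exact three-file ChemProt dialect plus
deterministic parses. Each sentence instantiates one of ~20 class
templates (3–5 per CPR group): classes 3/4/5/6/9 embed a class-typical
interaction word; class 10 uses neutral co-occurrence wording (mapped to
CPR:10 in the generator's dictionary) or no interaction word at all.
Templates vary the structural signals the features read: chain, star and
appositive parse shapes; adjacency; brackets; "significantly"; substrate
cue words; negation; bystander entities (which also create extra
CPR:10-labelled pairs). Entity surfaces are drawn from small chemical and
protein name pools; sentence-initial tokens are capitalized so the
splitter sees natural boundaries.

Default conditions: 40 documents × 3 sentences for training, 15 × 3 held
out, class prior (0.15, 0.18, 0.12, 0.12, 0.13, 0.30) over
(3, 4, 5, 6, 9, 10) — leaning on CPR:4 and CPR:10 as real candidate sets
do — and zero label noise, under which the planted interaction word
determines the label exactly (a decision stump on the word's dictionary
CPR scores 100%; the generator's self-consistency test). A noise rate
flips a sentence's label uniformly to another class while the wording
keeps signalling the planted one.

These corpora are deliberately easy: the signal is strongly separable, so
the end-to-end micro-F1 ≥ 0.9 checks in the test suite verify *plumbing*
— candidate construction, masking, featurization, stacking, fold
averaging, selection, evaluation — not linguistic robustness. Passing
them says nothing about performance on real text, where interaction
words are ambiguous, parses are noisy, classes 3 and 4 share vocabulary,
and most published systems stay below F1 0.65. The generator also makes
no attempt at realistic lexical distributions, coreference, anaphora or
cross-sentence relations.

The template grammar is versioned with the package: changing it changes
every downstream expectation, so it should be treated as frozen test
infrastructure, not a tuning surface.

## Problem sizes used by the tests

The shipped suite runs entirely from generated data: oracle comparisons
use 1100+ random graphs and sentences; model-level tests use 12–20
documents with 4–5 folds; the end-to-end and ablation checks use
40-document training corpora with the full 10 folds across three seeds.
These sizes were chosen as the smallest at which every class is
well-represented in every fold; the pipeline itself has no scale limits
beyond memory, and the candidate builder is linear in sentences ×
entities per sentence.

## Known limitations

* Sentence-bound by design: cross-sentence relations are invisible
  (reported, not recovered). Multiple-instance learning over a pair's
  triplet bag is the natural next step and is out of scope here.
* The seed dictionary is a small curated list, not a full trigger
  lexicon; recall on real corpora depends directly on dictionary
  coverage, and `read_interaction_dictionary()` exists precisely so users
  can supply richer ones.
* Dictionary matching is exact-token (optionally suffix-stemmed), not
  lemmatized; morphology-rich triggers need dictionary entries per form.
* No probability calibration: stage-III scores order predictions well but
  are not calibrated posteriors.
* LDA degrades gracefully but inelegantly on collinear one-hot blocks
  (constant-within-group columns are dropped before fitting); with very
  few candidates per class, prefer the tree-only stage-II configuration.
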