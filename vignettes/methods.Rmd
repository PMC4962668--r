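---
title: "Methods: sieve coreference and joint decoding for CID extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sieve coreference and joint decoding for CID extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sievecid)
```

## The problem

Chemical-induced disease (CID) extraction asks, for a PubMed abstract, which
(chemical, disease) concept pairs stand in a marker/mechanism relation — the
chemical correlates with, or plays a role in the etiology of, the disease.
The output is a set of ordered concept-id pairs per abstract, with ids drawn
from a MeSH-like vocabulary whose C branch covers diseases and whose D
branch covers drugs and chemicals. Two things make this harder than
sentence-level relation classification: entities are reported as normalized
ids rather than strings, and a substantial share of relations is expressed
across sentence boundaries through coreferential re-mentions ("this side
effect", an abbreviation, a morphological variant).

`sievecid` implements a full desk-scale pipeline: joint named-entity
recognition and normalization, nine-pass sieve coreference resolution that
converts inter-sentence relations into intra-sentence candidates, a linear
hinge-loss relation classifier over a large dependency-based feature set,
and a five-step distant-supervision corpus builder driven by a curated
relation table.

## Entity recognition and normalization

### Structured perceptron NER

Sentences are tagged over the five-label alphabet {B-DS, I-DS, B-CD, I-CD,
O} by a structured perceptron decoded with left-to-right beam search. A
state's score is the sum over positions of `w · f(x, i, y_{i-1})` with the
current tag conjoined into every feature name. The feature set is the
standard lexicographic one: word identity and stem, orthographic shape,
±2-token context windows, POS of the current and neighboring tokens,
per-branch dictionary-hit flags (longest ontology match covering the
token), and the previous tag.

Training uses inexact search with early-update violation fixing: the beam
is tracked against the gold prefix, and at the first position where the
gold prefix falls out of the beam the weights are updated with the feature
difference between the gold prefix and the best beam prefix, abandoning the
rest of the sentence. A running average of the weights is kept (the
standard `w − u/t` trick) and used for decoding. Instance order is shuffled
per epoch under a caller-supplied seed; training is otherwise exactly
deterministic, which the tests assert bit-wise.

Ties in the beam are broken by ranking states on (score, lexicographic tag
key) with the tag order O < B-CD < B-DS < I-CD < I-DS. We chose a total
order on tag strings rather than insertion order because an independent
exhaustive-enumeration oracle can reproduce it exactly; with a zero model
the decoder therefore returns all-O. The oracle tests decode with
`beam_width = 5^n` on random sentences of at most 6 tokens and require
bit-identical argmax sequences against enumeration of every BIO-valid
sequence under the same scoring function.

### Normalization: SSI with a skip-gram back-off

A mention is linked to a concept of the branch matching its type by a
two-stage back-off. The first stage is a supervised semantic indexing (SSI)
model: a token-token correlation matrix `W` scoring
`bow(mention)' W bow(concept)`, with concept bags built from the preferred
name plus synonyms. `W` is initialized to the identity — so the untrained
score is exactly the token-overlap count, a closed form the tests exploit —
and trained by margin ranking with one uniformly sampled same-branch
negative per positive per epoch. The second stage scores cosine similarity
between averaged skip-gram token vectors of the mention and the concept's
preferred name; it only sees mentions the SSI stage leaves below threshold.
Both acceptance thresholds default to 0 because no principled values are
available a priori; they are configuration, not constants.

The skip-gram trainer is a small negative-sampling implementation intended
for the package's toy corpora (default dimension 200, the conventional size
for biomedical vectors); a pretrained model in word2vec text format can be
substituted via `read_word2vec()`, which is how a production deployment
would use large external vectors.

### Joint decoding

Joint decoding augments the per-position beam score with a normalization
term. Our reading of the piecewise scoring function is span-centric:

* a begin tag starts a candidate span and contributes the best-concept
  score of the one-token span;
* an inside tag grows the open span and contributes the best-concept score
  of the grown span (the two-argument form only makes sense as span
  extension, so the beam state tracks the open span);
* when a completed span's best-concept score falls below `none_threshold`,
  every position of that span retroactively contributes the constant
  `none_threshold` instead and the span is emitted unlinked;
* an O position contributes the same constant.

With the default `none_threshold = 0` the O and unlinked cases contribute
nothing, which recovers the piecewise form exactly. Making O positions
carry the constant as well is what gives the rewrite its crucial
invariance: if the threshold exceeds every attainable concept score, every
position of every sequence carries the same constant, and the argmax is the
NER-only argmax. `none_threshold = +Inf` is therefore handled symbolically
— sequences are compared by (number of constant positions, residual score)
— and the tests assert that the joint spans then equal `beam_decode`'s
spans everywhere, all unlinked. A scale factor (`nen_scale`, default 1) is
exposed because nothing guarantees that perceptron scores and
normalization scores are commensurate.

## Sieve coreference resolution

Candidate pairs are all unordered pairs over the pool of entity mentions
and noun phrases (greedy POS chunking with the pattern
`determiner? (adjective|noun|number)* noun`, determiners excluded).
Coreference here is mention unification, not anaphora resolution, so kept
pairs are clustered by connected components; no antecedent direction is
recorded. Pairs whose two sides carry different entity types are never
merged. The cascade order is fixed; a pair kept by sieve *k* is invisible
to later sieves:

1. **Identical concept id** from the normalization step.
2. **Abbreviation expansion.** `(SHORT)` parentheticals are validated by
   strict right-to-left character alignment of the short form inside the
   candidate long form (first character anchored at a word start). Strict
   alignment cannot validate pairs like PND/prednisone whose interior
   letters appear out of order, so a fallback accepts the single preceding
   token when it starts with the short form's first letter and contains all
   its letters.
3. **Grammatical conversion**: preposition substitution, preposition drop
   with substring swap, and the two rotation rules, over the inventory
   {of, in, on, for, with, to}; a variant must resolve in the ontology to
   the partner's id.
4. **Number replacement** across arabic 1–20, roman i–xx, cardinals
   one–twenty and multiplicatives single–quadruple (the inventory is
   config-extensible; twenty is an arbitrary desk-scale cap).
5. **Synonym replacement**: one side's surface is a dictionary synonym of
   the partner's concept.
6. **Affix normalization** from a fixed, extensible table: prefix swaps
   macro/micro, hyper/hypo, intra/inter and removals; suffix swaps
   -toxicity/-toxic, -emia/-oma, -ic/-y and removals.
7. **Stemming**: the Porter-stemmed phrase is looked up in a stemmed
   ontology index. Like every variant sieve, the transform must actually
   change the phrase; a phrase its own stem leaves unchanged was already
   testable raw in sieve 5, and letting sieve 7 re-match raw surfaces would
   make it subsume sieve 5 entirely.
8. **Partial match**: mutual-maximal stemmed-token overlap with at least
   two shared stems covering at least half of the shorter phrase, and at
   least one unshared stem on *each* side. The genuinely partial pairs this
   sieve exists for ("calcium channel blocking agents" / "calcium channel
   blockers") always leave an unshared head on both sides, whereas
   permutation and containment pairs — which belong to the variant sieves —
   never do. We considered requiring head-token equality instead, but the
   canonical example above has unequal heads ("agents" vs "blockers") even
   after stemming, so that criterion rejects exactly the pairs the sieve
   should keep. Number-form tokens are ignored as uninformative.
9. **Hyponym terms**: a noun phrase matching a small chemical ("drug",
   "dose", ...) or disease ("disease", "case", "infection", "side effect",
   ...) dictionary is linked to the nearest matching typed mention within
   two sentences, preferring the nearest preceding one (anaphors usually
   follow their antecedents).

After clustering, noun phrases sharing a cluster with typed, linked
mentions become mentions with the cluster's majority type and id (ties
resolved by the earliest mention), provenance `coref`. Gold mentions are
never modified. This label propagation is the inter-to-intra conversion:
a chemical and a disease id that co-occurred only across sentences now
co-occur inside one.

## Relation extraction

Every (chemical mention, disease mention) pair co-occurring in a sentence
is a candidate. Five namespaced feature families are extracted: token
features of each entity head (word, stem, shape, character 1–4-grams,
POS); neighboring-token features from all 2-step dependency paths around
each head; token 1–4-grams in a ±3 window around each entity; word,
dependency and mixed n-grams over the window spanning the pair; and
shortest-dependency-path features (bucketed length, word and label n-grams
along the path, governor–dependent word pairs, edge walks
word–label–word and vertex walks label–word–label with their
sub-structures). Multi-token mentions are represented by their syntactic
head for path and neighbor features; mention tokens are blinded to
CHEM/DIS placeholders in families 2–5 so the classifier cannot memorize
surfaces, while family 1 keeps raw forms. Feature values are occurrence
counts. When a sentence has no parse, families 2 and 5 are simply absent.

The shortest path is computed by breadth-first search over the arcs
treated as undirected, recording each arc's direction; neighbors are
expanded in ascending token index so ties resolve to the lexicographically
smallest index sequence. The classifier is a linear L2-regularized
hinge-loss (L1-loss) support vector machine with balanced class weights and
`C = 1` by default; the fitted hyperplane is extracted into a named sparse
weight vector so prediction is a dot product. Abstract-level output is the
set of distinct id pairs with at least one positive candidate; unlinked
mentions are excluded.

Training labels are distant: a candidate is positive when its id pair is
in the document's curated relation set, negative otherwise (all
co-occurring pairs, not a sample — at desk scale exhaustive negatives are
cheap and unbiased).

## The silver corpus builder

The five construction steps are pure functions composed by
`build_silver()`: filter the curated table to marker/mechanism (M)
evidence; collect the referenced abstracts from a store; drop abstracts on
an exclusion list (the evaluation corpus — the builder guarantees zero
overlap); dictionary-annotate chemical and disease mentions
(case-insensitive leftmost-longest matching at token boundaries over the
full abstract — morphological expansion is deliberately left to the sieve
machinery downstream); and keep sentences witnessing a curated pair.
Step 5 defaults to the strict reading — the co-occurring pair must be a
curated M pair, since type-only co-occurrence would plant co-occurrence
noise in a corpus meant for relation supervision — and a flag relaxes it
to type-only. Sentence splitting is rule-based (period/question/
exclamation with an abbreviation guard list) and pluggable, like
tokenization.

## Synthetic fixtures: what they emulate, and what they do not

All tests run on generated data. `make_ontology()` plants concept names
that give each variant sieve real work (prepositional names, numbered
names, affixed names, synonym pairs); `make_documents()` builds abstracts
from a closed template inventory with gold mentions, gold relations and
chain dependency parses, planting three mechanisms on demand: an
intra-sentence pattern whose trigger token lies between the pair, an
inter-sentence pattern witnessed by an anaphoric hyponym ("this
complication"), and a defined-then-reused abbreviation. Defaults are
desk-scale: 8 concepts per branch, 12 documents of 4 content sentences,
a quarter of documents realized inter-sententially and a quarter through
abbreviations — the proportions stress both conversion mechanisms without
dominating the corpus. `make_sieve_showcase()` is a hand-built document in
which, for every sieve, at least one pair is keepable by that sieve alone,
which is what makes exact cascade-ablation testing possible.

The generator is deliberately unlike real PubMed prose: vocabulary is
closed, parses are chains, sentences are short, normalization surfaces are
dictionary synonyms. Passing tests therefore demonstrate that the
algorithms are implemented correctly (decoding is exact, training
separates separable data, sieves keep exactly their intended pairs, the
planted generative rule is recoverable), not that the pipeline reaches any
particular accuracy on real abstracts — that would require the real corpus,
the full vocabulary and pretrained vectors, none of which are shipped.

Problem sizes used by the test suite and the acceptance script: decoding
oracles on 100 random sentences of at most 6 tokens; perceptron
learnability on the 40-sentence separable corpus within 10 epochs;
planted-signal recovery on ~500 held-out candidates per seed across 5
seeds; dependency-path checks on 50 random 8-node trees. These sizes keep
every oracle exhaustive (enumeration over all BIO-valid sequences is
feasible only for short sentences) while still exercising each code path.

## Numerical and degenerate-input choices

* All character offsets are 0-based half-open over `title + " " + abstract`.
* Unlinkable mentions serialize as concept `-1` and are excluded from
  id-level evaluation.
* Precision/recall/F1 return 0 on zero denominators rather than erroring.
* Empty sentences decode to empty tag sequences with score 0; epochs = 0
  yields a zero model; a corpus without mentions trains to all-O.
* Disconnected parses yield an absent path and the path-dependent feature
  families are omitted.
* Every stochastic component (instance shuffling, negative sampling,
  embedding initialization, fixture generation) is seeded by the caller;
  equal seeds give bit-identical results, which the suite asserts.

## Known limitations

Composite and discontinuous mentions are out of scope (one contiguous span,
one id). Pronominal anaphora is not attempted — the hyponym sieve covers
the nominal anaphora the task actually exhibits. The skip-gram trainer is
not performance-tuned and should be replaced by pretrained vectors beyond
toy scale. Sieve 8's partial-overlap criterion, like any token-overlap
heuristic, can still merge long near-duplicate noun phrases that a human
would keep apart; the cascade order (id-based sieves first) and the
mutual-maximality requirement are the guards.
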