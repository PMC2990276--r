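---
title: "Semantic spaces and literature-based discovery with semleap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic spaces and literature-based discovery with semleap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semleap)
```

## The problem

Literature-based discovery (LBD) looks for plausible connections between
concepts that never appear together in the literature. The classical A-B-C
scheme searches for a concept C that shares intermediate "B" concepts with a
starting concept A: in *open* discovery one starts from A and looks for
candidate C's; in *closed* discovery one starts from a suspected pair (A, C)
and looks for the bridging B. Enumerating B's symbolically scales badly.
semleap instead encodes an entire corpus into fixed-dimensional vector
spaces in which indirect relationships are *already present geometrically*,
so both discovery modes reduce to nearest-neighbor search.

Two kinds of input are supported, each with its own space:

* **occurrence data** (per-citation lists of concept identifiers and
  free-text terms, the kind of output a concept tagger produces) feed a
  *general-association* space built by reflective random indexing;
* **predications** (subject-PREDICATE-object triples with citation
  provenance, the kind of output a relation extractor produces) feed a
  *predication* space built with predicate-specific permutation binding.

## Elemental vectors

Every concept, term, and document representation is built from sparse
ternary *elemental vectors*: of the `d` coordinates (default 500), `s`
(default 10) are non-zero, half `+1` and half `-1`. Two such vectors are
near-orthogonal with high probability — the expected absolute cosine at the
defaults is about 0.02 — so a sum of elemental vectors behaves like a
low-dimensional record of the set of names it contains.

An elemental vector is a pure function of its owner's name and the global
seed: a 64-bit hash of the name seeds a counter-based generator that draws
the `s` coordinates and alternates their signs. This has two consequences
that the rest of the package relies on. First, nothing need be stored —
vectors are regenerated on demand, bit-identically. Second, the space is
independent of corpus traversal order, because no generator state is shared
between names. `d`, `s`, and the seed live in `space_config()`; `s` must be
even so the signs balance, and `s > d` is rejected as infeasible.

## The general-association space (RRI)

`build_rri()` runs one term-document-term reflective cycle:

1. each document vector is the weighted sum of the elemental vectors of the
   tokens (concepts *and* terms) it contains;
2. each token's semantic vector is the sum of the vectors of the documents
   it occurs in, normalized to unit length.

Tokens distributed alike end up with similar semantic vectors *even if they
never co-occur*, which is exactly the property open discovery needs.
Because concepts and terms share one document space, `translate()` maps
free-text terms onto concepts by nearest-neighbor search — useful when the
user knows a word but not the controlled vocabulary identifier.

The token weight is configurable: `idf` (`log(N/df)`, the default — rare
tokens carry more information), `log_entropy` (`1 - log(df)/log(N)`), or
`none`. With `weighting = "none"` and one cycle the construction is linear
in the corpus, so duplicating every document changes no cosine — a property
the test suite checks. Additional reflective cycles (`cycles > 1`) rebuild
document vectors from the learned semantic vectors and re-accumulate; one
cycle is the default because it already produces the indirect associations
the discovery operations need, and further cycles progressively blur the
distinction between first- and second-order association.

## The predication space (PSI)

Each predicate gets a deterministic permutation of the coordinates `1..d`
(seeded shuffle keyed by the predicate name). Permuting an elemental vector
yields a near-orthogonal vector for the predicate-argument *pair*, so
predication structure can be encoded without growing the space. The subject
role uses the permutation itself, the object role its inverse — binding is
directional and exactly invertible.

For each predication *A --P--> B*, `build_psi()` accumulates

    semantic(A) += bind(P, subject, e(B)) + e(B)
    semantic(B) += bind(P, object,  e(A)) + e(A)

The *bound* term records which predicate connected the concepts; the *raw*
elemental term makes two concepts that share a predication partner similar
even when their predicates differ. That second term is what makes the
"logical leap" work: second-order relatedness is encoded directly into the
semantic vectors, so `logical_leap()` is nothing more than a semantic-to-
semantic nearest-neighbor search (with direct predication partners screened
out).

Repeated assertions of the same triple from different citations accumulate
once per citation by default, so heavily-asserted relations weigh more;
`unique_triples = TRUE` switches to set semantics. The choice only scales
vector magnitude for a given pair, not direction, so rankings for a concept
with a single partner are unaffected; with many partners the frequency
weighting shifts emphasis toward well-attested relations, which mirrors the
distributional emphasis of the occurrence space and is therefore the
default.

Searches against the space come in three forms, all in `direct_search()`:

* **unrestricted**: candidates are ranked by the cosine between the cue's
  semantic vector and the candidate's raw elemental vector — "everything
  this concept occurs in predications with";
* **single predicate** (+ the cue's role in it): the probe becomes
  `bind(P, role, e(candidate)) + e(candidate)`, pinning the relation type;
* **template** (`predicate_template()`, shipped biological and clinical
  sets as editable YAML): each candidate is scored by its *best* admissible
  predicate, i.e. the maximum over template predicates (both roles) of the
  bound-vector cosine. Two deliberate choices here: the raw elemental term
  is dropped, because it is shared by every predicate type and would let
  non-template relations leak through; and scores are combined by maximum
  rather than sum, because summing `2 x |template|` near-orthogonal probes
  dilutes a single genuine relation below the noise floor. The shipped
  template memberships are a configuration default, not a claim — only one
  canonical example of each family is fixed by convention
  ("associated_with" biological, "treats" clinical).

## Discovery operations

* `nearest_indirect_neighbors()` — open discovery: nearest semantic
  neighbors that never co-occur with the cue in any citation of the past
  corpus. Screening is citation-level; the cue is always excluded.
* `general_search()` — the same screened search for multi-concept cues
  (candidates co-occurring with *any* cue are dropped).
* `logical_leap()` — second-order associates in the predication space; by
  default concepts sharing a *direct predication* with the cue are screened
  (predication-level), since in that space "directly related" means
  "related by a predication". The open-discovery harness can evaluate
  either space under citation-level screening, which is the uniform
  definition the time-sliced evaluation uses.
* `middle_term()` — closed discovery in the predication space: the nearest
  *elemental* vector to the sum of the two cue semantic vectors is exactly
  the concept whose elemental both cues accumulated, i.e. the shared
  partner. `k = 1` by default: a predication chain needs one bridge, and
  the single strongest candidate is the hypothesis worth verifying. Every
  candidate is verified against the predication database (`verified` is
  true iff it occurs in a predication with each cue).
* `bridging_concepts()` — closed discovery in the occurrence space, with
  verification by direct co-occurrence with both cues.
* `link_concepts()` — retrieves the neighborhood of a combined cue vector,
  scales its proximity matrix with Pathfinder, and (for predication
  spaces) annotates each retained edge with its supporting predicates,
  pruning edges supported by none — a geometric association between
  concepts that share no predication is not shown as a link. For
  predication spaces the neighbor group is drawn from *both* layers
  (elemental neighbors are direct partners, semantic neighbors are
  second-order relatives) and the proximity is the symmetrized
  semantic-to-elemental cosine, so the scaled network follows predication
  structure and chains like A-X-Z-Y-B connect the cues through interposed
  concepts.

Multi-concept cues are combined by normalized vector sum throughout (sum
and average give the same direction after normalization).

## Pathfinder network scaling

`pfnet()` keeps an edge only if no path of at most `q` edges is cheaper
under the Minkowski r-metric (path cost `(sum w_i^r)^(1/r)`; maximum edge
weight at `r = Inf`). Defaults are `r = Inf`, `q = n - 1` — the sparsest
standard network, which provably contains a minimum spanning tree and gives
legible, tree-like displays. Numerical choices:

* computation runs on the `w^r` scale (max composition for `r = Inf`), so
  no roots are taken; the `q = n - 1` case uses repeated path doubling to
  convergence and bounded `q` a length-limited dynamic program;
* ties — a competing path exactly as cheap as the edge — retain the edge,
  preserving MST containment;
* retained edge weights are copied from the input matrix untouched;
* `Inf`/`NA` entries mean "no edge"; asymmetric or negative matrices are
  rejected; comparisons use a 1e-9 relative tolerance (with continuous
  random weights, near-ties at that scale do not occur).

Cosines become distances via `1 - cos` by default; `1/cos` is offered
because the two differ in *sums* (hence in finite-`r` path costs) even
though they agree in rank order. The test suite checks the implementation
edge-for-edge against an exhaustive simple-path enumeration oracle on
random graphs of up to 12 nodes.

## The synthetic corpus and what it shows

`generate_corpus()` builds a two-slice corpus with known ground truth,
standing in for a time-sliced literature. Its defaults are the package's
study conditions:

* 1500 concepts, 300 terms, 2000 past citations, Poisson(5) concepts per
  background citation, Zipf(1.1) background concept frequencies —
  heavy-tailed like real concept statistics;
* 200 planted predication chains A -> B <- C (predicates drawn from the
  biological template), the ground truth for closed discovery;
* 100 planted indirect pairs (X, Y): each gets 3 dedicated bridge concepts
  Z with past citations {X, Z} and {Z, Y}, never {X, Y}; the future slice
  contains {X, Y} directly. These are the gold standard for open
  discovery: the bridges make X and Y distributionally similar while
  screening removes the bridges themselves from the candidate list;
* 2500 background noise predications over the background pool (kept away
  from chain and pair concepts so the planted structure is exactly the
  ground truth), and term "aliases" attached to background concepts (80%
  emission) so term-concept translation has recoverable structure.

The generator is byte-deterministic given its seed, re-audits its own
invariant (no planted pair co-occurs in the past slice) after writing, and
ships its ground truth as a JSON manifest. An infeasible request — more
planted structure than concepts, no room for background citations — fails
with the violated constraint named.

What passing on this corpus does *not* show: real extraction output has
annotation errors, negation, synonymy and massively skewed predicate
distributions; planted bridges here are clean and dedicated, so absolute
precision figures on synthetic data say nothing about absolute performance
on a real corpus. The synthetic evaluation establishes *relative* and
*structural* claims only — learned spaces beat the random-elemental
baseline, screening is sound, recovery degrades with dimension reduction —
which is why the evaluation harness always reports the random baseline
alongside.

`generate_psi_benchmark()` is the second generator: a predication set in
which every concept participates in a bounded number of distinct
predications (caps drawn uniformly from 1..20, so the low-degree subset is
populated). On it, encode/retrieve fidelity of the predication space is
scored directly: at `d = 500`, recall@20 of true partners is about 0.96 and
rank-1 precision for concepts in at most 5 predications is essentially 1,
rising monotonically with dimension (about 0.84 at `d = 250`, about 0.995
at `d = 1000` under seed 1) — the signature of interference from random
elemental overlap, which more dimensions dilute.

## The time-sliced evaluation harness

`evaluate_open()` formalizes open discovery as prediction of future
co-occurrence: for each test concept, take its `k = 10` nearest indirect
neighbors in the past slice and score the fraction that co-occur with it
directly in the future slice (precision@10 against the future gold
standard). Two built-in null checks: evaluating the past against itself is
*exactly* zero (every future co-occurrence was screened), and
`random_baseline()` — concepts represented by bare elemental vectors —
gives the chance floor. `select_test_concepts()` applies the eligibility
rules (corpus frequency at most 100000, at least 5 predications as
subject, both bounds inclusive) before sampling. Per-concept precisions
are summarized as mean with standard error (sample SD / sqrt(n)), and all
retrieved candidates are binned by cosine (width 0.1 over [0, 1]) against
their hit fraction — `autoplot()` draws this strength-vs-accuracy profile.
Model comparisons use a one-sided sign-flip permutation test on the paired
per-concept precisions (`paired_permutation_pvalue()`).

Problem sizes used by the shipped tests and `scripts/acceptance.R`: the
full default corpus (100 test concepts), the 1000-concept fidelity
benchmark at `d` in {250, 500, 1000}, 100 random graphs of up to 12 nodes
for the Pathfinder oracle, and 100 global seeds of the worked smad-proteins
example. These sizes were chosen so the whole evaluation reruns in well
under a minute of CPU while every planted effect remains unambiguous.

## Degenerate inputs and numerical conventions

* Zero-content semantic vectors (a token whose every document was skipped)
  are dropped from the store with a message, never normalized.
* All finalized semantic vectors have unit norm to within 1e-9.
* Nearest-neighbor ties break lexicographically by name, so output is
  deterministic; search is exhaustive (stores here hold at most ~10^6
  names; correctness over speed, no approximate indexing).
* Malformed predication and occurrence lines are counted and skipped, not
  fatal; duplicate citation ids merge; an all-filtered predication file
  yields an explicit empty-database warning.
* A concept co-occurs with itself whenever it occurs at all; self-pairs
  are excluded from every neighbor list upstream, so the convention only
  matters to verification scans, where it must be fixed.

## Known limitations

* Negation handling is a filter (drop `NEG_`-prefixed and listed
  predicates), not negation-aware reasoning.
* One reflective cycle and citation-level screening are defaults chosen
  for the discovery use case, not fitted to any corpus.
* The biological/clinical template memberships are conventional defaults;
  users with a specific relation inventory should supply a custom set.
* Exhaustive search makes interactive use on corpora beyond ~10^6 concepts
  memory- and latency-bound; approximate indexing is deliberately out of
  scope.
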