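# semleap

Distributional semantic spaces for literature-based discovery (LBD).

`semleap` is for text-mining and informatics researchers who want to find
*plausible but unreported* connections between biomedical concepts — the
A–B–C scheme in which two concepts A and C that never appear together are
linked through shared intermediate concepts B. Instead of enumerating B
concepts symbolically, the package encodes an entire corpus into compact
vector spaces in which indirect relatedness is present geometrically, so
both open discovery (find candidate C's for a cue A) and closed discovery
(find the bridge B for a suspected pair) reduce to nearest-neighbor search.

## The models

**Elemental vectors.** Every concept/term gets a sparse ternary signature
e(x) ∈ {−1, 0, +1}^d with s non-zeros (defaults d = 500, s = 10), generated
deterministically from its name and a global seed. Random pairs are
near-orthogonal: E|cos(e(x), e(y))| ≈ 0.02 at the defaults.

**General associations (reflective random indexing).** One
term→document→term cycle over an occurrence corpus:

    doc(D)      = Σ_{x ∈ D} w(x) · e(x)          w = idf by default
    semantic(x) = normalize( Σ_{D ∋ x} doc(D) )

Tokens with similar distributions get similar vectors even if they never
co-occur. Terms and concepts share the document space, so free-text terms
can be *translated* to concept identifiers by nearest-neighbor search.

**Predication space (permutation binding).** Each predicate P gets a
deterministic coordinate permutation Π_P (subject role; the object role
uses Π_P⁻¹). For every predication A —P→ B:

    semantic(A) += Π_P e(B) + e(B)
    semantic(B) += Π_P⁻¹ e(A) + e(A)

The bound term pins the relation type; the raw term makes concepts sharing
a partner similar even across predicate types, which enables the
**logical leap**: second-order associates are retrieved directly by
semantic–semantic search. The shared **middle term** for a pair (A, C) is
the nearest *elemental* vector to semantic(A) + semantic(C), verified
against the predication database.

**Pathfinder scaling.** Result neighborhoods are displayed as sparse
networks: an edge survives iff no path of ≤ q edges is cheaper under the
Minkowski r-metric (defaults r = ∞, q = n − 1, which retain a minimum
spanning tree).

**Time-sliced evaluation.** Open discovery is scored as prediction of
future co-occurrence: the k = 10 nearest *indirect* neighbors of a test
concept in a past corpus are checked for direct co-occurrence in a future
corpus, against a random-elemental-vector baseline. A synthetic corpus
generator plants A→B←C predication chains and indirect future pairs so
every operation has exact ground truth.

## Worked example

The canonical second-order retrieval: a fixture with two planted
predications — `smad_proteins INTERACTS_WITH transforming_growth_factor_beta`
and `latent_tgf_beta_binding_protein INTERACTS_WITH
transforming_growth_factor_beta` — plus 50 random distractor predications.

```r
library(semleap)

fix <- tempfile(fileext = ".tsv")
smad_fixture(fix)
pdb <- read_predications(fix)
psi <- build_psi(pdb, space_config(dimension = 500, global_seed = 1))

logical_leap(psi, "smad_proteins", k = 3)
#> # Discovery report [PSI] cues: smad_proteins (1 screened out)
#> # A tibble: 3 × 4
#>   concept                         cosine screened verified
#>   <chr>                            <dbl> <lgl>    <lgl>
#> 1 latent_tgf_beta_binding_protein 1      FALSE    NA
#> 2 distractor_02                   0.0838 FALSE    NA
#> 3 distractor_18                   0.0797 FALSE    NA
```

The leap surfaces `latent_tgf_beta_binding_protein` at rank 1 with cosine
1.0 — the two proteins share their only predication partner, so their
semantic vectors coincide — while the directly-related
`transforming_growth_factor_beta` is screened out (it is a first-order,
not a second-order, associate). Closed discovery then recovers the bridge:

```r
middle_term(psi, "smad_proteins", "latent_tgf_beta_binding_protein")
#> # A tibble: 1 × 3
#>   concept                         cosine verified
#>   <chr>                            <dbl> <lgl>
#> 1 transforming_growth_factor_beta  0.707 TRUE
```

`verified = TRUE` means the candidate occurs in predications with *both*
cues — the explicit two-predication chain that explains the association.

On a synthetic time-sliced corpus with 100 planted indirect future pairs,
the learned space predicts future co-occurrence far above the
random-vector floor:

```r
gen    <- generate_corpus(synth_spec(seed = 1), tempfile("corpus"))
past   <- read_occurrences(gen$paths$past)
future <- read_occurrences(gen$paths$future)
rri    <- build_rri(past, space_config(dimension = 500, global_seed = 1))
cues   <- gen$manifest$future_pairs$a

glance(evaluate_open(rri, past, future, cues, k = 10))
#> # A tibble: 1 × 5
#>   mean_precision   sem n_concepts     k model
#>            <dbl> <dbl>      <int> <dbl> <chr>
#> 1            0.1     0        100    10 RRI
```

Each cue has exactly one planted future partner, so 0.1 = 1/10 is the
ceiling; the random baseline on the same corpus scores 0.007 (sign-flip
permutation p = 2.0e-4).

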