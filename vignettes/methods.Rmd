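---
title: "Methods: quantile-rank support scoring of biomedical associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantile-rank support scoring of biomedical associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assocsupport)
```

## The model

The package assesses a dataset of typed biomedical associations — an
edge list over eleven entity types (genes/proteins, cell lines,
tissues, compounds, diseases, pharmacological classes, chemical
entities, pathways, cellular components, domains, molecular
functions) — against a collection of *metapath embedding spaces*.
Each space represents one biomedical context: entities that lie close
in it share properties in that context (co-membership in pathways,
similar interaction patterns, shared disease involvement, ...).  The
central assumption is therefore that **embedding proximity is evidence
of prior knowledge about a pair**, and the package's job is to turn
raw proximity into a calibrated, comparable score.

Raw cosine distances are not comparable across spaces: different
contexts have different intrinsic distance scales.  The support score
is therefore a *quantile rank*: the fraction of background distances —
cosine distances between arbitrary cross-role entity pairs of the same
space — at or below the observed pair's distance.  This is a
probability-integral transform per space; under the null hypothesis
that a pair is an arbitrary pair, its quantile rank is uniform on
(0, 1], which is what makes cutoffs such as 0.05 meaningful and
comparable across contexts.

Three layers are built on this score:

1. **Aggregation.** An edge's dataset-level score is the *minimum*
   quantile rank over the metapaths covering it: an association counts
   as supported when at least one biomedical context supports it
   ("best context wins").  The supported fraction of the dataset is
   reported at a cutoff grid.  The minimum rule is the aggregation
   consistent with reading a dataset-level supported percentage that
   exceeds what any single context covers; its cost is an elevated
   null rate (see *Calibration*), which is exactly why the permutation
   null is attached to it.
2. **Calibration.** The same scoring is applied to degree-preserving
   permutations of the input network, yielding an *expected support*
   curve (mean ± sd per cutoff over the ensemble) and per-pair
   empirical enrichment p-values against the pooled null quantile
   ranks, with the enrichment score −log10(p).
3. **Prediction.** Per metapath, an AUROC measures how well negated
   distance separates observed edges from permuted ones; a second
   AUROC does the same for node pairs with similar interaction
   profiles.  High-AUROC metapaths are the descriptors one would feed
   to a downstream link-prediction model.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `cutoffs` | 0.01, 0.05, 0.10, 0.25 | quantile-rank stratification grid; 0.05 is the conventional headline threshold for "supported" |
| `background_n` | 10 000 | sampled background size when exhaustive enumeration is too large; bounds memory while keeping the empirical CDF within ~0.01 of the exact one |
| `exact_threshold` | 10^6 pairs | below this, the background enumerates *all* distinct cross-role pairs, making small-space quantile ranks exact |
| `n_perm` | 25 | permuted networks; balances runtime against Monte-Carlo error of the expected curve and gives enrichment pools of `n_perm × covered edges` values |
| `swap_factor` | 10 | attempted double-edge swaps per edge and relation; ~10|E| attempts is the standard burn-in for edge-swap randomization |
| `profile_jaccard` | 0.5 | minimum neighbour-set Jaccard for a "similar interacting profile" positive |
| `negative_ratio` | 1 | sampled negatives per positive in the profile task |
| `seed` | — | master seed; every stochastic component derives a child seed from it by fixed arithmetic (`seed + index`), so runs are bit-reproducible |

## Design choices where the design was open

* **Background = arbitrary cross-role pairs,** not the space's known
  edges.  The quantile rank must answer "how close is this pair
  relative to arbitrary pairs in this context"; using known edges as
  background would answer a different (conditional) question.
* **Ties count as `≤`.** An observed distance equal to a background
  distance counts against the pair.  This is conservative (a pair is
  never reported closer than the background warrants), deterministic,
  and makes the binary-search implementation exactly equal to the
  brute-force counting oracle.
* **Permutation scheme: degree-preserving double-edge swaps,**
  independently within each (source type, target type) relation;
  undirected swaps for homogeneous relations, target-end swaps for
  bipartite heterogeneous ones; swaps creating self-pairs or
  duplicates are rejected and retried.  Degree preservation is the
  standard null that separates embedding proximity from hubness.
  Single-edge relations are returned unpermuted with a warning.  The
  scheme label `degree_preserving_swap` is recorded in the run
  metadata.
* **Enrichment p-values use the +1 pseudocount,**
  `p = (1 + #{null ≤ obs}) / (1 + pool)`, standard permutation-test
  practice: p is never 0 and never below `1/(pool+1)`.
* **Profile-similarity task.** "Similar interacting profile" is
  operationalised as neighbour-set Jaccard ≥ 0.5 over the input
  network, excluding pairs that are themselves edges; negatives are a
  seeded sample of non-edge, non-positive pairs.  This is the plainest
  reading of "nodes interacting with the same partners" and the
  threshold is exposed as a parameter.  Degenerate graphs (e.g. a
  star, where every non-edge pair is positive) yield positives-only
  label sets with a warning rather than an error.
* **Homogeneous edges are undirected** and canonicalised
  (lexicographic identifier order); heterogeneous edges keep their
  orientation because the two sides play different embedding roles.
  Self-pairs are rejected — a self-distance of 0 would trivially count
  as supported.  Identifier matching is exact and case-sensitive; no
  cross-vocabulary mapping is attempted.
* **Mixed type pairs in one dataset are allowed**; each space is
  matched to each compatible type pair in either orientation, and
  ranking entries carry an `entity_group` so heterogeneous results
  stay separable per type pair.
* **Heterogeneous spaces store two role matrices** (`src.tsv`,
  `dst.tsv`) beside a `meta.yaml`; single-vocabulary spaces store one
  (`emb.tsv`).  Endpoint types are parsed from the first and last
  hyphen-delimited tokens of the metapath name.

## Numerical choices and degenerate inputs

Cosine distances are clamped to [0, 2] against floating-point
round-off; zero-norm vectors are dropped at load time (they have no
direction, hence no cosine), with a logged count.  Quantile ranks are
computed by binary search (`findInterval`) on the sorted background,
which is exactly the `≤`-count.  The AUROC uses the rank-sum
(Mann–Whitney) formulation with midranks, exactly equal to
concordant-pair counting with ties at one half, and invariant under
monotone transforms of the distance.  All-pairs background enumeration
is chunked (2×10^5 pairs at a time) to bound memory.  Empty
intersections — an edge set with no applicable space, a metapath with
an empty null pool, a class with zero covered pairs — degrade to
annotated placeholders, `NA` columns or omitted entries with warnings,
never to crashes.  Ranking ties are broken lexicographically by
metapath name so output order is deterministic.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` draws isotropic standard-normal base vectors per
space and plants signal into a chosen fraction of edges: the target
entity's vector is replaced by the convex pull
`(1−w)·x_dst + w·x_src + ε`, `w = s/(1+s)`, `ε ~ N(0, noise_sd²)`.
Planted targets are distinct, and in homogeneous fixtures planted
sources are drawn outside the planted-target pool, so no vector is
pulled twice and no planted source is displaced by another edge's pull
— each planted pair's geometry is controlled by `s` and `noise_sd`
alone.  Unplanted edges pair independently drawn entities, so a
`signal_fraction = 0` fixture is an exact null.  Per-space vocabulary
dropout exercises coverage handling.  Defaults (5 spaces, 1000
entities, 32 dimensions, 500 edges, 10% dropout) keep exhaustive
backgrounds exact while leaving room for distinct planted targets even
at `signal_fraction = 1`.

The generator does **not** mimic real embedding geometry: real spaces
are anisotropic, hub-dominated and cluster-structured, and real
datasets have skewed degree distributions and correlated contexts.
Passing tests on fixtures therefore demonstrates the *statistical
machinery* — oracle-exact scoring, null calibration, signal recovery,
degree-preserving permutation, reproducibility — not performance on
any real knowledge graph.

## Problem sizes used in the test suite

Unit and property tests run on spaces of 4–100 entities with exact
backgrounds; calibration and recovery checks use the generator
defaults (500 edges, 5 spaces, 1000 entities, 25 permutations);
oracle-equivalence checks sweep 100 random spaces (≤ 50 entities) and
200 random AUROC instances (≤ 200×200 scores).  These sizes were
chosen so that every expected value in a test is either exact or has
Monte-Carlo error far below its assertion tolerance.

## Known limitations

* The minimum-rule aggregate is intentionally liberal; its null rate
  grows with the number of covering contexts (≈ `1−(1−c)^k` for `k`
  independent contexts at cutoff `c`).  Always read it against the
  expected-support curve, which is computed under the same rule.
* Cosine distance is the only metric; spaces whose geometry encodes
  similarity in inner products or Euclidean distances are out of
  scope.
* Enrichment p-values share one null pool per metapath; with few
  permutations on small datasets the p-value grid is coarse.
* No identifier mapping: entities absent from a space's vocabulary
  simply reduce coverage, which is reported rather than imputed.
```{r session}
sessionInfo()
```
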