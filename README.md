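# assocsupport

Quantify how strongly a set of biomedical associations is supported by
existing knowledge, encoded as context-specific **metapath embedding
spaces**, and estimate how much of the set is potentially novel.

## The problem

High-throughput screens keep producing new association datasets —
protein–protein interactions, drug–gene links, disease comorbidities,
drug–cell-line sensitivities.  Before trusting or following up such a
dataset, one wants to know: *which of these pairs are already backed by
current knowledge, in which biological contexts, and which are genuinely
new?*  Knowledge graphs condense that prior knowledge into per-context
embeddings: for each **metapath** (a typed walk pattern such as
gene→pathway→gene), every entity gets a low-dimensional vector, and
entities that are close in a metapath's space share biomedical
properties in that context.

`assocsupport` takes (1) an edge list of typed entity pairs and (2) a
directory of embedding spaces, and produces per-pair, per-context
support scores, a dataset-level support estimate calibrated against a
network-permutation null, and a ranking of the embedding contexts by
their ability to predict the dataset's associations.  Eleven entity
types are recognised (GEN, CLL, TIS, CPD, DIS, PHC, CHE, PWY, CMP, DOM,
MFN); edge sets may be homogeneous (e.g. gene–gene) or heterogeneous
(e.g. compound–gene), and may mix several type pairs.

## The statistic

For an edge \((u, v)\) and a metapath space \(m\) with vectors
\(x_u, x_v\), the **support score** is the quantile rank of the cosine
distance

\[
d_m(u, v) = 1 - \frac{x_u \cdot x_v}{\lVert x_u\rVert\,\lVert x_v\rVert},
\qquad
q_m(u, v) = \frac{\#\{\, d \in B_m : d \le d_m(u,v) \,\}}{|B_m|},
\]

where \(B_m\) is an empirical background of cosine distances between
arbitrary cross-role entity pairs of the same space (enumerated
exhaustively for small spaces, sampled otherwise).  A low quantile rank
means the pair is unusually close in that context — strongly supported.
Per-edge scores are aggregated by the minimum across covering metapaths
("best context wins"), and the dataset-level supported fraction is
reported at a grid of cutoffs (0.01, 0.05, 0.10, 0.25 by default, with
0.05 the headline threshold).

Calibration uses a **degree-preserving permutation null**: repeated
double-edge swaps within each typed relation (bipartite-aware for
heterogeneous relations) keep every node's degree fixed, so excess
support must come from embedding proximity rather than hubness.  The
ensemble yields (i) the *expected support* curve, (ii) per-pair
empirical enrichment p-values
\(p = (1 + \#\{q_\text{null} \le q_\text{obs}\}) / (1 + N_\text{pool})\)
with score \(-\log_{10} p\), and (iii) per-metapath AUROCs (tie-aware
rank-sum estimator) for discriminating observed edges from permuted
ones, plus a node-profile AUROC variant based on neighbour-set Jaccard
similarity.

## Worked example

```r
library(assocsupport)

cfg <- fixture_config(n_spaces = 3, entities_per_type = 200, n_edges = 100,
                      signal_fraction = 0.4, signal_strength = 5, seed = 42)
fx  <- generate_fixture(cfg)
run <- run_support_analysis(fx$edges, fx$spaces, n_perm = 10, seed = 42)
run
#> # Support-assessment run
#> # Support summary: 100/100 edges covered (100.0%)
#> #   quantile rank <= 0.01 :  40.0% of covered edges supported
#> #   quantile rank <= 0.05 :  44.0% of covered edges supported
#> #   quantile rank <= 0.1  :  49.0% of covered edges supported
#> #   quantile rank <= 0.25 :  69.0% of covered edges supported
#> # A tibble: 4 × 4
#>   cutoff observed expected_mean expected_sd
#>    <dbl>    <dbl>         <dbl>       <dbl>
#> 1   0.01     0.4         0.0281      0.0205
#> 2   0.05     0.44        0.109       0.0356
#> 3   0.1      0.49        0.211       0.0351
#> 4   0.25     0.69        0.496       0.0614
#> # Top metapaths by edge AUROC:
#> # A tibble: 3 × 8
#>   metapath     entity_group auroc_edges auroc_profile n_pos n_neg  rank is_top
#> 1 GEN-ctx1-GEN GEN-GEN            0.695         0.470    81   819     1 TRUE
#> 2 GEN-ctx3-GEN GEN-GEN            0.687         0.634    83   835     2 TRUE
#> 3 GEN-ctx2-GEN GEN-GEN            0.682         0.610    85   844     3 TRUE
```

40% of the edges were planted with strong signal, and indeed 40% of
them sit below quantile rank 0.01 while the permutation null expects
only ~3%; at the 0.05 headline cutoff the observed support is 44%
against an expected 11%, i.e. roughly the null rate on top of the
planted fraction.  The planted truth is recovered cleanly:

```r
recover_signal_fraction(run$summary, fx$truth, run$enrichment)
#> # A tibble: 1 × 4
#>   planted_fraction estimated_fraction cutoff enrichment_auroc
#> 1              0.4               0.44   0.05                1
```

With an output directory, `run_support_analysis(..., out_dir = "out")`
additionally writes three TSV tables — the per edge×metapath quantile
ranks with enrichment columns, the digested per-metapath summary
counts, and the metapath ranking — plus a flat metadata file and a
six-panel analytical canvas (`canvas.png`).  `tidy()`, `glance()` and
`autoplot()` methods expose each result as a tibble or ggplot.  A thin
command-line wrapper lives in `inst/exec/assocsupport.R`
(`run` and `simulate` subcommands).

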