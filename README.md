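# clonetrace

Tools for B cell receptor (BCR) repertoire analysis across multiple tumour
sites and therapy timepoints: clonotype networks, depth-matched clonal
sharing, repertoire/phylogeny concordance, clone classification, diversity
and somatic-hypermutation profiling, and minimum-spanning-tree degree
centrality as a predictor of immunosurveilling and temporally persistent
BCRs. It is aimed at immunologists and computational biologists working
with AIRR-style rearrangement tables from multi-site tumour sampling.

## The core method

A clone groups receptor sequences with the same gene-level IGHV call and
identical or point-mutation-related CDR3s; clones are connected components
of the union of a single-substitution sequence network (equal length,
nucleotide Hamming distance 1) and single-linkage clustering of
equal-length CDR3s at amino-acid identity ≥ 0.95.

Within each clone observed in ≥ 2 samples with ≥ 10 unique sequences, the
trimmed sequence stack (terminal columns ≥ 95% occupied, ≥ 80 nt) yields
unique variants, a pairwise Hamming matrix *d*, and its minimum spanning
tree (deterministic tie-breaking). The degree centrality of variant *i*,

> deg(i) = number of MST edges incident to *i*,

predicts whether the variant is immunosurveilling (observed in ≥ 2
metastatic sites) or persistent (≥ 2 timepoints): predict positive when
deg(i) > c for cutoffs c ∈ {1, 2, 10}, scored by sensitivity, specificity
and accuracy. Sharing between samples *A*, *B* is quantified by the median
Jaccard coefficient |A ∩ B| / |A ∪ B| over 10,000 draws of equal-depth
unique-sequence subsamples (90% of the shallowest sample); Ward-D2 trees
on 1 − J are compared to tumour phylogenies by the Pearson correlation of
cophenetic distances with a one-sided label-permutation test.

## Worked example

Everything runs on a synthetic multi-site repertoire with planted ground
truth, so the example is fully reproducible offline:

```r
library(clonetrace)
library(dplyr)
library(purrr)

sim <- simulate_repertoire(sim_config(n_participants = 1), seed = 7)
sim
#> Simulated repertoire: 2038 records, 200 clones, 16 samples; 60 planted
#> hubs (345 SHM collisions)

rec <- assign_clones(sim$records)
networks <- build_clone_networks(rec)
networks
#> Clone lineage networks: 31 clones, 1096 variants (0 clones skipped)

v <- networks$variants
evaluate_degree_classifier(v$degree, v$n_sites >= 2,
                           cutoffs = c(1, 2, 10)) |> tidy()
#> # A tibble: 3 × 8
#>   cutoff    tp    fp    tn    fn sensitivity specificity accuracy
#>    <dbl> <int> <int> <int> <int>       <dbl>       <dbl>    <dbl>
#> 1      1    56   507   533     0       1           0.512    0.537
#> 2      2    55    23  1017     1       0.982       0.978    0.978
#> 3     10    22     0  1040    34       0.393       1        0.969
```

At cutoff 2 the degree predictor recovers the planted disseminated ("hub")
variants with accuracy 0.98: variants with more than two lineage
neighbours are almost exactly the ones observed in several sites. Clone
classes follow the same tibble-first style:

```r
props <- clone_proportions(rec)
cl_max <- props |> group_by(clone_id) |>
  summarise(m = log10(100 * max(proportion)))
model <- fit_expansion_threshold(log10(100 * props$proportion),
                                 n_components = 4, select_bic = TRUE,
                                 constraint_values = cl_max$m)
glance(model)
#> # A tibble: 1 × 6
#>   cutoff frac_expanded     n n_components    bic fallback
#>    <dbl>         <dbl> <int>        <int>  <dbl> <lgl>
#> 1  0.105        0.0583   465            2  -992. FALSE

classes <- classify_clone_class(props, classify_topology(rec), model)
count(classes, clone_class)
#> # A tibble: 4 × 2
#>   clone_class     n
#>   <chr>       <int>
#> 1 A               3
#> 2 B              10
#> 3 C             183
#> 4 D              27
```

The fitted clone-size cutoff (log10 percent scale) separates the planted
expanded component; classes split clones into private/shared ×
expanded/unexpanded. `plot_sharing_matrix()`, `plot_clone_network()` and
`autoplot()` methods render the standard figures.

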