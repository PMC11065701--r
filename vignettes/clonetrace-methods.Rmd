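---
title: "Methods: clonal networks, sharing statistics and degree-centrality prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal networks, sharing statistics and degree-centrality prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrace)
library(dplyr)
```

## Scope and data model

`clonetrace` analyses B cell receptor (BCR, heavy chain) and T cell
receptor repertoires sampled from several anatomical sites and therapy
timepoints of the same participant. The unit of observation is one unique
rearranged VDJ nucleotide sequence in one sample, with a UMI count as its
abundance (one UMI approximates one mRNA molecule), a gene-level V call, a
CDR3 amino-acid sequence, an isotype and a somatic hypermutation (SHM)
count. Everything downstream operates on a plain tibble of such records,
so results compose with ordinary dplyr pipelines.

Upstream read processing (UMI consensus building, V(D)J annotation) is out
of scope: the package starts from an AIRR-style rearrangement table.

## Clonotype assembly

A B cell clone is a set of sequences descending from one pre-B cell:
identical V gene and identical or point-mutation-related CDR3. We build,
per participant and chain, the union of two graphs over unique sequences:

* an edge between sequences of equal length at nucleotide Hamming
  distance exactly 1 (single-substitution network; indels never join);
* an edge between sequences with the same gene-level V call and
  equal-length CDR3s at amino-acid identity >= 0.95 (matches / length).

Connected components of the union are clones. Single linkage is
deliberate: network/connected-component semantics make clone membership
transitive, which is how lineages related through unobserved
intermediates reassemble. The identity threshold applies to the CDR3, not
the full VDJ (the full-VDJ variant can be obtained by clustering on
`vdj_nt` identity externally); at a typical 15-20 aa CDR3 the 0.95
threshold tolerates at most one amino-acid mismatch per pair, and
single-linkage chaining extends this along a lineage. Clustering is never
performed across participants, whose repertoires are expected to be
disjoint up to chance collisions.

## Depth-matched sharing

Raw overlap counts between samples confound sharing with sequencing
depth. All sharing statistics therefore subsample every sample to a
common depth — 90% of the unique-VDJ count of the shallowest sample —
and report the median over repeated draws (10,000 by default; tests and
examples use fewer) of the shared-sequence count, the Jaccard coefficient
|A ∩ B| / |A ∪ B|, or the shared clone count. Medians use the
lower-median convention so the estimator stays on the integer grid of
observable counts. Subsampling operates on unique sequences, not UMIs:
the question is whether a receptor is present at all in both samples.
Per-pair RNG streams are derived deterministically from one base seed, so
a sharing matrix is reproducible and independent of pair evaluation
order.

## Similarity trees and concordance with tumour phylogenies

Jaccard matrices are turned into dendrograms by Ward-D2 agglomerative
clustering on the distance `D = 1 - J` (the similarity-to-distance map is
not canonical; `1 - J` is bounded, monotone and standard). Concordance
between two trees over the same samples is the Pearson correlation of
their cophenetic distances — merge heights for dendrograms, branch-length
path sums for edge-weighted phylogenies supplied as Newick (e.g. tumour
mutational trees, whose reconstruction is out of scope).

Significance uses a one-sided permutation test: the labels of the second
tree are shuffled (topology fixed; shuffling one tree is sufficient since
only the label pairing matters) and the add-one estimator
`p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)` keeps p valid and strictly
positive at finite permutation counts; `p` can never fall below
`1/(n_perm + 1)`. An exact mode enumerates all `n!` permutations for
small leaf sets, which also makes the p value exactly invariant under
consistent relabeling.

## Clone classes and the expansion threshold

Within a participant with at least two samples, clones are *stem* (seen
in all samples), *clade* (more than one but not all) or *private* (one
sample); stem and clade clones are immunosurveilling. Expansion is
defined on the clone-size scale of per-sample UMI percentage: a Gaussian
mixture (fitted by EM through mclust; model-based hierarchical
initialisation makes the fit deterministic, which we prefer over random
restarts) on pooled log10 percentages yields a cutoff at the
posterior-equality crossing between the top component and the rest. The
pipeline lets BIC choose up to four components, since the unexpanded bulk
is right-skewed and often absorbs a second component; the cutoff always
sits at the crossing between the top component and everything below, and
degeneracy is judged by the gap between the top two component means. The
cutoff is raised to the 90th percentile if more than 10% of clones would
otherwise be called expanded; that constraint is evaluated on one value
per clone (its maximum over samples), not on pooled clone-sample
observations, since a widely shared clone would otherwise be counted
many times. A clone above the cutoff in *any* sample is expanded. Crossed
with topology this gives classes A (private expanded), B (shared
expanded), C (private unexpanded), D (shared unexpanded).

## Diversity, SHM and isotype profiles

Diversity (Gini in mean-absolute-difference form, Shannon entropy in
nats, mean clone size) is computed on per-clone UMI counts under
UMI-weighted subsampling without replacement to a common depth, averaging
1,000 iterations by default; here the UMI is the draw unit because the
indices measure abundance structure. The "mean clone size" is reported as
mean UMIs per observed clone at fixed depth (equivalently depth over
observed richness; a share-normalised variant is available), since no
canonical definition exists. SHM categories use the fixed bounds 0-1 /
2-10 / 11-33 / >33 mutations, or a refitted 4-component mixture on
log(SHM + 1) whose adjacent posterior crossings become thresholds.
Sample-level SHM averages per-clone means first so large clones are not
overrepresented. Antigen-experienced BCRs are class-switched with more
than four mutations; inexperienced are IgD/IgM with at most four.

## Lineage graphs and degree centrality

The headline method asks which individual BCR variants within a clone
are immunosurveilling (observed in >= 2 sites) or temporally persistent
(>= 2 timepoints). For each clone observed in >= 2 samples with >= 10
unique sequences:

1. the aligned sequence stack is end-trimmed until both terminal columns
   have >= 95% non-gap occupancy, requiring >= 80 nt after trimming
   (shorter clones are skipped). Clone members whose length differs from
   the clone's modal length cannot enter a substitution-only distance
   model and are excluded from the graph (they remain in abundance
   statistics);
2. identical trimmed sequences are grouped into variants, aggregating
   per-sample abundance;
3. the pairwise Hamming matrix is computed (a residual gap counts as a
   mismatch against a base and a match against a gap);
4. a minimum spanning tree is built with Kruskal's algorithm using
   deterministic (weight, i, j) tie-breaking — integer Hamming weights
   tie constantly, and the tie order must not depend on row order or an
   implementation detail. When ties admit several minimum spanning
   trees, the rule fixes one reproducibly; for distances that are
   additive along a mutation genealogy the MST is unique, so degrees do
   not depend on labeling at all;
5. each variant's degree (incident MST edges) is its centrality; degree
   1 means no progeny variants.

A variant is predicted immunosurveilling when its degree exceeds a
cutoff; cutoffs 1, 2 and 10 are evaluated with sensitivity, specificity
and accuracy from the 2x2 confusion matrix. Sensitivity is non-increasing
and specificity non-decreasing in the cutoff by construction.

## CDR3 screening against reference antibodies

To check that apparent tumour immunosurveillance is not a systemic
anti-pathogen response, CDR3s are screened against a reference library of
antibodies with known viral/bacterial specificity, after removing
synthetic fusion proteins and animal-derived entries. Matching is
equal-length Hamming with up to three amino-acid mismatches; a
length-changing edit is never a match, consistent with the
substitution-only treatment elsewhere. The packaged database is a
synthetic stand-in that reproduces the published per-source composition
(5,800 retained entries; HIV-1 3,525, C. tetani 817, influenza A 486,
vaccinia 92, HCV 80, S. pneumoniae 59, S. aureus 38, HHV-5 32, remainder
"other"), because the original compilation is not redistributable here;
a user-supplied table in the same format drops in directly.

## The synthetic study and what it does (and does not) show

`simulate_repertoire()` generates the package's reference study: 4
participants, 8 sites (including a designated lymph-node origin) times 2
therapy timepoints, 200 clones per participant. Each clone grows a
genealogy from a random 350 nt germline with a 60 nt (20 aa) CDR3:

* chain-like growth in segments of at most 6 steps with branch
  probability 0.02 — lineages are sampled densely enough that most
  observed variants differ from a neighbour by few mutations (per-edge
  substitutions are 1 + Geometric with mean 1.25; CDR3-region hits
  change the amino acid with probability 0.75);
* each node is marked a *hub* with probability 0.05 at creation, so hub
  placement is agnostic to depth and hence to SHM;
* hubs model disseminated, locally expanding variants: they are observed
  in 3 sites (always including the lymph-node origin) and both
  timepoints, seed a burst of 3 + Poisson(5) local progeny (per-edge
  mean 2.5 mutations — the expanded subtree is sampled more sparsely),
  and attract chain restarts, so diversification concentrates at
  disseminated variants, the phenomenon the degree predictor exploits;
  a hub's non-hub children settle in one draw from the hub's sites and
  timepoints, so the hub subtree spans sites collectively while each
  non-hub variant remains local;
* clone sizes follow a two-component lognormal on the log10-percent
  scale (means -3 and -1, sd 0.3, 5% expanded); per sample, UMIs are
  allocated multinomially to the variants present, so realised clone
  proportions carry normalisation and sampling noise on top of the
  planted mixture;
* class-switch probability rises logistically with lineage depth;
  unswitched records are IgM/IgD.

Because per-edge mutation counts are at least 1, all variants are
distinct and pairwise Hamming distances are additive along the
genealogy, so the MST provably recovers the true tree except where
repeated hits on one position create shortcuts; such collisions are
counted and reported per run. Truth tables carry clone identity, parent
links, hub status, depth, true SHM and per-variant site/timepoint spans,
so clonotype recovery (adjusted Rand index), expansion-cutoff recovery,
classifier metrics and the degree/SHM independence check all have exact
planted references.

The generator emulates the statistical structure the analyses assume —
point-mutation lineages, heavy-tailed clone sizes, cross-site hubs,
depth-linked class switching. It does not emulate realistic V(D)J
recombination, indels, allele-level V calls, sequencing error, or
selection; passing recovery tests therefore demonstrates correctness of
the machinery under the stated model, not performance on real
repertoires.

## Numerical choices and degenerate inputs

* Problem sizes in tests and the acceptance run are scaled to the
  package's reference study (about 9,000 records, about 5,000 lineage
  variants); sharing uses hundreds of subsample iterations where the
  defaults would use 10,000.
* Medians of subsampled integer statistics use the lower median.
* A degenerate mixture fit (component means closer than 0.1 on the log10
  scale) falls back to a 90th-percentile cutoff with a warning; SHM
  refitting with fewer than 200 records falls back to the fixed bounds.
* Single-variant clones cannot carry a degree and are reported as
  degenerate skips; participants with one sample yield `unclassifiable`
  topology and are excluded from class analyses.
* Sequences containing `N` pass validation (the alphabet admits them)
  but `N` is compared literally in Hamming distances; the generator
  never emits them.
* `shared_overlap()` requires the subsample depth to be attainable in
  both samples and fails loudly otherwise.

## Known limitations

* The CDR3-identity stage never clusters unequal-length CDR3s, so clones
  related through indels fragment by design.
* The MST is computed on unique variants; duplicate-sequence multi-edges
  are collapsed before degree computation.
* Lineage graphs for clones whose members differ in length use only the
  modal-length members rather than a gapped multiple alignment.
* Cross-participant sharing is available but unnormalised for the
  chance-collision rate expected between unrelated repertoires.
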