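---
title: "Network reachability between a query trait and disease gene sets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network reachability between a query trait and disease gene sets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obnet)
```

## The problem

Given a catalogue of disease gene sets (GWAS/OMIM-style), a gene set for a
query trait such as obesity, and a reference protein-interaction network,
which diseases are connected to the query trait at the molecular level, and
through which biological processes? `obnet` answers this with three scores
of *mutual reachability* between two gene sets on a network, evaluated on
*functional modules* — the subnetworks induced by GO biological-process or
KEGG pathway gene sets:

* **OBNet** — network propagation (random walk with restart) plus a
  GSEA-style running-sum statistic, with permutation significance;
* **OBsp** — average shortest-path distance between the two gene sets;
* **OBoverlap** — the direct Jaccard overlap of the two gene sets.

## Modules

Each gene set with fewer than 500 genes is mapped onto the reference
network (`build_modules()`); its *core* is the mapped members and its
subnetwork the induced subgraph. A module can be *expanded*
(`expand_module()`): an RWR seeded on the core genes runs on the whole
reference network and the top-ranked non-core genes are added until the
module reaches five times its mapped size or 500 genes, whichever is
smaller. Expansion seeds on the whole network deliberately — its purpose is
to reach genes just outside the annotated set. A trait–disease pair is
scored on a module only when the module carries at least five genes from
each side (`eligible_for_scoring()`); with fewer mapped genes the
propagation statistic is unstable.

Decisions worth noting: the 5× growth factor counts the *mapped* core
genes, since unmapped annotation cannot participate; ties at the expansion
cutoff break lexicographically after probability so runs are bitwise
reproducible; the whole-network variant is represented as a single module
whose core is every node, never expanded.

## Random walk with restart

The adjacency matrix is column-normalized, `A'[i,j] = A[i,j] / sum_k
A[k,j]`, and the walk iterates

    P[t+1] = (1 - r) A' P[t] + r P0

from `P0` uniform over the seed genes, with restart probability `r = 0.5`
by default, until the L1 difference of successive iterates falls below
1e-6. Because the iteration map contracts at rate `1 - r`, convergence is
geometric; `max_iter = 10000` is a safety valve only. The fixed point is
the unique solution of `(I - (1-r)A')p = r P0`, which the test suite uses
as an independent linear-algebra oracle.

Numerical choices: the convergence metric is the L1 norm (only a
"difference" is prescribed by the method); isolated nodes have all-zero
columns that leak probability mass, so the converged vector is renormalized
to sum one — ranks are unchanged — and the leaked fraction logged; seeds
absent from the network are dropped with a warning, and it is an error only
if none remain; ties in the probability ranking break lexicographically.

## The OBNet statistic

For one module, direction 1 seeds the RWR on the disease genes and walks
the module's genes in decreasing probability order. Meeting a query-trait
(obesity) gene adds `(N - G)/G` to a running sum; any other gene subtracts
`G/(N - G)`, where `N` is the number of genes traversed and `G` the number
of trait genes among them. The peak (maximum) of the running sum is `ES1`.
Direction 2 swaps the roles of the two sets to give `ES2`, and the combined
score is the convex combination

    ES_beta = beta * ES1 + (1 - beta) * ES2,   0 < beta < 1,

with `beta = 0.1` by default, weighting the direction seeded on the query
trait more heavily.

Two properties of these increments deserve emphasis, because they differ
from classic GSEA. First, they are *not* zero-sum: traversing all `N` genes
always ends at `(N - G) - G`, so the peak carries a deterministic drift
component. The test suite pins this endpoint algebra so the implemented
increments are exactly these, not the classic
Kolmogorov–Smirnov form (`classic_increments = TRUE` switches to `1/G` /
`-1/(N-G)` for comparison). Second, "peak" is read as the maximum of the
running sum, not the maximum absolute excursion — consistent with the
one-sided, upper-tail interpretation of reachability.

Seed handling was genuinely open: the traversed list excludes the RWR seed
genes by default (`include_seeds = FALSE`), because seeds trivially rank
first and are not candidates to "meet"; this also avoids inflating the
score when the seed and target sets coincide. If the exclusion leaves no
target in the list (the degenerate identical-sets case), the traversal
falls back to including the seeds, and the permutation null is built with
the same geometry so observed and null statistics are treated
symmetrically.

### Significance

The trait genes in the module are re-drawn uniformly (without replacement)
from the module's gene universe `n_perm = 100` times; both directions are
recomputed per draw. The observed `ES_beta` is converted to a z-score
against the null mean and standard deviation and the p-value is the
upper-tail normal probability — high reachability is the only direction of
interest. When `include_seeds = FALSE`, disease seed genes are excluded
from the permutation universe, mirroring their exclusion from the observed
statistic. A degenerate null (`sd = 0`) yields p = 1 when the observed
score does not exceed the null mean and the smallest representable double
otherwise, with a log message.

**Known limitation — calibration of the normal conversion.** The running
sum's peak is a maximum statistic whose permutation null is mildly skewed,
so converting it to a normal tail probability from 100 permutations is an
approximation. Under a fully null fixture the emitted p-values are close to
but not exactly uniform (the fraction below 0.05 sits around 0.06–0.10
across regimes we simulated); a Kolmogorov–Smirnov test against the uniform
rejects at 500 replicates. An empirical rank-based p-value would be uniform
by construction, but the z-conversion is retained because it is the
method's specified form; downstream rankings depend only on the monotone
ordering and are unaffected.

### Ranking diseases

Per disease, module p-values are Benjamini–Hochberg adjusted (the scope —
within disease, the default, or across all disease–module pairs — is a
switch, since only the adjustment method is prescribed), and the disease
score is the minimum adjusted p across its modules. Diseases sort
ascending, ties breaking on the identifier.

## OBsp and OBoverlap

`obsp_module_distance()` averages unweighted (hop-count) shortest-path
lengths over all (disease gene, trait gene) pairs mapped to the module;
edge confidences are used only for the ingest threshold, matching common
practice for STRING-derived networks. Genes in both sets contribute
distance-0 pairs (a `drop_shared` switch removes them), and unreachable
pairs are excluded from the mean rather than assigned a penalty — an
infinity-contaminated mean would make every disconnected module worst —
with the finite-pair count retained for audit. The disease score is the
minimum mean distance across modules, ranked ascending. "All gene pairs"
is read as pairs of genes mapped to the module, the same universe the
eligibility rule uses. `oboverlap_rank()` is the Jaccard coefficient of
the raw gene sets, ranked descending.

The literature gold-set builder (`gold_set_from_counts()`) computes the
Jaccard coefficient of per-disease abstract-identifier counts against the
query trait's count and keeps diseases at or above 0.004, plus curated
additions; live literature retrieval is out of scope, so the counts are an
input table.

## Key connector analysis

`kca()` implements dynamic neighbourhood search on an undirected network:
restrict to the subnetwork of nodes within `L = 2` hops of the target set
`G`; for each gene `g` and each layer `h = 1..H` (`H = 2`), test the genes
within `h` hops of `g` (excluding `g`) for hypergeometric enrichment in
`G` with the subnetwork as background; take the minimum p across layers
and Bonferroni-correct across genes. Genes at corrected p ≤ 0.05 are key
connectors — hub-like mediators, not directed regulators. The focal gene is
excluded from the population and from the success set when it belongs to
`G` (self-membership is not a connection); the difference is O(1/|N_G|)
either way. The upper (enrichment) tail is used throughout.

## Evaluation

`roc_auc()` treats gold-list membership as the positive label and the
ranking score as the decision statistic (ascending scores such as p-values
are negated). Tied scores are grouped into one threshold, so a tied
positive–negative pair contributes 0.5 — the AUC equals the normalized
Mann–Whitney U statistic, which the tests verify directly and against an
independent ROC implementation. Gold diseases absent from a ranking are
appended at the worst observed score by default (dropping them is a
switch, and the choice moves the AUC, so it is explicit); an optional
`universe` argument appends *all* absent diseases, which matters when
eligibility filters rank only a subset. A blocklist can exclude
self-referential traits (e.g. body-mass measures) whose gold membership is
circular.

## Expression-based validation

`mdc()` computes module differential connectivity: connectivity of a gene
pair within a condition is the absolute Pearson correlation across that
condition's samples (optionally soft-thresholded `|r|^power`, the
WGCNA-adjacent convention; power 1 by default since no exponent is
prescribed), and MDC is the ratio of mean pairwise connectivity between
two conditions. Swapping the conditions inverts the ratio exactly.
Significance (`mdc_significance()`) shuffles the condition labels over
samples — the permutation unit was open; label shuffling is the natural
reading — and uses a two-sided empirical p with add-one correction,
BH-adjusted across modules.

`overlap_fisher()` tests every module pair across two collections with a
one-sided (enrichment) Fisher exact test on the shared-gene 2×2 table over
a gene universe (default: the union of both collections), BH over all
pairs. `overlap_permutation_study()` assesses whether the number of
significantly overlapping modules exceeds chance: genes are reassigned to
module labels uniformly at random preserving each module's size, a
selector re-picks the top `k` modules per permutation, the significant
overlaps are recounted, and the observed count is referred to the
permutation mean and standard deviation through an upper-tail normal
p-value (`normal_tail_p()`).

## The synthetic benchmark

`generate_benchmark()` emulates the full input bundle with planted signal.
The default network is a stochastic block model (3000 genes, 20 blocks,
within/between edge probabilities 0.15/0.005): blocks play the role of
biological processes, so sampled gene sets (30–60 genes, 90% from their own
block) induce internally dense modules, and the network is large relative
to the 5×/500 expansion rule — as a real interactome is — so expanded
modules stay local. Query-trait genes (25) are seeded in two shared
modules; each planted disease draws each of its genes, with probability
`proximity_effect`, from the 2-hop neighbourhood of the query genes inside
the shared blocks *but outside the core gene sets* — the zone expansion
grows into — and uniformly otherwise. Planted diseases are therefore
largely invisible to unexpanded modules and recovered by expanded ones,
which is precisely the behaviour the expansion step exists to produce; at
`proximity_effect = 0` planted and background diseases are exchangeable.
The truth record carries every assignment, so expected labels are exact.

What the generator does *not* emulate: scale-free degree structure, the
overlap structure of real GO terms, annotation bias, or biologically
meaningful symbols. Passing benchmarks here demonstrates that the
algorithms recover the signal they are defined to measure, not that any
particular biological conclusion transfers.

`generate_expression()` draws within-module expression from an
equicorrelated multivariate normal per condition (`sqrt(rho) f +
sqrt(1-rho) e`), giving exact pairwise correlation `rho`; background genes
are independent noise.

## Problem sizes used by the test suite

The heavier checks run at deliberately modest sizes chosen as this
package's own test conditions: 50 random graphs up to 200 nodes for the
RWR/linear-solve agreement; every ordering up to N = 10 for the
running-sum oracle; 500 replicates at 100 permutations for the null
calibration; 20 benchmark seeds (3000-gene networks) for planted-signal
recovery; 100 fixture draws for the planted-hub key-connector check; and
200 + 200 samples, 30 genes for the MDC recovery check. All randomness
flows from explicit integer seeds.

## Limitations

Beyond the calibration point above: the method carries no tissue
specificity; all genes are weighted equally within a set; the reachability
scores depend on the module catalogue's coverage; and the non-zero-sum
increments make the running-sum peak sensitive mainly to the ranks of the
worst-ranked target genes when `G` is small relative to `N`, which is
worth keeping in mind when interpreting scores on large expanded modules.
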