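---
title: "Network-based prioritization of GWAS results: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based prioritization of GWAS results: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprior)
```

This vignette is the package's own account of the method: the model and
its assumptions, the tunable parameters, what the synthetic generator
does and does not emulate, the numerical choices, and known limitations.

## The model

The premise is that complex-trait association signal is distributed over
functionally related genes, and that protein–protein interaction (PPI)
neighborhoods are a usable proxy for functional relatedness. The unit of
inference is therefore not a gene but a **two-step sub-network**: for a
seed protein $s$, the induced subgraph on all proteins within graph
distance 2 of $s$. One sub-network is seeded per protein; sub-networks
whose node sets are contained in (or equal to) another retained
sub-network's are excluded, and only networks with 20–200 proteins are
kept. The two-step radius is a compromise: one-step neighborhoods of a
typical interactome are too small to carry distributed signal (median of
a few proteins), three-step neighborhoods blur into most of the
component.

### Gene weights: modified PageRank with dynamic damping

Within a sub-network of $N$ proteins, each gene receives a weight from
the fixed point of

$$w(A) = \frac{1 - d_A}{2N} + d_A \sum_{H \in \mathcal{N}(A)} \frac{w(H)}{\deg(H)},
\qquad
d_A = \frac{\deg(A)}{\sum_{g \in \mathcal{N}(A)} \deg(g)},$$

with all degrees taken inside the sub-network. This is eigenvector-style
centrality in the PageRank family, with two departures from the classical
algorithm. First, the damping factor is not a global constant (classical
choices are $0.5 \le d \le 0.95$) but is computed per node as the ratio
of the node's degree to the summed degree of its neighbors: nodes whose
neighbors are themselves highly connected are damped more, which adapts
the weight propagation to the heterogeneous topology of biological
networks. A fixed-damping mode is deliberately not offered. Second, the
teleport denominator is $2N$ rather than $N$, which scales the total
weight of a network into $(0,1)$ and keeps every individual weight
strictly between 0 and 1. Undirected graphs have no dangling nodes, so no
node is excluded.

Useful exact properties (all verified in the test suite):

* on any $k$-regular sub-network, $d_A = 1/k$ and every weight equals
  $1/(2N)$;
* on the 4-node star, the center solves to $3/8$ and each leaf to $1/8$;
* weights are equivariant under node relabeling;
* the iteration matrix is similar to a row-substochastic non-negative
  matrix (row sums $d_A \le 1$), so power iteration converges for every
  sub-network the pipeline produces.

### Combining weights with association signal

Gene-level association p-values are standardized against the dataset:
$z_i = (\bar p - p_i)/s_p$, where $\bar p$ and $s_p$ are the mean and
sample (n−1) standard deviation of all p-values in the GWAS dataset. The
orientation — small p-values map to *large* z — is chosen so that an
upper-tail conversion applies at the network level; with the opposite
sign the ranking would simply invert. Note $z_i$ is a dataset-relative
standardization of a uniform-ish variable, not a probit transform: under
a global null it has mean 0 and variance 1 but is not Gaussian; only the
combined network score is treated as approximately normal (see
calibration below).

Each network's combined score is the Liptak–Stouffer statistic with
PageRank weights in place of the classical square-root sample sizes:

$$Z_{\mathrm{comb}} = \frac{\sum_i w_i z_i}{\sqrt{\sum_i w_i^2}},$$

invariant to rescaling the weights and reducing to the unweighted
Stouffer statistic $\sum z_i/\sqrt n$ for equal weights. $Z_\mathrm{comb}$
is converted to an upper-tail normal p-value and Bonferroni-corrected by
the network's scored gene count times the number of scored networks (a
deliberately conservative correction that ignores the heavy overlap
between sub-networks; the *ranking*, which drives all downstream use, is
unaffected by the correction's severity). Ranking is by ascending
corrected p-value with deterministic tie-breaks (descending
$Z_\mathrm{comb}$, then network id), and percentiles are
$100 \cdot \mathrm{rank} / \#\mathrm{networks}$.

A gene's **network percentile** is the percentile of the best-ranked
network containing it, contrasted with its **gene-wise percentile** from
its own p-value. The network percentile is the quantity that stabilizes
across cohorts.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `size_min`, `size_max` | 20, 200 | proteins | sub-network size band; below 20 networks carry little distributed signal, above 200 the Bonferroni factor and "small-world" recurrence dominate |
| `flank` | 50000 | bases | positional SNP→gene window of the fallback assignment; captures nearby regulatory variation |
| `alpha_gene` | 0.05 | — | gene-wise cutoff used only to partition member genes in the summary output |
| `top_fraction` | 0.02 | — | share of the ranking treated as "top" in null-frequency and cross-dataset comparisons |
| `tol`, `max_iter` | 1e-10, 1000 | — | power-iteration stopping rule |
| `n_gwas_permutations` | 10000 | runs | GWAS-label null (tests and examples use far fewer) |
| `n_network_randomizations` | 100 | runs | node-label null |

## Null procedures

Two permutation nulls diagnose recurrent, trait-independent networks:

* **GWAS permutation** shuffles the gene→p-value assignment. Networks and
  weights are unchanged, so the package freezes membership and weights
  once and only re-scores — thousands of permutations cost seconds.
* **Network randomization** applies a random bijection to the node labels
  of the *global* interactome, then rebuilds, filters and re-weights
  sub-networks from scratch each run. The permutation is global rather
  than per-sub-network because relabeling must happen before any
  topology-dependent quantity (two-step membership, hubs) is interpreted;
  degree multisets, node and edge counts are preserved by construction.

A network's null frequency is the share of runs in which it lands in the
top `top_fraction` of the ranking; frequencies above 0.5 are flagged
`recurrent` (interpret with caution — the network rises for topological
reasons), below 0.05 `trait_specific`.

## The synthetic generator

`synthetic_spec()` defines a study condition: an interactome model, a
planted trait module, and a signal strength. Defaults are chosen once to
emulate the regime the method targets: a 2000-gene preferential-attachment
graph with `m = 2` edges per node, whose two-step sub-networks have
median size in the tens with a heavy tail — so the 20–200 band retains on
the order of half the networks, mirroring a real interactome's
proportions; a 30-gene planted module; and Beta($a$, 1) planted p-values,
which give the exact null at $a = 1$ and stochastically small p-values
for $a < 1$ with a single interpretable parameter. The module is grown
from a mid-degree center (40th–80th degree percentile, preferring centers
whose two-step neighborhood can hold the whole module), closest shells
first, highest degree first within a shell — so the module aligns with a
buildable sub-network rather than an arbitrary gene set. All draws are
reproducible from one integer seed via deterministically spawned child
seeds; replicate "cohorts" redraw every p-value while keeping the
interactome and module fixed.

What the generator does **not** emulate: linkage disequilibrium and
SNP-level structure (signal is injected directly at the gene level),
ascertainment bias of interactome databases (preferential attachment is a
geometric stand-in, not a literature-bias model), correlated p-values
between neighboring genes, and measurement error in interactions.
Passing tests on synthetic data therefore demonstrate the pipeline's
statistical calibration and recovery behavior under known truth, not
performance on any particular cohort.

## Numerical choices

* **Iteration scheme**: synchronous Jacobi-style updates from the uniform
  start $w^{(0)} = 1/(2N)$; stop when the max-norm change drops below
  `tol = 1e-10` or after 1000 iterations (systems are at most 200×200 and
  strictly contractive in practice; non-convergence returns the current
  iterate with `converged = FALSE` and a warning rather than an error).
* **Isolated nodes** (only possible in degenerate single-node networks):
  damping 0, weight $1/(2N)$ — the bare teleport term.
* **No post-iteration renormalization**: the $2N$ scaling is taken as
  part of the model and weights feed the scorer as-is.
* **Subset removal** sorts node sets by decreasing size and retains a
  network unless it is contained in an already-retained one; equal sets
  collapse to the lexicographically smallest seed. Containment is checked
  only against retained networks indexed by a shared member node, which
  keeps the step near-linear in practice.
* **Degenerate inputs**: a p-value dataset with zero standard deviation
  is an error (standardization undefined); networks sharing no gene with
  the dataset are left unscored and flagged rather than imputed;
  duplicate genes in a p-value table are an error because no merge rule
  is defensible without knowing the upstream tool.
* **Hypergeometric tail convention**: `hypergeom_overlap()` defaults to
  the inclusive upper tail $P(X \ge k)$, the standard enrichment
  p-value. Published overlap p-values are sometimes computed as the
  strict tail $P(X > k)$ (the observed count passed directly to an
  exclusive-tail routine); `inclusive = FALSE` reproduces that
  convention. For the worked 6035/34/1232/16 example the two differ by
  a factor of ~4 (4.28e-4 vs 1.11e-4) — worth checking when comparing
  against published numbers.

## Problem sizes used in validation

The test suite and the acceptance script validate at sizes chosen to
exercise every pipeline stage while completing quickly: property checks
on graphs of 3–50 nodes against brute-force oracles (depth-2 BFS, dense
linear solves, $O(n^2)$ subset scans, exhaustive hypergeometric
enumeration); calibration on a 2000-gene synthetic interactome with 200
GWAS permutations (the across-network mean top-2% hit frequency is
deterministically $\lfloor 0.02 n\rfloor/n$; the fraction of uncorrected
network p-values below 0.05 lands near 0.05, slightly conservative
because standardized uniform z-scores are platykurtic and the combined
score only asymptotically normal); and planted-module recovery at
Beta(0.05, 1) over 20 replicate cohorts, where the planted-seed network's
percentile stays in the top 2% essentially always and the
across-replicate variance of planted genes' network percentiles is
orders of magnitude below the variance of their gene-wise percentiles —
the stabilization the method exists to provide.

## Known limitations

* Results inherit the interactome's ascertainment: well-studied genes
  have more recorded interactions, and their neighborhoods are easier to
  prioritize. The node-label null flags the worst of this but cannot
  remove it.
* The Bonferroni correction over overlapping networks is conservative;
  corrected p-values near 1 are common and the percentile ranking is the
  operative output.
* The positional SNP→gene fallback (Šidák min-p over assigned SNPs)
  ignores linkage disequilibrium and gene length bias; results from an
  LD-aware gene-based association tool should be preferred whenever
  available.
* Gene symbols are matched verbatim (upper-cased); no alias resolution is
  attempted, so identifier mismatches between the interactome and the
  GWAS table silently shrink the scored gene set (the scorer logs the
  dropped count).
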