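---
title: "Local alignment of multilayer networks: model, parameters and design choices"
author: "mlnalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local alignment of multilayer networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlnalign)
```

## The problem

A multilayer (multiplex) network is a tuple of graph layers over per-layer
node sets, joined by inter-layer edges. They arise wherever one system
carries several interaction types at once: gene and disease layers joined by
gene–disease associations, protein interaction layers from different
evidence channels, multi-relation social networks. *Local* network alignment
asks for small matched regions of similarity between two such networks — as
opposed to global alignment, which seeks one overall node mapping. Local
aligners designed for simple graphs cannot use the inter-layer structure;
this package implements a local aligner that does.

The method has two stages:

1. **Alignment-graph construction.** Seed similarities (e.g. orthology
   scores) propose cross-network node pairs per layer. A greedy
   best-similarity one-to-one matching turns them into *pair nodes*. Edges
   between pair nodes encode joint adjacency of their members in the two
   inputs, separately within layers and across layers (details below).
2. **Community mining.** A weighted community-detection algorithm partitions
   the alignment graph; each community of at least `minSize` pair nodes is
   one local region of similarity, and their union is the reported partial
   node mapping.

## Edge classification and scoring

Within a layer, for two pair nodes $(u_1,v_1)$ and $(u_2,v_2)$, let $d_1$ be
the hop distance between $u_1,u_2$ in network 1's layer graph and $d_2$
between $v_1,v_2$ in network 2's. With gap threshold $\Delta$:

| condition | kind | default weight |
|---|---|---|
| $d_1 = d_2 = 1$ | homogeneous match | 1.0 |
| exactly one of $d_1,d_2$ is 1, other $\in [2,\Delta]$ | homogeneous gap | 0.2 |
| exactly one is 1, other $> \Delta$ or $\infty$ | homogeneous mismatch | 0.5 |
| otherwise | no edge | — |

Across layers, for pair nodes in layers $k \ne h$, the corresponding
inter-layer edge is looked up in each input: present in both gives a
heterogeneous match (0.9), present in exactly one a heterogeneous mismatch
(0.4), absent in both no edge.

Two readings of the gap rule are possible, because with the default
$\Delta = 2$ a literal "distance less than $\Delta$" would mean "adjacent",
which is already the match case. We use the reading under which $\Delta$
actually discriminates gaps from mismatches: gap means distance in
$[2, \Delta]$ in the non-adjacent network. The mismatch weight (0.5)
deliberately exceeds the gap weight (0.2); this is counter-intuitive (a
mismatch is worse evidence than a gap) but is the reference
parameterisation, and all five weights plus $\Delta$ are exposed in
`ScoringConfig()` for users who prefer a monotone scheme.

All classification is purely topological: input edge weights, if present in
a file, are ignored with a warning. Distances are computed per layer with
breadth-first search over the layer's intra-edge graph only (igraph), so a
path through another layer never shortens an intra-layer distance.

## Mining and the flattening argument

Pair nodes are distinct per layer, so the multilayer alignment graph *is* a
simple weighted undirected graph over (layer, pair) vertices; multilayer
community detection on it reduces exactly to weighted community detection on
the flattened graph. The default backend is Infomap in two-level,
undirected, weighted mode (`igraph::cluster_infomap`, 10 trials); `louvain`
(weighted modularity) is registered as an alternative. The miner is
pluggable by design — `genlouvain`, `abacus`, `clique_percolation` and
`mdlp` are reserved registry names that error as not implemented rather than
silently falling back. Backends are seeded explicitly, so a fixed
`(method, seed)` gives byte-identical community files.

Singleton communities are excluded from the reported mapping by default
(`minSize = 2`): a local region of similarity consisting of one node pair is
vacuous. This is why node coverage can fall slightly below 1 even at zero
noise. Passing `minSize = 1` keeps every mined pair.

## Quality measures

Against a known true mapping $M$ (set of node pairs), with $N$ the aligned
pairs of a layer:

* $P\text{-}NC = |M \cap N| / |M|$, $R\text{-}NC = |M \cap N| / |N|$, and
  F-NC combines them. The combination rule is the harmonic mean (the usual
  F-score); an arithmetic option is exposed since only "a combination" is
  prescribed. The multilayer F-NC is the arithmetic mean over layers.
* NCV-GS3: node coverage $NCV = (|V(G_1')| + |V(G_2')|)/(|V_1| + |V_2|)$
  over the subgraphs induced by the aligned nodes, and
  $GS3 = c / (|E(G_1')| + |E(G_2')| - c)$ with $c$ the conserved-edge count.
  We combine them as the geometric mean, the convention of the
  network-alignment literature this measure comes from; arithmetic is
  exposed as an option. When both induced edge sets are empty, GS3 is
  defined as 1 (nothing to conserve, nothing violated); when exactly one is
  empty the formula itself yields 0.
* Inter-layer edges are pooled: one NCV-GS3 over all inter-layer edges, with
  NCV over the union of all layers' node sets (each node counted once).
  The experiment driver also reports an inter-layer F-NC — node correctness
  restricted to pairs whose member node touches an inter-layer edge — since
  no standard definition exists for it; this restriction is this package's
  choice.

NCV denominators always use the full original node sets: degradation removes
edges only, never nodes.

## The synthetic benchmark and what it does (not) show

`generateMultilayer()` draws each layer as an Erdős–Rényi $G(n, m)$ graph
and each layer pair as a uniform sample of cross-layer node pairs. The
benchmark suite is ten two-layer, 30-node networks with total edge counts
90, 96, 84, 78, 95, 88, 93, 83, 94, 96. The catalogue fixes only layers,
nodes and totals; the remaining geometry is set here once: 15 nodes per
layer, and an inter-layer fraction of 0.2 (so e.g. N1 has 72 intra- and 18
inter-layer edges). The fraction is an explicit, sweepable parameter because
the inter-layer measures are undefined without inter-layer edges; 0.2 gives
mean intra-layer degree ≈ 5 and a visible inter-layer signal without
dominating the layers.

Noise degrades a network by removing $\lfloor p \cdot |E| \rfloor$ edges
drawn uniformly from the union of intra- and inter-layer edges (one global
pool — the simplest reading of "randomly removing edges"), at
$p \in \{0.05, \dots, 0.25\}$. The proof-of-concept experiment
(`runExperiment()`) aligns each benchmark network against itself ($p = 0$)
and against each degraded copy with identity seeds — 60 runs — and scores
every run against the identity truth.

The generator emulates size, density and layer structure, not realism:
real biological layers have heavy-tailed degree distributions, clustering,
and noisy, incomplete seed lists (orthology is neither one-to-one nor
always correct). Passing the benchmark shows the machinery recovers planted
structure under edge deletion; it does not certify performance on real
networks, where seed quality typically dominates.

## Numerical and design choices

* **Determinism.** Every stochastic step (generation, degradation, mining)
  takes an explicit seed; suite-level streams are derived from one master
  seed by a stable string hash (`stableSeed()`), so whole experiments are
  bit-reproducible and runs are independent across networks and noise
  levels.
* **Tie-breaks.** Greedy pair selection orders seeds by similarity
  descending, then lexicographically by `(id1, id2)`; community ids are
  renumbered in first-appearance order; all writers sort their lines.
  Output files are therefore byte-stable.
* **Degenerate inputs.** Empty networks, empty layers and empty seed maps
  flow through every stage (empty alignment graph, empty community set,
  empty mapping); F-NC is an error only when the *true* mapping is empty,
  where the measure is genuinely undefined. Layers present in only one
  input are skipped with a warning; fully disjoint layer vocabularies are a
  usage error.
* **Node identity.** Nodes are namespaced per layer; no replica relation
  across layers is assumed, and layer correspondence between the two inputs
  is by layer-identifier equality — explicit names are the least surprising
  rule, and relabelling is the caller's responsibility.
* **Edge-list dialect.** The TSV dialect carries 2-column node-declaration
  lines in addition to 4-column edge lines so that isolated nodes (which
  degradation creates and NCV needs) survive a write/read round trip.
* **Problem sizes.** Default experiments use the ten 30-node benchmark
  networks (60 runs, seconds on a laptop); the test suite's statistical
  checks average 20 master seeds, chosen to make the monotone noise response
  visible above run-to-run variance at this network size.

## Known limitations

* Inter-layer classification has no gap case: a distance-2 inter-layer
  relation (through a third node) is not scored. Whether one should exist is
  an open modelling question.
* P-NC and R-NC orientation follows the reference formulas literally
  (`|M∩N|/|M|` and `|M∩N|/|N|`); note this is transposed relative to the
  common precision/recall convention when reading the numbers.
* Only Infomap and Louvain backends are implemented; the other four reserved
  miners would need their own multilayer treatments.
* With identity seeds the mined mapping is always a subset of the truth, so
  R-NC is 1 by construction in the self-alignment benchmark; discriminating
  recall requires noisy or incomplete seed lists, which the benchmark does
  not model.

## A worked run

```{r example}
net <- generateMultilayer(30, 2, 90, interFraction = 0.2, seed = 1, name = "N1")
noisy <- degradeNetwork(net, 0.25, seed = 2)
res <- runAlignment(net, noisy, identitySeeds(net), seed = 42)
res$graph
rep <- evaluateAlignment(net, noisy, identityTrueMapping(net), res$mapping)
rep
```
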