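# mlnalign: local alignment of multilayer networks

Multilayer (multiplex) networks — gene/disease layers joined by association
edges, multi-evidence protein interaction networks, multi-relation social
networks — need alignment methods that use their inter-layer structure.
`mlnalign` finds **local** alignments between two multilayer networks: small
matched regions of similarity, rather than one global node mapping.

The method merges the two inputs into a weighted **multilayer alignment
graph**. Seed similarities (e.g. orthology scores) select one-to-one matched
node pairs per layer; each pair becomes a vertex, and edges encode joint
adjacency of the pair members in the two inputs. Within a layer, with `d1`,
`d2` the member hop distances in the two networks and gap threshold `Δ`
(default 2):

* `d1 = d2 = 1` → homogeneous **match** (weight 1.0);
* adjacent in exactly one network, distance in `[2, Δ]` in the other →
  homogeneous **gap** (0.2);
* adjacent in exactly one, distance `> Δ` or disconnected in the other →
  homogeneous **mismatch** (0.5).

Across layers, the corresponding inter-layer edge present in both networks
gives a heterogeneous match (0.9); in exactly one, a heterogeneous mismatch
(0.4). Communities mined on this graph (Infomap by default, Louvain as an
alternative) are the local alignments. Quality is scored against a known
true mapping with multilayer extensions of F-score node correctness
(`F-NC`, from `P-NC = |M∩N|/|M|` and `R-NC = |M∩N|/|N|`) and of
`NCV-GS3 = sqrt(NCV · GS3)`, the combined node-coverage/edge-conservation
measure, including a pooled inter-layer variant.

The package also ships the synthetic benchmark used to validate the method:
ten two-layer, 30-node networks degraded by removing 5–25% of edges at
random, aligned against their originals with identity seeds.

## Worked example

```r
library(mlnalign)

net   <- generateMultilayer(30, 2, 90, interFraction = 0.2, seed = 1, name = "N1")
noisy <- degradeNetwork(net, 0.25, seed = 2)       # removes floor(0.25*90) = 22 edges
res   <- runAlignment(net, noisy, identitySeeds(net), seed = 42)
res$graph
#> MultilayerAlignmentGraph: 30 pair node(s) in 2 layer(s), 90 edge(s)
#>   HOM_MATCH=57 HOM_MISMATCH=1 HOM_GAP=14 HET_MATCH=11 HET_MISMATCH=7

evaluateAlignment(net, noisy, identityTrueMapping(net), res$mapping)
#> EvaluationReport
#>  layer p_nc r_nc f_nc ncv    gs3 ncv_gs3
#>     L1    1    1    1   1 0.8333  0.9129
#>     L2    1    1    1   1 0.7500  0.8660
#>   multilayer F-NC     1.0000
#>   multilayer NCV-GS3  0.8894
#>   interlayer NCV-GS3  0.7817
#>   interlayer F-NC     1.0000
```

Reading the output: all 30 nodes stay paired (the 90 alignment-graph edges
mirror the original network's 72 intra + 18 inter edges, with the 22 removed
edges reclassified from matches to gaps/mismatches), so node correctness is
perfect; edge conservation drops to `GS3 ≈ 0.75–0.83` per layer, giving a
multilayer NCV-GS3 of 0.89 at this harshest noise level.

The full experiment — 10 benchmark networks × noise
{0, 5, 10, 15, 20, 25}% — is one call:

```r
res <- runExperiment(masterSeed = 1)   # 60 runs, a few seconds
mean(res$multilayer_ncv_gs3)
#> [1] 0.9350866
experimentSummary(res)                 # per-network mean/sd across noise levels
```

See `vignettes/multilayer-local-alignment.Rmd` for the model, parameter
semantics and design choices.

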