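# Alignment-graph construction: pair-node selection, intra-layer
# classification against a brute-force BFS oracle, inter-layer edges.

test_that("pair nodes follow greedy best-similarity matching with lexicographic ties", {
  ids <- c("a", "b", "x", "y")
  net <- MultilayerNetwork(name = "m", layers = "L1", nodes = list(L1 = ids))
  seeds <- SeedMap(data.frame(
    layer = "L1", id1 = c("a", "a", "b"), id2 = c("x", "y", "y"),
    similarity = c(0.9, 0.8, 0.7)))
  pn <- selectPairNodes(seeds, net, net)
  expect_identical(pn$u, c("a", "b"))
  expect_identical(pn$v, c("x", "y"))

  # equal similarities competing for one node: smaller (id1, id2) wins
  tie <- SeedMap(data.frame(layer = "L1", id1 = c("b", "a"), id2 = c("x", "x"),
                            similarity = c(0.5, 0.5)))
  pn2 <- selectPairNodes(tie, net, net)
  expect_identical(nrow(pn2), 1L)
  expect_identical(pn2$u, "a")

  # identity seeds pair every node with itself
  net2 <- generateMultilayer(10, 2, 14, seed = 1)
  pn3 <- selectPairNodes(identitySeeds(net2), net2, net2)
  expect_identical(nrow(pn3), 10L)
  expect_true(all(pn3$u == pn3$v))

  # invalid references are rejected at use time
  badSeeds <- SeedMap(data.frame(layer = "L1", id1 = "a", id2 = "nope",
                                 similarity = 1))
  expect_error(selectPairNodes(badSeeds, net, net), "not in network 2")
})

test_that("intra-layer classification matches the literal rule table on all distance combinations", {
  for (delta in c(2L, 3L)) {
    for (d1 in c(1:5, Inf)) {
      for (d2 in c(1:5, Inf)) {
        expect_identical(classifyIntra(d1, d2, delta),
                         ruleTableOracle(d1, d2, delta),
                         info = sprintf("d1=%s d2=%s delta=%d", d1, d2, delta))
      }
    }
  }
  expect_error(classifyIntra(1, 1, delta = 1), "delta")
})

test_that("the three-node worked instance classifies as match / mismatch / none", {
  # net1: path a-b-c; net2: only edge a-b; identity pairs on {a,b,c}
  mk <- function(edges) MultilayerNetwork(
    name = "t", layers = "L1", nodes = list(L1 = c("a", "b", "c")),
    intraEdges = list(L1 = edges))
  net1 <- mk(data.frame(from = c("a", "b"), to = c("b", "c")))
  net2 <- mk(data.frame(from = "a", to = "b"))
  g <- buildMultilayerAlignmentGraph(net1, net2, identitySeeds(net1))
  ed <- g@edges
  key <- paste(ed$u1, ed$u2)
  expect_identical(nrow(ed), 2L)
  expect_identical(ed$kind[key == "a b"], "HOM_MATCH")
  # b,c adjacent in net1 but disconnected in net2: mismatch, not gap
  expect_identical(ed$kind[key == "b c"], "HOM_MISMATCH")
  # a,c: d1 = 2, d2 = Inf: no edge
  expect_false("a c" %in% key)
})

test_that("layer alignment edges equal the brute-force BFS oracle on random instances", {
  set.seed(1301)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    inst <- randomLayerInstance(n)
    g <- buildMultilayerAlignmentGraph(inst$net1, inst$net2,
                                       identitySeeds(inst$net1))
    got <- g@edges[order(g@edges$u1, g@edges$u2), c("u1", "u2", "kind")]
    oracle <- layerKindsOracle(inst$net1, inst$net2, "L1", delta = 2L)
    oracle <- oracle[order(oracle$a, oracle$b), ]
    expect_identical(unname(as.matrix(got)),
                     unname(as.matrix(oracle[, c("a", "b", "kind")])))
  }
})

test_that("self-alignment yields a pure-match graph isomorphic to the input", {
  net <- generateMultilayer(30, 2, 90, seed = 17)
  g <- buildMultilayerAlignmentGraph(net, net, identitySeeds(net))
  expect_identical(nrow(g@pairNodes), 30L)
  expect_identical(nrow(g@edges), 90L)  # |E_intra| + |E_inter|
  expect_true(all(g@edges$kind %in% c("HOM_MATCH", "HET_MATCH")))
  expect_identical(sum(g@edges$kind == "HOM_MATCH"), numEdges(net, "intra"))
  expect_identical(sum(g@edges$kind == "HET_MATCH"), numEdges(net, "inter"))
  # every original intra edge appears as a match between its identity pairs
  e <- intraEdges(net, "L1")
  hom <- g@edges[g@edges$kind == "HOM_MATCH" & g@edges$layer1 == "L1", ]
  expect_setequal(paste(hom$u1, hom$u2), paste(e$from, e$to))
})

test_that("inter-layer edges classify as het-match / het-mismatch / none", {
  mk <- function(inter) MultilayerNetwork(
    name = "t", layers = c("G", "D"),
    nodes = list(G = c("G1", "G5"), D = c("D2", "D4")),
    intraEdges = list(),
    interEdges = inter)
  net1 <- mk(data.frame(layer1 = c("G", "G"), id1 = c("G1", "G5"),
                        layer2 = c("D", "D"), id2 = c("D4", "D2")))
  net2 <- mk(data.frame(layer1 = "G", id1 = "G1", layer2 = "D", id2 = "D4"))
  g <- buildMultilayerAlignmentGraph(net1, net2, identitySeeds(net1))
  ed <- g@edges
  pairKey <- apply(cbind(ed$u1, ed$u2), 1,
                   function(x) paste(sort(x), collapse = "+"))
  # (G1,D4) in both inputs: heterogeneous match at weight 0.9
  m <- ed[pairKey == "D4+G1", ]
  expect_identical(m$kind, "HET_MATCH")
  expect_equal(m$weight, 0.9)
  # (G5,D2) only in net1: heterogeneous mismatch at weight 0.4
  mm <- ed[pairKey == "D2+G5", ]
  expect_identical(mm$kind, "HET_MISMATCH")
  expect_equal(mm$weight, 0.4)
  # (G1,D2), (G5,D4) in neither: no edge
  expect_identical(nrow(ed), 2L)
})

test_that("alignment of a network with a degraded copy counts surviving edges as matches", {
  net <- generateMultilayer(30, 2, 90, seed = 21)
  noisy <- degradeNetwork(net, 0.25, seed = 22)
  g <- buildMultilayerAlignmentGraph(net, noisy, identitySeeds(net))
  expect_identical(sum(g@edges$kind == "HOM_MATCH"), numEdges(noisy, "intra"))
  expect_identical(sum(g@edges$kind == "HET_MATCH"), numEdges(noisy, "inter"))
  # monotone degradation: harsher noise never adds matches
  noisier <- degradeNetwork(net, 0.5, seed = 22)
  g2 <- buildMultilayerAlignmentGraph(net, noisier, identitySeeds(net))
  expect_lte(sum(g2@edges$kind %in% c("HOM_MATCH", "HET_MATCH")),
             sum(g@edges$kind %in% c("HOM_MATCH", "HET_MATCH")))
  # weight discipline
  cfg <- ScoringConfig()
  expect_true(all(g@edges$weight %in%
                    c(cfg@wMatch, cfg@wMismatch, cfg@wGap,
                      cfg@wHetMatch, cfg@wHetMismatch)))
})

test_that("layer handling: shared layers required, extra layers skipped with warning", {
  n1 <- MultilayerNetwork(name = "a", layers = c("L1", "L2"),
                          nodes = list(L1 = "a", L2 = "b"))
  n2 <- MultilayerNetwork(name = "b", layers = "L1", nodes = list(L1 = "a"))
  seeds <- SeedMap(data.frame(layer = "L1", id1 = "a", id2 = "a",
                              similarity = 1))
  expect_warning(g <- buildMultilayerAlignmentGraph(n1, n2, seeds), "skipping")
  expect_identical(g@layers, "L1")

  n3 <- MultilayerNetwork(name = "c", layers = "LX", nodes = list(LX = "a"))
  expect_error(buildMultilayerAlignmentGraph(n1, n3, seeds), "no common|no layer")
})
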