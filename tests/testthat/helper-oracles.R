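# Independent oracles used to cross-check the implementation. These are kept
# deliberately naive: hand-written BFS over adjacency lists, a literal
# transcription of the match/mismatch/gap rule table, and exhaustive
# enumeration for modularity, so that they share no code with the package's
# igraph-based paths.

# hop distances from `src` to all nodes, by plain BFS over an adjacency list
bfsDistOracle <- function(nodes, edges, src) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  if (NROW(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$from[i]; b <- edges$to[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[src] <- 0
  queue <- src
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (is.infinite(dist[nb])) {
        dist[nb] <- dist[cur] + 1
        queue <- c(queue, nb)
      }
    }
  }
  dist
}

# literal rule table for intra-layer classification
ruleTableOracle <- function(d1, d2, delta) {
  if (d1 == 1 && d2 == 1) return("HOM_MATCH")
  one <- (d1 == 1) + (d2 == 1)
  if (one == 1) {
    other <- max(d1, d2)
    if (other >= 2 && other <= delta) return("HOM_GAP")
    return("HOM_MISMATCH")
  }
  NA_character_
}

# random single-layer two-network instance over a shared node set
randomLayerInstance <- function(nNodes, pEdge1 = 0.25, pEdge2 = 0.25) {
  ids <- sprintf("x%02d", seq_len(nNodes))
  pairs <- t(combn(ids, 2))
  draw <- function(p) {
    keep <- runif(nrow(pairs)) < p
    data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
               stringsAsFactors = FALSE)
  }
  mk <- function(e) MultilayerNetwork(
    name = "rand", layers = "L1", nodes = list(L1 = ids),
    intraEdges = list(L1 = e))
  list(net1 = mk(draw(pEdge1)), net2 = mk(draw(pEdge2)), ids = ids)
}

# brute-force alignment-edge kinds for one layer under identity pairing,
# using only the BFS oracle and the literal rule table
layerKindsOracle <- function(net1, net2, layer, delta) {
  ids <- intersect(nodeIds(net1, layer), nodeIds(net2, layer))
  e1 <- intraEdges(net1, layer); e2 <- intraEdges(net2, layer)
  out <- list()
  for (i in seq_len(length(ids) - 1)) {
    d1 <- bfsDistOracle(nodeIds(net1, layer), e1, ids[i])
    d2 <- bfsDistOracle(nodeIds(net2, layer), e2, ids[i])
    for (j in seq(i + 1, length(ids))) {
      kind <- ruleTableOracle(d1[ids[j]], d2[ids[j]], delta)
      if (!is.na(kind))
        out[[length(out) + 1L]] <- data.frame(
          a = ids[i], b = ids[j], kind = kind, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(a = character(0), b = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# exhaustive best 2-partition by weighted modularity (for tiny graphs)
bestTwoPartitionModularity <- function(vertices, edges) {
  # edges: data.frame(from, to, weight)
  m2 <- 2 * sum(edges$weight)
  strength <- setNames(rep(0, length(vertices)), vertices)
  for (i in seq_len(nrow(edges))) {
    strength[edges$from[i]] <- strength[edges$from[i]] + edges$weight[i]
    strength[edges$to[i]] <- strength[edges$to[i]] + edges$weight[i]
  }
  modOf <- function(side) {  # side: logical per vertex
    q <- 0
    for (grp in c(TRUE, FALSE)) {
      members <- vertices[side == grp]
      inw <- sum(edges$weight[edges$from %in% members & edges$to %in% members])
      q <- q + inw / (m2 / 2) - (sum(strength[members]) / m2)^2
    }
    q
  }
  best <- NULL; bestQ <- -Inf
  n <- length(vertices)
  for (mask in seq_len(2^(n - 1)) - 1L) {  # fix vertex 1 in group TRUE
    side <- c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0))
    q <- modOf(side)
    if (q > bestQ) { bestQ <- q; best <- side }
  }
  list(side = setNames(best, vertices), modularity = bestQ)
}

# small deterministic toy network shared by several tests:
# L1: path a-b-c plus d isolated; L2: edge a-b; one inter edge L1:a - L2:b
toyNet <- function() {
  MultilayerNetwork(
    name = "toy", layers = c("L1", "L2"),
    nodes = list(L1 = c("a", "b", "c", "d"), L2 = c("a", "b")),
    intraEdges = list(
      L1 = data.frame(from = c("a", "b"), to = c("b", "c")),
      L2 = data.frame(from = "a", to = "b")),
    interEdges = data.frame(layer1 = "L1", id1 = "a", layer2 = "L2", id2 = "b"))
}
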