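## Construction of the multilayer alignment graph: pair-node selection,
## intra-layer edge classification (match / mismatch / gap) and inter-layer
## edge classification (heterogeneous match / mismatch).

#' Select pair nodes by greedy best-similarity matching
#'
#' Implements the seed-guided pairing rule: within each layer, each node is
#' matched with the most similar node of the other network. Seed entries are
#' sorted by similarity (descending) with lexicographic `(id1, id2)`
#' tie-break, and accepted greedily iff neither endpoint is already paired in
#' that layer, producing a deterministic one-to-one partial matching.
#'
#' @param seeds A [SeedMap-class] validated against the two networks.
#' @param net1,net2 The two input [MultilayerNetwork-class] objects.
#' @return `data.frame(layer, u, v, similarity)`, one row per pair node.
#' @export
selectPairNodes <- function(seeds, net1, net2) {
  stopifnot(is(seeds, "SeedMap"))
  e <- seeds@entries
  if (nrow(e) == 0) return(cbind(.df0("layer", "u", "v"),
                                 data.frame(similarity = numeric(0))))
  for (i in seq_len(nrow(e))) {
    ly <- e$layer[i]
    if (!ly %in% layerNames(net1) || !ly %in% layerNames(net2))
      stop(sprintf("seed entry %d: layer '%s' not present in both networks", i, ly))
    if (!e$id1[i] %in% nodeIds(net1, ly))
      stop(sprintf("seed entry %d: node '%s' not in network 1 layer '%s'",
                   i, e$id1[i], ly))
    if (!e$id2[i] %in% nodeIds(net2, ly))
      stop(sprintf("seed entry %d: node '%s' not in network 2 layer '%s'",
                   i, e$id2[i], ly))
  }
  e <- e[order(e$layer, -e$similarity, e$id1, e$id2), , drop = FALSE]
  rows <- list()
  for (ly in unique(e$layer)) {
    sub <- e[e$layer == ly, , drop = FALSE]
    usedU <- character(); usedV <- character()
    for (i in seq_len(nrow(sub))) {
      if (sub$id1[i] %in% usedU || sub$id2[i] %in% usedV) next
      usedU <- c(usedU, sub$id1[i]); usedV <- c(usedV, sub$id2[i])
      rows[[length(rows) + 1L]] <- data.frame(
        layer = ly, u = sub$id1[i], v = sub$id2[i],
        similarity = sub$similarity[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$layer, out$u, out$v), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an intra-layer candidate edge from two member distances
#'
#' Given the shortest-path hop distances between the member nodes of two pair
#' nodes — `d1` in network 1, `d2` in network 2 — returns the homogeneous
#' edge kind: `HOM_MATCH` if the members are adjacent in both networks
#' (`d1 == 1` and `d2 == 1`); `HOM_GAP` if they are adjacent in exactly one
#' and at distance in `[2, delta]` in the other; `HOM_MISMATCH` if adjacent in
#' exactly one and at distance beyond `delta` (or disconnected) in the other;
#' `NA` otherwise (no edge). `delta` is the gap threshold discriminating gaps
#' from mismatches.
#'
#' @param d1,d2 Hop distances (>= 1, or `Inf` for disconnected).
#' @param delta Integer gap threshold, >= 2.
#' @return One of `"HOM_MATCH"`, `"HOM_GAP"`, `"HOM_MISMATCH"`, or
#'   `NA_character_`.
#' @examples
#' classifyIntra(1, 1, 2)  # HOM_MATCH
#' classifyIntra(1, 2, 2)  # HOM_GAP
#' classifyIntra(1, 3, 2)  # HOM_MISMATCH
#' classifyIntra(2, 2, 2)  # NA: no edge
#' @export
classifyIntra <- function(d1, d2, delta = 2L) {
  if (delta < 2) stop("delta must be >= 2")
  if (is.na(d1) || is.na(d2) || d1 < 1 || d2 < 1)
    stop("distances must be >= 1 or Inf")
  if (d1 == 1 && d2 == 1) return("HOM_MATCH")
  if (xor(d1 == 1, d2 == 1)) {
    other <- max(d1, d2)
    if (other <= delta) return("HOM_GAP")
    return("HOM_MISMATCH")
  }
  NA_character_
}

# igraph handle for one layer's intra-edge graph over the full layer node set
.layerGraph <- function(net, layer) {
  ids <- nodeIds(net, layer)
  e <- intraEdges(net, layer)
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = ids))
}

#' Build the alignment edges of one layer
#'
#' For every unordered pair of pair nodes `(u1,v1)`, `(u2,v2)` of the layer
#' (with distinct members on both sides), computes the member hop distances in
#' the two input layer graphs and applies [classifyIntra()]; a classified pair
#' yields an edge with the configured weight for its kind.
#'
#' @param layer Layer identifier.
#' @param pairNodes Pair-node table from [selectPairNodes()].
#' @param net1,net2 The two input networks.
#' @param cfg A [ScoringConfig-class].
#' @return `data.frame(layer1, u1, v1, layer2, u2, v2, kind, weight)`.
#' @export
buildLayerAlignmentGraph <- function(layer, pairNodes, net1, net2,
                                     cfg = ScoringConfig()) {
  pn <- pairNodes[pairNodes$layer == layer, , drop = FALSE]
  pn <- pn[order(pn$u, pn$v), , drop = FALSE]
  n <- nrow(pn)
  empty <- data.frame(layer1 = character(0), u1 = character(0),
                      v1 = character(0), layer2 = character(0),
                      u2 = character(0), v2 = character(0),
                      kind = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < 2) return(empty)
  d1 <- igraph::distances(.layerGraph(net1, layer), v = pn$u, to = pn$u)
  d2 <- igraph::distances(.layerGraph(net2, layer), v = pn$v, to = pn$v)
  w <- c(HOM_MATCH = cfg@wMatch, HOM_MISMATCH = cfg@wMismatch,
         HOM_GAP = cfg@wGap)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (pn$u[i] == pn$u[j] || pn$v[i] == pn$v[j]) next  # defensive
      kind <- classifyIntra(d1[i, j], d2[i, j], cfg@delta)
      if (is.na(kind)) next
      rows[[length(rows) + 1L]] <- data.frame(
        layer1 = layer, u1 = pn$u[i], v1 = pn$v[i],
        layer2 = layer, u2 = pn$u[j], v2 = pn$v[j],
        kind = kind, weight = unname(w[kind]), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Add inter-layer edges to the alignment graph
#'
#' For every pair of pair nodes in two different layers, checks whether the
#' corresponding inter-layer edge exists in each input network: present in
#' both yields a heterogeneous match, present in exactly one a heterogeneous
#' mismatch, absent in both no edge.
#'
#' @inheritParams buildLayerAlignmentGraph
#' @return Edge `data.frame` as in [buildLayerAlignmentGraph()], with kinds
#'   `HET_MATCH` / `HET_MISMATCH`.
#' @export
addInterlayerEdges <- function(pairNodes, net1, net2, cfg = ScoringConfig()) {
  empty <- data.frame(layer1 = character(0), u1 = character(0),
                      v1 = character(0), layer2 = character(0),
                      u2 = character(0), v2 = character(0),
                      kind = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  layers <- unique(pairNodes$layer)
  if (length(layers) < 2) return(empty)
  ie1 <- interEdges(net1); ie2 <- interEdges(net2)
  keys1 <- .interKey(ie1$layer1, ie1$id1, ie1$layer2, ie1$id2)
  keys2 <- .interKey(ie2$layer1, ie2$id1, ie2$layer2, ie2$id2)
  rows <- list()
  pairIdx <- utils::combn(length(layers), 2)
  for (p in seq_len(ncol(pairIdx))) {
    k <- layers[pairIdx[1, p]]; h <- layers[pairIdx[2, p]]
    pk <- pairNodes[pairNodes$layer == k, , drop = FALSE]
    ph <- pairNodes[pairNodes$layer == h, , drop = FALSE]
    if (nrow(pk) == 0 || nrow(ph) == 0) next
    for (i in seq_len(nrow(pk))) {
      c1 <- .canonInter(rep(k, nrow(ph)), rep(pk$u[i], nrow(ph)), rep(h, nrow(ph)), ph$u)
      c2 <- .canonInter(rep(k, nrow(ph)), rep(pk$v[i], nrow(ph)), rep(h, nrow(ph)), ph$v)
      e1 <- .interKey(c1$layer1, c1$id1, c1$layer2, c1$id2) %in% keys1
      e2 <- .interKey(c2$layer1, c2$id1, c2$layer2, c2$id2) %in% keys2
      kind <- ifelse(e1 & e2, "HET_MATCH",
                     ifelse(xor(e1, e2), "HET_MISMATCH", NA_character_))
      hit <- which(!is.na(kind))
      if (length(hit) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        layer1 = k, u1 = pk$u[i], v1 = pk$v[i],
        layer2 = h, u2 = ph$u[hit], v2 = ph$v[hit],
        kind = kind[hit],
        weight = ifelse(kind[hit] == "HET_MATCH", cfg@wHetMatch, cfg@wHetMismatch),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$layer1, out$u1, out$v1, out$layer2, out$u2, out$v2), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the full multilayer alignment graph
#'
#' Orchestrates the two construction steps: (i.a) pair-node selection and
#' intra-layer edge classification for every layer the two networks share,
#' then (i.b) inter-layer edge classification. Layers present in only one
#' network are skipped with a warning; disjoint layer vocabularies are an
#' error.
#'
#' @param net1,net2 The two input [MultilayerNetwork-class] objects.
#' @param seeds A [SeedMap-class].
#' @param cfg A [ScoringConfig-class].
#' @return A [MultilayerAlignmentGraph-class].
#' @examples
#' net <- generateMultilayer(10, 2, 14, seed = 1)
#' g <- buildMultilayerAlignmentGraph(net, net, identitySeeds(net))
#' g  # self-alignment: every edge is a match
#' @export
buildMultilayerAlignmentGraph <- function(net1, net2, seeds,
                                          cfg = ScoringConfig()) {
  common <- intersect(layerNames(net1), layerNames(net2))
  if (length(common) == 0)
    stop("the two networks share no layer identifiers")
  skipped <- setdiff(union(layerNames(net1), layerNames(net2)), common)
  if (length(skipped))
    warning(sprintf("skipping layer(s) present in only one network: %s",
                    paste(skipped, collapse = ", ")))
  pn <- selectPairNodes(seeds, net1, net2)
  pn <- pn[pn$layer %in% common, , drop = FALSE]
  intra <- lapply(common, buildLayerAlignmentGraph, pairNodes = pn,
                  net1 = net1, net2 = net2, cfg = cfg)
  inter <- addInterlayerEdges(pn, net1, net2, cfg)
  edges <- do.call(rbind, c(intra, list(inter)))
  rownames(edges) <- NULL
  new("MultilayerAlignmentGraph", layers = common, pairNodes = pn,
      edges = edges)
}

#' Export an alignment graph to TSV
#'
#' Writes the alignment-graph dialect: header `#multiloal-aligngraph v1`,
#' node lines `N<TAB>layer<TAB>u|v<TAB>similarity` and edge lines
#' `E<TAB>layer_p<TAB>u1|v1<TAB>layer_q<TAB>u2|v2<TAB>kind<TAB>weight`,
#' deterministically sorted.
#'
#' @param g A [MultilayerAlignmentGraph-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeAlignmentGraph <- function(g, path) {
  stopifnot(is(g, "MultilayerAlignmentGraph"))
  pn <- g@pairNodes
  pn <- pn[order(pn$layer, pn$u, pn$v), , drop = FALSE]
  nodeLines <- if (nrow(pn)) paste("N", pn$layer, paste(pn$u, pn$v, sep = "|"),
                                   format(pn$similarity, trim = TRUE), sep = "\t")
  ed <- g@edges
  ed <- ed[order(ed$layer1, ed$u1, ed$v1, ed$layer2, ed$u2, ed$v2), ,
           drop = FALSE]
  edgeLines <- if (nrow(ed)) paste("E", ed$layer1, paste(ed$u1, ed$v1, sep = "|"),
                                   ed$layer2, paste(ed$u2, ed$v2, sep = "|"),
                                   ed$kind, format(ed$weight, trim = TRUE),
                                   sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("#multiloal-aligngraph v1", nodeLines, edgeLines), con, sep = "\n")
  invisible(path)
}
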