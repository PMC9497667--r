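#' @import methods
NULL

#' MultilayerNetwork: a set of graph layers joined by inter-layer edges
#'
#' Container for an undirected multilayer network: an ordered set of layers,
#' a node set per layer, an intra-layer edge set per layer, and one set of
#' inter-layer edges whose endpoints lie in two different layers. Nodes are
#' namespaced per layer: the same id occurring in two layers denotes two
#' distinct nodes. Edges are unordered, stored canonically (endpoints sorted),
#' with no self-loops and no duplicates.
#'
#' @slot name Character scalar naming the network.
#' @slot layers Character vector of layer identifiers in declaration order.
#' @slot nodes Named list, one character vector of node ids per layer.
#' @slot intraEdges Named list, one `data.frame(from, to)` per layer with
#'   `from < to` lexicographically.
#' @slot interEdges `data.frame(layer1, id1, layer2, id2)` with
#'   `(layer1, id1) < (layer2, id2)` and `layer1 != layer2`.
#' @seealso [MultilayerNetwork()] for construction,
#'   [readMultilayerEdgelist()] for file input, [validateNetwork()].
#' @export
setClass("MultilayerNetwork", representation(
  name = "character",
  layers = "character",
  nodes = "list",
  intraEdges = "list",
  interEdges = "data.frame"
))

setValidity("MultilayerNetwork", function(object) {
  v <- validateNetwork(object)
  if (length(v) == 0) TRUE else v
})

#' SeedMap: seed node similarities between two networks
#'
#' A list of candidate cross-network node correspondences (e.g. orthology
#' scores): each entry pairs a node of network 1 with a node of network 2 in
#' the *same* layer and carries a similarity in `[0, 1]`. Seed entries guide
#' the selection of pair nodes when the alignment graph is built.
#'
#' @slot entries `data.frame(layer, id1, id2, similarity)`.
#' @seealso [readSeedMap()], [identitySeeds()], [selectPairNodes()].
#' @export
setClass("SeedMap", representation(entries = "data.frame"))

setValidity("SeedMap", function(object) {
  e <- object@entries
  need <- c("layer", "id1", "id2", "similarity")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  if (nrow(e) > 0 && (!is.numeric(e$similarity) ||
                      any(e$similarity < 0 | e$similarity > 1)))
    return("similarity values must lie in [0, 1]")
  TRUE
})

#' ScoringConfig: alignment-edge weights and the gap threshold
#'
#' Weights assigned to the five alignment-edge kinds and the gap threshold
#' `delta` (shortest-path length discriminating gaps from mismatches within a
#' layer). Defaults follow the reference parameterisation: homogeneous
#' match 1.0, mismatch 0.5, gap 0.2; heterogeneous match 0.9, mismatch 0.4;
#' `delta = 2`.
#'
#' @slot wMatch,wMismatch,wGap Weights for homogeneous (intra-layer) edge kinds.
#' @slot wHetMatch,wHetMismatch Weights for heterogeneous (inter-layer) kinds.
#' @slot delta Integer gap threshold, at least 2.
#' @export
setClass("ScoringConfig", representation(
  wMatch = "numeric", wMismatch = "numeric", wGap = "numeric",
  wHetMatch = "numeric", wHetMismatch = "numeric", delta = "integer"
))

setValidity("ScoringConfig", function(object) {
  w <- c(object@wMatch, object@wMismatch, object@wGap,
         object@wHetMatch, object@wHetMismatch)
  if (length(w) != 5 || any(!is.finite(w)) || any(w <= 0))
    return("all five weights must be positive finite scalars")
  if (length(object@delta) != 1 || is.na(object@delta) || object@delta < 2L)
    return("delta must be an integer >= 2")
  TRUE
})

#' MultilayerAlignmentGraph: matched node pairs with scored joint-adjacency edges
#'
#' The merged representation of two multilayer networks: each vertex (a "pair
#' node") matches one node of network 1 with one node of network 2 in the same
#' layer; each edge records how the two member pairs relate in the two inputs —
#' homogeneous match/mismatch/gap within a layer, heterogeneous match/mismatch
#' across layers — together with its configured weight.
#'
#' @slot layers Character vector of layers shared by the two input networks.
#' @slot pairNodes `data.frame(layer, u, v, similarity)`; within a layer each
#'   `u` and each `v` appears at most once (one-to-one pairing).
#' @slot edges `data.frame(layer1, u1, v1, layer2, u2, v2, kind, weight)` with
#'   `kind` one of `HOM_MATCH`, `HOM_MISMATCH`, `HOM_GAP`, `HET_MATCH`,
#'   `HET_MISMATCH`.
#' @seealso [buildMultilayerAlignmentGraph()], [detectCommunities()].
#' @export
setClass("MultilayerAlignmentGraph", representation(
  layers = "character",
  pairNodes = "data.frame",
  edges = "data.frame"
))

.EDGE_KINDS <- c("HOM_MATCH", "HOM_MISMATCH", "HOM_GAP",
                 "HET_MATCH", "HET_MISMATCH")

setValidity("MultilayerAlignmentGraph", function(object) {
  pn <- object@pairNodes
  ed <- object@edges
  if (!all(c("layer", "u", "v", "similarity") %in% names(pn)))
    return("pairNodes must have columns layer, u, v, similarity")
  if (!all(c("layer1", "u1", "v1", "layer2", "u2", "v2", "kind", "weight")
           %in% names(ed)))
    return("edges must have columns layer1,u1,v1,layer2,u2,v2,kind,weight")
  if (nrow(pn) > 0) {
    for (ly in unique(pn$layer)) {
      sub <- pn[pn$layer == ly, ]
      if (anyDuplicated(sub$u) || anyDuplicated(sub$v))
        return(sprintf("pairing is not one-to-one in layer '%s'", ly))
    }
  }
  if (nrow(ed) > 0) {
    if (!all(ed$kind %in% .EDGE_KINDS))
      return("unknown edge kind")
    hom <- startsWith(ed$kind, "HOM")
    if (any(hom & ed$layer1 != ed$layer2))
      return("homogeneous edges must join pair nodes of the same layer")
    if (any(!hom & ed$layer1 == ed$layer2))
      return("heterogeneous edges must join pair nodes of different layers")
    key <- paste(ed$layer1, ed$u1, ed$v1, ed$layer2, ed$u2, ed$v2, sep = "\t")
    if (anyDuplicated(key)) return("duplicate alignment edges")
    if (any(ed$layer1 == ed$layer2 & ed$u1 == ed$u2 & ed$v1 == ed$v2))
      return("self-loop alignment edge")
  }
  TRUE
})

#' CommunitySet: a partition of alignment-graph pair nodes
#'
#' Result of mining the multilayer alignment graph: every pair node is assigned
#' to exactly one community; each community is one candidate local region of
#' similarity between the two input networks.
#'
#' @slot membership `data.frame(layer, u, v, community)` with integer community
#'   ids, one row per pair node.
#' @slot method Character scalar: the backend that produced the partition.
#' @slot seed Integer RNG seed used by the backend.
#' @seealso [detectCommunities()], [communitiesToAlignment()],
#'   [writeCommunities()].
#' @export
setClass("CommunitySet", representation(
  membership = "data.frame",
  method = "character",
  seed = "integer"
))

setValidity("CommunitySet", function(object) {
  m <- object@membership
  if (!all(c("layer", "u", "v", "community") %in% names(m)))
    return("membership must have columns layer, u, v, community")
  if (nrow(m) > 0 && anyDuplicated(paste(m$layer, m$u, m$v, sep = "\t")))
    return("a pair node appears in more than one community")
  TRUE
})

#' EvaluationReport: alignment quality scores
#'
#' Per-layer and aggregated quality of a local alignment against a known true
#' node mapping: node correctness (P-NC, R-NC and their F-score F-NC) and the
#' coverage/conservation measure NCV-GS3, computed per layer over intra-layer
#' edges, averaged into multilayer scores, and computed once over the pooled
#' inter-layer edge sets.
#'
#' @slot perLayer `data.frame(layer, p_nc, r_nc, f_nc, ncv, gs3, ncv_gs3)`.
#' @slot multilayerFNC Mean of the per-layer F-NC values.
#' @slot multilayerNcvGs3 Mean of the per-layer NCV-GS3 values.
#' @slot interlayerNcvGs3 NCV-GS3 computed on the pooled inter-layer edges.
#' @slot interlayerFNC Node correctness restricted to nodes incident to
#'   inter-layer edges.
#' @seealso [evaluateAlignment()].
#' @export
setClass("EvaluationReport", representation(
  perLayer = "data.frame",
  multilayerFNC = "numeric",
  multilayerNcvGs3 = "numeric",
  interlayerNcvGs3 = "numeric",
  interlayerFNC = "numeric"
))
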