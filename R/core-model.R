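#' Construct a MultilayerNetwork
#'
#' Builds a validated [MultilayerNetwork-class] from node and edge tables.
#' Edges are canonicalised (endpoints sorted) and deduplicated; construction
#' fails if any invariant is violated (self-loops, endpoints outside the
#' declared node sets, inter-layer edges within one layer).
#'
#' @param name Network name.
#' @param layers Character vector of layer identifiers (order is kept).
#' @param nodes Named list mapping each layer to a character vector of node ids.
#' @param intraEdges Named list mapping layers to `data.frame(from, to)`
#'   (or 2-column matrices) of intra-layer edges. Missing layers get no edges.
#' @param interEdges `data.frame(layer1, id1, layer2, id2)` of inter-layer
#'   edges (may be `NULL`).
#' @return A `MultilayerNetwork`.
#' @examples
#' net <- MultilayerNetwork(
#'   name = "toy", layers = c("L1", "L2"),
#'   nodes = list(L1 = c("a", "b"), L2 = c("x")),
#'   intraEdges = list(L1 = data.frame(from = "a", to = "b")),
#'   interEdges = data.frame(layer1 = "L1", id1 = "a", layer2 = "L2", id2 = "x")
#' )
#' numEdges(net)
#' @export
MultilayerNetwork <- function(name = "", layers = character(),
                              nodes = list(), intraEdges = list(),
                              interEdges = NULL) {
  layers <- as.character(layers)
  nodeList <- stats::setNames(vector("list", length(layers)), layers)
  for (ly in layers) {
    ids <- nodes[[ly]]
    nodeList[[ly]] <- sort(unique(as.character(if (is.null(ids)) character() else ids)))
  }
  intraList <- stats::setNames(vector("list", length(layers)), layers)
  for (ly in layers) {
    e <- intraEdges[[ly]]
    if (is.null(e) || NROW(e) == 0) {
      intraList[[ly]] <- .df0("from", "to")
    } else {
      e <- as.data.frame(e, stringsAsFactors = FALSE)
      ce <- .canonIntra(as.character(e[[1]]), as.character(e[[2]]))
      ce <- unique(ce)
      ce <- ce[order(ce$from, ce$to), , drop = FALSE]
      rownames(ce) <- NULL
      intraList[[ly]] <- ce
    }
  }
  if (is.null(interEdges) || NROW(interEdges) == 0) {
    inter <- .df0("layer1", "id1", "layer2", "id2")
  } else {
    e <- as.data.frame(interEdges, stringsAsFactors = FALSE)
    inter <- .canonInter(as.character(e[[1]]), as.character(e[[2]]),
                         as.character(e[[3]]), as.character(e[[4]]))
    inter <- unique(inter)
    inter <- inter[order(inter$layer1, inter$id1, inter$layer2, inter$id2), ,
                   drop = FALSE]
    rownames(inter) <- NULL
  }
  new("MultilayerNetwork", name = as.character(name), layers = layers,
      nodes = nodeList, intraEdges = intraList, interEdges = inter)
}

#' Validate a multilayer network, reporting every violation
#'
#' Checks the structural invariants of a multilayer network — edge endpoints
#' declared in their layer's node set, no self-loops, no duplicate edges,
#' inter-layer edges spanning two distinct layers — and returns one message per
#' violation. Unlike the class validity check (which refuses to construct an
#' invalid object), this function never throws, so it can audit externally
#' assembled data: `net` may be a [MultilayerNetwork-class] or a plain list
#' with elements `layers`, `nodes`, `intraEdges`, `interEdges`.
#'
#' @param net A `MultilayerNetwork` or a list with the same fields.
#' @return Character vector of violation descriptions; `character(0)` if valid.
#' @examples
#' net <- generateMultilayer(nNodes = 10, nLayers = 2, nEdges = 12, seed = 1)
#' validateNetwork(net)
#' @export
validateNetwork <- function(net) {
  if (is(net, "MultilayerNetwork")) {
    layers <- net@layers; nodes <- net@nodes
    intra <- net@intraEdges; inter <- net@interEdges
  } else {
    layers <- net$layers; nodes <- net$nodes
    intra <- net$intraEdges; inter <- net$interEdges
  }
  out <- character()
  if (anyDuplicated(layers))
    out <- c(out, "duplicate layer identifiers")
  if (!setequal(names(nodes), layers) || !setequal(names(intra), layers))
    out <- c(out, "nodes/intraEdges must be keyed exactly by the layers")
  for (ly in intersect(layers, names(nodes))) {
    ids <- nodes[[ly]]
    if (any(!nzchar(ids)))
      out <- c(out, sprintf("empty node id in layer '%s'", ly))
    if (anyDuplicated(ids))
      out <- c(out, sprintf("duplicate node ids in layer '%s'", ly))
  }
  for (ly in intersect(layers, names(intra))) {
    e <- intra[[ly]]
    if (NROW(e) == 0) next
    ids <- nodes[[ly]]
    loops <- e$from == e$to
    for (i in which(loops))
      out <- c(out, sprintf("self-loop on '%s' in layer '%s'", e$from[i], ly))
    bad <- !(e$from %in% ids) | !(e$to %in% ids)
    for (i in which(bad & !loops))
      out <- c(out, sprintf("intra-edge (%s,%s) in layer '%s' uses undeclared node",
                            e$from[i], e$to[i], ly))
    key <- .intraKey(ly, pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key))
      out <- c(out, sprintf("duplicate intra-edges in layer '%s'", ly))
  }
  if (NROW(inter) > 0) {
    same <- inter$layer1 == inter$layer2
    for (i in which(same))
      out <- c(out, sprintf("inter-edge (%s:%s,%s:%s) lies within one layer",
                            inter$layer1[i], inter$id1[i],
                            inter$layer2[i], inter$id2[i]))
    for (i in which(!same)) {
      ok1 <- inter$layer1[i] %in% layers &&
        inter$id1[i] %in% nodes[[inter$layer1[i]]]
      ok2 <- inter$layer2[i] %in% layers &&
        inter$id2[i] %in% nodes[[inter$layer2[i]]]
      if (!ok1 || !ok2)
        out <- c(out, sprintf("inter-edge (%s:%s,%s:%s) uses undeclared node",
                              inter$layer1[i], inter$id1[i],
                              inter$layer2[i], inter$id2[i]))
    }
    key <- .interKey(inter$layer1, inter$id1, inter$layer2, inter$id2)
    if (anyDuplicated(key))
      out <- c(out, "duplicate inter-edges")
  }
  out
}

#' Construct a ScoringConfig
#'
#' @param wMatch,wMismatch,wGap Weights for homogeneous match / mismatch / gap
#'   edges (defaults 1.0 / 0.5 / 0.2).
#' @param wHetMatch,wHetMismatch Weights for heterogeneous match / mismatch
#'   edges (defaults 0.9 / 0.4).
#' @param delta Gap threshold (shortest-path length, integer >= 2; default 2):
#'   a pair adjacent in one network is a gap if its counterpart distance in the
#'   other network is in `[2, delta]`, a mismatch if it exceeds `delta`.
#' @return A [ScoringConfig-class].
#' @examples
#' ScoringConfig()
#' ScoringConfig(delta = 3)
#' @export
ScoringConfig <- function(wMatch = 1.0, wMismatch = 0.5, wGap = 0.2,
                          wHetMatch = 0.9, wHetMismatch = 0.4, delta = 2L) {
  new("ScoringConfig", wMatch = wMatch, wMismatch = wMismatch, wGap = wGap,
      wHetMatch = wHetMatch, wHetMismatch = wHetMismatch,
      delta = as.integer(delta))
}

#' Construct a SeedMap from a table of entries
#'
#' @param entries `data.frame(layer, id1, id2, similarity)`.
#' @return A [SeedMap-class].
#' @export
SeedMap <- function(entries = NULL) {
  if (is.null(entries) || NROW(entries) == 0) {
    entries <- cbind(.df0("layer", "id1", "id2"),
                     data.frame(similarity = numeric(0)))
  } else {
    entries <- data.frame(layer = as.character(entries$layer),
                          id1 = as.character(entries$id1),
                          id2 = as.character(entries$id2),
                          similarity = as.numeric(entries$similarity),
                          stringsAsFactors = FALSE)
  }
  new("SeedMap", entries = entries)
}

## ---- accessors -------------------------------------------------------------

#' Accessors for MultilayerNetwork
#'
#' @param x A `MultilayerNetwork`.
#' @param layer A layer identifier, or `NULL` for all layers.
#' @param type One of `"all"`, `"intra"`, `"inter"`.
#' @name MultilayerNetwork-accessors
#' @rdname MultilayerNetwork-accessors
NULL

#' @describeIn MultilayerNetwork-accessors Layer identifiers in declaration
#'   order.
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname MultilayerNetwork-accessors
#' @export
setMethod("layerNames", "MultilayerNetwork", function(x) x@layers)

#' @describeIn MultilayerNetwork-accessors Node ids of one layer, or all
#'   layers as a named list.
#' @export
setGeneric("nodeIds", function(x, layer = NULL) standardGeneric("nodeIds"))

#' @rdname MultilayerNetwork-accessors
#' @export
setMethod("nodeIds", "MultilayerNetwork", function(x, layer = NULL) {
  if (is.null(layer)) return(x@nodes)
  if (!layer %in% x@layers) stop(sprintf("unknown layer '%s'", layer))
  x@nodes[[layer]]
})

#' @describeIn MultilayerNetwork-accessors Intra-layer edges of one layer
#'   (or all layers as a named list).
#' @export
setGeneric("intraEdges", function(x, layer = NULL) standardGeneric("intraEdges"))

#' @rdname MultilayerNetwork-accessors
#' @export
setMethod("intraEdges", "MultilayerNetwork", function(x, layer = NULL) {
  if (is.null(layer)) return(x@intraEdges)
  if (!layer %in% x@layers) stop(sprintf("unknown layer '%s'", layer))
  x@intraEdges[[layer]]
})

#' @describeIn MultilayerNetwork-accessors Inter-layer edge table.
#' @export
setGeneric("interEdges", function(x) standardGeneric("interEdges"))

#' @rdname MultilayerNetwork-accessors
#' @export
setMethod("interEdges", "MultilayerNetwork", function(x) x@interEdges)

#' @describeIn MultilayerNetwork-accessors Total node count across layers.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname MultilayerNetwork-accessors
#' @export
setMethod("numNodes", "MultilayerNetwork", function(x)
  sum(lengths(x@nodes)))

#' @describeIn MultilayerNetwork-accessors Edge count of the requested class.
#' @export
setGeneric("numEdges", function(x, type = c("all", "intra", "inter"))
  standardGeneric("numEdges"))

#' @rdname MultilayerNetwork-accessors
#' @export
setMethod("numEdges", "MultilayerNetwork", function(x, type = c("all", "intra", "inter")) {
  type <- match.arg(type)
  nIntra <- sum(vapply(x@intraEdges, nrow, integer(1)))
  nInter <- nrow(x@interEdges)
  switch(type, all = nIntra + nInter, intra = nIntra, inter = nInter)
})

#' Query edge presence, independent of endpoint order
#'
#' Edges are undirected: `hasIntraEdge(net, "L1", "a", "b")` and
#' `hasIntraEdge(net, "L1", "b", "a")` agree, as do the two endpoint orders of
#' [hasInterEdge()].
#'
#' @param net A [MultilayerNetwork-class].
#' @param layer Layer of both endpoints (intra) .
#' @param u,v Node ids.
#' @return Logical scalar.
#' @export
hasIntraEdge <- function(net, layer, u, v) {
  e <- intraEdges(net, layer)
  if (nrow(e) == 0) return(FALSE)
  a <- min(u, v); b <- max(u, v)
  any(e$from == a & e$to == b)
}

#' @rdname hasIntraEdge
#' @param layerU,layerV Layers of the two endpoints (inter).
#' @export
hasInterEdge <- function(net, layerU, u, layerV, v) {
  e <- interEdges(net)
  if (nrow(e) == 0) return(FALSE)
  ce <- .canonInter(layerU, u, layerV, v)
  any(e$layer1 == ce$layer1 & e$id1 == ce$id1 &
        e$layer2 == ce$layer2 & e$id2 == ce$id2)
}


## ---- show methods ----------------------------------------------------------

setMethod("show", "MultilayerNetwork", function(object) {
  cat(sprintf("MultilayerNetwork '%s': %d layer(s), %d node(s), %d intra + %d inter edge(s)\n",
              object@name, length(object@layers), numNodes(object),
              numEdges(object, "intra"), numEdges(object, "inter")))
  for (ly in object@layers)
    cat(sprintf("  layer %-8s %3d nodes, %3d edges\n", ly,
                length(object@nodes[[ly]]), nrow(object@intraEdges[[ly]])))
})

setMethod("show", "SeedMap", function(object) {
  cat(sprintf("SeedMap: %d entr%s over %d layer(s)\n",
              nrow(object@entries), if (nrow(object@entries) == 1) "y" else "ies",
              length(unique(object@entries$layer))))
})

setMethod("show", "ScoringConfig", function(object) {
  cat(sprintf(paste0("ScoringConfig: match=%g mismatch=%g gap=%g ",
                     "het-match=%g het-mismatch=%g delta=%d\n"),
              object@wMatch, object@wMismatch, object@wGap,
              object@wHetMatch, object@wHetMismatch, object@delta))
})

setMethod("show", "MultilayerAlignmentGraph", function(object) {
  kinds <- table(factor(object@edges$kind, levels = .EDGE_KINDS))
  cat(sprintf("MultilayerAlignmentGraph: %d pair node(s) in %d layer(s), %d edge(s)\n",
              nrow(object@pairNodes), length(object@layers), nrow(object@edges)))
  if (nrow(object@edges) > 0)
    cat("  ", paste(sprintf("%s=%d", names(kinds), as.integer(kinds)),
                    collapse = " "), "\n", sep = "")
})

setMethod("show", "CommunitySet", function(object) {
  m <- object@membership
  sizes <- if (nrow(m)) table(m$community) else integer(0)
  cat(sprintf("CommunitySet (%s, seed %d): %d communit%s over %d pair node(s)\n",
              object@method, object@seed, length(sizes),
              if (length(sizes) == 1) "y" else "ies", nrow(m)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  print(object@perLayer, row.names = FALSE, digits = 4)
  cat(sprintf("  multilayer F-NC     %.4f\n", object@multilayerFNC))
  cat(sprintf("  multilayer NCV-GS3  %.4f\n", object@multilayerNcvGs3))
  cat(sprintf("  interlayer NCV-GS3  %.4f\n", object@interlayerNcvGs3))
  cat(sprintf("  interlayer F-NC     %.4f\n", object@interlayerFNC))
})
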