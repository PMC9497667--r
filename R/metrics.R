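## Alignment quality measures: node correctness (P-NC / R-NC / F-NC) and the
## coverage/conservation measure NCV-GS3, per layer, aggregated across layers,
## and pooled over inter-layer edges.

.pairSetKey <- function(df) paste(df$u, df$v, sep = "\t")

#' Node correctness of an alignment against the true mapping
#'
#' With `M` the set of node pairs mapped under the true node mapping and `N`
#' the set of pairs aligned by the method, computes
#' `P-NC = |M intersect N| / |M|`, `R-NC = |M intersect N| / |N|` (0 if `N` is
#' empty), and their combination F-NC (harmonic mean by default, the usual
#' F-score; arithmetic mean available via `combine`).
#'
#' @param M `data.frame(u, v)` of true pairs (non-empty).
#' @param N `data.frame(u, v)` of aligned pairs.
#' @param combine `"harmonic"` (default) or `"arithmetic"`.
#' @return Named list `p_nc`, `r_nc`, `f_nc`.
#' @examples
#' M <- data.frame(u = c("a", "b", "c"), v = c("a", "b", "c"))
#' N <- data.frame(u = c("a", "b"), v = c("a", "x"))
#' nodeCorrectness(M, N)  # p = 1/3, r = 1/2, f = 0.4
#' @export
nodeCorrectness <- function(M, N, combine = c("harmonic", "arithmetic")) {
  combine <- match.arg(combine)
  if (NROW(M) == 0) stop("true mapping M is empty: node correctness undefined")
  mKeys <- unique(.pairSetKey(M))
  nKeys <- unique(.pairSetKey(N))
  inter <- length(intersect(mKeys, nKeys))
  p <- inter / length(mKeys)
  r <- if (length(nKeys) == 0) 0 else inter / length(nKeys)
  f <- if (combine == "harmonic") {
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  } else {
    (p + r) / 2
  }
  list(p_nc = p, r_nc = r, f_nc = f)
}

#' Average per-layer F-NC values into the multilayer F-NC
#'
#' @param values Numeric vector of per-layer F-NC values (>= 1 layer).
#' @return Arithmetic mean.
#' @export
multilayerFNC <- function(values) {
  if (length(values) == 0) stop("no layers: multilayer F-NC undefined")
  mean(values)
}

#' @rdname multilayerFNC
#' @export
multilayerNcvGs3 <- function(values) {
  if (length(values) == 0) stop("no layers: multilayer NCV-GS3 undefined")
  mean(values)
}

# conserved-edge count and induced edge counts for one layer mapping
.gs3Counts <- function(e1, e2, fMap) {
  # e1, e2: canonical data.frame(from, to); fMap: named map u -> v
  aligned1 <- names(fMap)
  ind1 <- e1[e1$from %in% aligned1 & e1$to %in% aligned1, , drop = FALSE]
  aligned2 <- unname(fMap)
  ind2 <- e2[e2$from %in% aligned2 & e2$to %in% aligned2, , drop = FALSE]
  keys2 <- .pairSetKey(data.frame(u = ind2$from, v = ind2$to))
  if (nrow(ind1)) {
    fa <- unname(fMap[ind1$from]); fb <- unname(fMap[ind1$to])
    mapped <- paste(pmin(fa, fb), pmax(fa, fb), sep = "\t")
    conserved <- sum(mapped %in% keys2)
  } else conserved <- 0L
  list(e1 = nrow(ind1), e2 = nrow(ind2), conserved = conserved)
}

.combineNcvGs3 <- function(ncv, gs3, combine) {
  if (combine == "geometric") sqrt(ncv * gs3) else (ncv + gs3) / 2
}

#' NCV, GS3 and NCV-GS3 of one layer
#'
#' Let `G1'`, `G2'` be the subgraphs of the two layer graphs induced by the
#' aligned nodes (domain and image of the layer mapping `f`). Node coverage
#' `NCV = (|V(G1')| + |V(G2')|) / (|V1| + |V2|)`; with `c` the number of edges
#' of `G1'` whose image under `f` is an edge of `G2'`,
#' `GS3 = c / (|E(G1')| + |E(G2')| - c)` (defined as 1 when both induced edge
#' sets are empty). NCV-GS3 combines the two, by default as the geometric
#' mean.
#'
#' @param net1,net2 The two [MultilayerNetwork-class] objects.
#' @param layer Layer identifier present in both networks.
#' @param f `data.frame(u, v)`: the layer's aligned pairs (one-to-one).
#' @param combine `"geometric"` (default) or `"arithmetic"`.
#' @return Named list `ncv`, `gs3`, `ncv_gs3`.
#' @export
ncvGs3Layer <- function(net1, net2, layer, f,
                        combine = c("geometric", "arithmetic")) {
  combine <- match.arg(combine)
  if (NROW(f) > 0 && (anyDuplicated(f$u) || anyDuplicated(f$v)))
    stop(sprintf("mapping is not one-to-one in layer '%s'", layer))
  v1 <- nodeIds(net1, layer); v2 <- nodeIds(net2, layer)
  fMap <- stats::setNames(as.character(f$v), as.character(f$u))
  ncv <- (sum(names(fMap) %in% v1) + sum(fMap %in% v2)) /
    (length(v1) + length(v2))
  cts <- .gs3Counts(intraEdges(net1, layer), intraEdges(net2, layer), fMap)
  denom <- cts$e1 + cts$e2 - cts$conserved
  gs3 <- if (cts$e1 == 0 && cts$e2 == 0) 1 else
    if (denom == 0) 0 else cts$conserved / denom
  list(ncv = ncv, gs3 = gs3, ncv_gs3 = .combineNcvGs3(ncv, gs3, combine))
}

#' Pooled NCV-GS3 over all inter-layer edges
#'
#' Applies the NCV-GS3 construction to the inter-layer edge sets as a whole:
#' induced inter-layer edges among aligned nodes in each network, conserved
#' edges those whose layer-wise image under the mapping is an inter-layer edge
#' of the other network, and NCV computed over the union of the node sets of
#' all layers.
#'
#' @param net1,net2 The two [MultilayerNetwork-class] objects.
#' @param f Full alignment mapping `data.frame(layer, u, v)`, one-to-one per
#'   layer.
#' @param combine `"geometric"` (default) or `"arithmetic"`.
#' @return Named list `ncv`, `gs3`, `ncv_gs3`.
#' @export
interlayerNcvGs3 <- function(net1, net2, f,
                             combine = c("geometric", "arithmetic")) {
  combine <- match.arg(combine)
  for (ly in unique(f$layer)) {
    sub <- f[f$layer == ly, , drop = FALSE]
    if (anyDuplicated(sub$u) || anyDuplicated(sub$v))
      stop(sprintf("mapping is not one-to-one in layer '%s'", ly))
  }
  keyOf <- function(layer, id) paste(layer, id, sep = "\t")
  fMap <- stats::setNames(as.character(f$v), keyOf(f$layer, f$u))

  nAligned1 <- sum(mapply(function(ly, u) u %in% nodeIds(net1, ly), f$layer, f$u))
  nAligned2 <- sum(mapply(function(ly, v) v %in% nodeIds(net2, ly), f$layer, f$v))
  ncv <- if (numNodes(net1) + numNodes(net2) == 0) 0 else
    (nAligned1 + nAligned2) / (numNodes(net1) + numNodes(net2))

  ie1 <- interEdges(net1); ie2 <- interEdges(net2)
  aligned1 <- keyOf(f$layer, f$u)
  ind1 <- ie1[keyOf(ie1$layer1, ie1$id1) %in% aligned1 &
                keyOf(ie1$layer2, ie1$id2) %in% aligned1, , drop = FALSE]
  aligned2 <- keyOf(f$layer, f$v)
  ind2 <- ie2[keyOf(ie2$layer1, ie2$id1) %in% aligned2 &
                keyOf(ie2$layer2, ie2$id2) %in% aligned2, , drop = FALSE]
  keys2 <- .interKey(ind2$layer1, ind2$id1, ind2$layer2, ind2$id2)
  if (nrow(ind1)) {
    fa <- unname(fMap[keyOf(ind1$layer1, ind1$id1)])
    fb <- unname(fMap[keyOf(ind1$layer2, ind1$id2)])
    ce <- .canonInter(ind1$layer1, fa, ind1$layer2, fb)
    conserved <- sum(.interKey(ce$layer1, ce$id1, ce$layer2, ce$id2) %in% keys2)
  } else conserved <- 0L
  denom <- nrow(ind1) + nrow(ind2) - conserved
  gs3 <- if (nrow(ind1) == 0 && nrow(ind2) == 0) 1 else
    if (denom == 0) 0 else conserved / denom
  list(ncv = ncv, gs3 = gs3, ncv_gs3 = .combineNcvGs3(ncv, gs3, combine))
}

# node correctness restricted to nodes incident to inter-layer edges
.interlayerFNC <- function(net1, net2, truth, mapping, combine = "harmonic") {
  incident <- function(net) {
    ie <- interEdges(net)
    unique(c(paste(ie$layer1, ie$id1, sep = "\t"),
             paste(ie$layer2, ie$id2, sep = "\t")))
  }
  inc1 <- incident(net1); inc2 <- incident(net2)
  restrict <- function(df) {
    keep <- paste(df$layer, df$u, sep = "\t") %in% inc1 |
      paste(df$layer, df$v, sep = "\t") %in% inc2
    df[keep, , drop = FALSE]
  }
  Mi <- restrict(truth)
  if (nrow(Mi) == 0) return(NA_real_)
  Ni <- restrict(mapping)
  nodeCorrectness(data.frame(u = paste(Mi$layer, Mi$u), v = paste(Mi$layer, Mi$v)),
                  data.frame(u = paste(Ni$layer, Ni$u), v = paste(Ni$layer, Ni$v)),
                  combine = combine)$f_nc
}

#' Evaluate an alignment against the true node mapping
#'
#' Computes the full quality report: per-layer P-NC / R-NC / F-NC and
#' NCV / GS3 / NCV-GS3 over intra-layer edges, their multilayer averages, the
#' pooled inter-layer NCV-GS3, and the inter-layer F-NC (node correctness
#' restricted to nodes incident to inter-layer edges).
#'
#' @param net1,net2 The two [MultilayerNetwork-class] objects.
#' @param truth True mapping `data.frame(layer, u, v)` (see
#'   [identityTrueMapping()]).
#' @param mapping Alignment mapping `data.frame(layer, u, v)` (see
#'   [communitiesToAlignment()]).
#' @param fCombine F-NC combination rule: `"harmonic"` or `"arithmetic"`.
#' @param ncvCombine NCV-GS3 combination rule: `"geometric"` or
#'   `"arithmetic"`.
#' @return An [EvaluationReport-class].
#' @examples
#' net <- generateMultilayer(10, 2, 14, seed = 1)
#' g <- buildMultilayerAlignmentGraph(net, net, identitySeeds(net))
#' com <- detectCommunities(g, seed = 42)
#' evaluateAlignment(net, net, identityTrueMapping(net),
#'                   communitiesToAlignment(com, minSize = 1))
#' @export
evaluateAlignment <- function(net1, net2, truth, mapping,
                              fCombine = c("harmonic", "arithmetic"),
                              ncvCombine = c("geometric", "arithmetic")) {
  fCombine <- match.arg(fCombine)
  ncvCombine <- match.arg(ncvCombine)
  layers <- intersect(layerNames(net1), layerNames(net2))
  if (length(layers) == 0) stop("the two networks share no layers")
  rows <- lapply(layers, function(ly) {
    M <- truth[truth$layer == ly, , drop = FALSE]
    N <- mapping[mapping$layer == ly, , drop = FALSE]
    nc <- nodeCorrectness(M, N, combine = fCombine)
    eg <- ncvGs3Layer(net1, net2, ly, N, combine = ncvCombine)
    data.frame(layer = ly, p_nc = nc$p_nc, r_nc = nc$r_nc, f_nc = nc$f_nc,
               ncv = eg$ncv, gs3 = eg$gs3, ncv_gs3 = eg$ncv_gs3,
               stringsAsFactors = FALSE)
  })
  perLayer <- do.call(rbind, rows)
  inter <- interlayerNcvGs3(net1, net2, mapping, combine = ncvCombine)
  new("EvaluationReport",
      perLayer = perLayer,
      multilayerFNC = multilayerFNC(perLayer$f_nc),
      multilayerNcvGs3 = multilayerNcvGs3(perLayer$ncv_gs3),
      interlayerNcvGs3 = inter$ncv_gs3,
      interlayerFNC = .interlayerFNC(net1, net2, truth, mapping,
                                     combine = fCombine))
}
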