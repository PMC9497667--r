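## Synthetic multilayer benchmark generator and noise degradation.

#' Edge counts of the ten benchmark networks
#'
#' The benchmark consists of ten two-layer, 30-node networks N1..N10 with
#' these total edge counts.
#' @export
benchmarkEdgeCounts <- c(N1 = 90, N2 = 96, N3 = 84, N4 = 78, N5 = 95,
                         N6 = 88, N7 = 93, N8 = 83, N9 = 94, N10 = 96)

#' Generate a random multilayer network
#'
#' Draws a uniform random multilayer network: nodes are split evenly across
#' layers, `round(interFraction * nEdges)` edges are inter-layer (split evenly
#' across layer pairs, remainder to the first pair) and the rest intra-layer
#' (split evenly across layers, remainder to the first layer). Within each
#' class, edges are drawn uniformly without replacement, i.e. each layer is an
#' Erdos-Renyi G(n, m) graph and each layer pair a uniform bipartite-style
#' cross-layer edge sample. Deterministic given `seed`.
#'
#' @param nNodes Total node count; must be divisible by `nLayers`.
#' @param nLayers Number of layers.
#' @param nEdges Total edge count (intra + inter).
#' @param interFraction Fraction of edges placed between layers (default 0.2).
#' @param seed Integer RNG seed.
#' @param name Network name.
#' @return A [MultilayerNetwork-class].
#' @examples
#' net <- generateMultilayer(30, 2, 90, seed = 1)
#' numEdges(net, "inter")  # round(0.2 * 90) = 18
#' @export
generateMultilayer <- function(nNodes, nLayers, nEdges, interFraction = 0.2,
                               seed = 1L, name = "synthetic") {
  if (nNodes %% nLayers != 0)
    stop("nNodes must be divisible by nLayers")
  if (interFraction < 0 || interFraction > 1)
    stop("interFraction must lie in [0, 1]")
  nPer <- nNodes %/% nLayers
  layers <- sprintf("L%d", seq_len(nLayers))
  ids <- sprintf("n%02d", seq_len(nPer))

  nInter <- round(interFraction * nEdges)
  nIntra <- nEdges - nInter
  nPairs <- if (nLayers >= 2) choose(nLayers, 2) else 0L
  if (nInter > 0 && nPairs == 0)
    stop("inter-layer edges requested but fewer than two layers")

  # even split with remainder to the first layer / first layer pair
  intraQuota <- rep(nIntra %/% max(nLayers, 1L), nLayers)
  if (nLayers > 0 && nIntra %% nLayers > 0)
    intraQuota[1] <- intraQuota[1] + nIntra %% nLayers
  interQuota <- if (nPairs > 0) rep(nInter %/% nPairs, nPairs) else integer(0)
  if (nPairs > 0 && nInter %% nPairs > 0)
    interQuota[1] <- interQuota[1] + nInter %% nPairs

  maxIntra <- choose(nPer, 2)
  if (any(intraQuota > maxIntra))
    stop(sprintf("infeasible: %d intra-layer edges requested in a layer of %d nodes",
                 max(intraQuota), nPer))
  if (length(interQuota) && any(interQuota > nPer^2))
    stop("infeasible: more inter-layer edges than node pairs for a layer pair")

  .withSeed(seed, {
    allIntraPairs <- if (nPer >= 2) t(utils::combn(ids, 2)) else
      matrix(character(0), ncol = 2)
    intraList <- stats::setNames(vector("list", nLayers), layers)
    for (k in seq_len(nLayers)) {
      m <- intraQuota[k]
      pick <- if (m > 0) sort(sample.int(nrow(allIntraPairs), m)) else integer(0)
      intraList[[layers[k]]] <- data.frame(
        from = allIntraPairs[pick, 1], to = allIntraPairs[pick, 2],
        stringsAsFactors = FALSE)
    }
    interRows <- list()
    if (nPairs > 0) {
      pairIdx <- utils::combn(nLayers, 2)
      for (p in seq_len(ncol(pairIdx))) {
        m <- interQuota[p]
        if (m == 0) next
        k <- pairIdx[1, p]; h <- pairIdx[2, p]
        pick <- sort(sample.int(nPer^2, m))
        i <- (pick - 1L) %/% nPer + 1L
        j <- (pick - 1L) %% nPer + 1L
        interRows[[length(interRows) + 1L]] <- data.frame(
          layer1 = layers[k], id1 = ids[i], layer2 = layers[h], id2 = ids[j],
          stringsAsFactors = FALSE)
      }
    }
    MultilayerNetwork(
      name = name, layers = layers,
      nodes = stats::setNames(rep(list(ids), nLayers), layers),
      intraEdges = intraList,
      interEdges = if (length(interRows)) do.call(rbind, interRows) else NULL)
  })
}

#' Degrade a network by random edge removal
#'
#' Removes `floor(noise * |E|)` edges drawn uniformly at random from the union
#' of intra- and inter-layer edges. Node sets are unchanged, so nodes may
#' become isolated. Deterministic given `seed`.
#'
#' @param net A [MultilayerNetwork-class].
#' @param noise Fraction of edges to remove, in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return A degraded copy of `net`.
#' @examples
#' net <- generateMultilayer(30, 2, 90, seed = 1)
#' numEdges(degradeNetwork(net, 0.25, seed = 2))  # 90 - floor(22.5) = 68
#' @export
degradeNetwork <- function(net, noise, seed = 1L) {
  stopifnot(is(net, "MultilayerNetwork"))
  if (noise < 0 || noise > 1) stop("noise must lie in [0, 1]")
  total <- numEdges(net)
  k <- floor(noise * total)
  if (k == 0) return(net)
  # enumerate edges: intra edges per layer first, then inter edges
  counts <- vapply(net@layers, function(ly) nrow(net@intraEdges[[ly]]),
                   integer(1))
  drop <- .withSeed(seed, sort(sample.int(total, k)))
  intraList <- net@intraEdges
  offset <- 0L
  for (ly in net@layers) {
    n <- counts[[ly]]
    local <- drop[drop > offset & drop <= offset + n] - offset
    if (length(local))
      intraList[[ly]] <- intraList[[ly]][-local, , drop = FALSE]
    offset <- offset + n
  }
  inter <- net@interEdges
  localInter <- drop[drop > offset] - offset
  if (length(localInter))
    inter <- inter[-localInter, , drop = FALSE]
  MultilayerNetwork(name = net@name, layers = net@layers, nodes = net@nodes,
                    intraEdges = intraList, interEdges = inter)
}

#' Identity true mapping of a network onto itself
#'
#' For the self-alignment benchmark the true node mapping is known: each node
#' maps to itself in every layer.
#'
#' @param net A [MultilayerNetwork-class].
#' @return `data.frame(layer, u, v)` with `u == v`, one row per node.
#' @export
identityTrueMapping <- function(net) {
  stopifnot(is(net, "MultilayerNetwork"))
  rows <- lapply(net@layers, function(ly) {
    ids <- net@nodes[[ly]]
    if (length(ids) == 0) return(NULL)
    data.frame(layer = ly, u = ids, v = ids, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(.df0("layer", "u", "v"))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Identity seed map of a network onto itself
#'
#' One entry `(layer, v, v, 1.0)` per node: the seeds used when a network is
#' aligned with itself or with a degraded copy of itself.
#'
#' @param net A [MultilayerNetwork-class].
#' @return A [SeedMap-class].
#' @export
identitySeeds <- function(net) {
  m <- identityTrueMapping(net)
  if (nrow(m) == 0) return(SeedMap())
  SeedMap(data.frame(layer = m$layer, id1 = m$u, id2 = m$v, similarity = 1.0,
                     stringsAsFactors = FALSE))
}

#' Write the full synthetic benchmark suite to disk
#'
#' Generates the ten benchmark networks (two layers, 30 nodes, edge counts
#' from [benchmarkEdgeCounts]), degrades each at the noise levels
#' 5/10/15/20/25%, writes identity seed files, and emits a manifest TSV
#' (`name, file, layers, nodes, edges, noise, seed`) listing every file.
#' Per-network RNG streams are derived from `seed` via [stableSeed()], so the
#' suite is bit-reproducible.
#'
#' @param outDir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param noiseLevels Noise levels for the degraded copies.
#' @param interFraction Inter-layer edge fraction passed to the generator.
#' @return Invisibly, the manifest `data.frame`.
#' @export
makeBenchmarkSuite <- function(outDir, seed = 1L,
                               noiseLevels = c(0.05, 0.10, 0.15, 0.20, 0.25),
                               interFraction = 0.2) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  addRow <- function(name, file, net, noise, s) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, file = file, layers = length(layerNames(net)),
      nodes = numNodes(net), edges = numEdges(net), noise = noise, seed = s,
      stringsAsFactors = FALSE)
  }
  for (nm in names(benchmarkEdgeCounts)) {
    s <- stableSeed(seed, nm, 0)
    net <- generateMultilayer(30, 2, benchmarkEdgeCounts[[nm]],
                              interFraction = interFraction, seed = s, name = nm)
    f <- file.path(outDir, paste0(nm, ".tsv"))
    writeMultilayerEdgelist(net, f)
    addRow(nm, basename(f), net, 0, s)
    sf <- file.path(outDir, paste0(nm, "_seeds.tsv"))
    writeSeedMap(identitySeeds(net), sf)
    for (p in noiseLevels) {
      sp <- stableSeed(seed, nm, p)
      noisy <- degradeNetwork(net, p, seed = sp)
      fn <- file.path(outDir, sprintf("%s_noise%02d.tsv", nm, round(100 * p)))
      writeMultilayerEdgelist(noisy, fn)
      addRow(nm, basename(fn), noisy, p, sp)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
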