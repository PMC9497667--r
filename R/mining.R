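## Community mining on the multilayer alignment graph. Because pair nodes are
## distinct per layer, the multilayer alignment graph is a simple weighted
## graph over (layer, pair) vertices, so mining reduces to weighted community
## detection on the flattened graph.

.pairKey <- function(layer, u, v) paste(layer, u, v, sep = "\t")

# flatten an alignment graph into a weighted undirected igraph
.flattenAlignmentGraph <- function(g) {
  pn <- g@pairNodes
  keys <- .pairKey(pn$layer, pn$u, pn$v)
  ed <- g@edges
  edges <- data.frame(from = .pairKey(ed$layer1, ed$u1, ed$v1),
                      to = .pairKey(ed$layer2, ed$u2, ed$v2),
                      weight = ed$weight, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = keys))
}

# backend registry: name -> function(igraph, seed) -> integer membership,
# or NA for names reserved but not implemented
.backendRegistry <- new.env(parent = emptyenv())

.registerBackend <- function(name, fn) assign(name, fn, envir = .backendRegistry)

.registerBackend("infomap", function(graph, seed, trials = 10L) {
  .withSeed(seed, igraph::membership(
    igraph::cluster_infomap(graph, e.weights = igraph::E(graph)$weight,
                            nb.trials = trials)))
})

.registerBackend("louvain", function(graph, seed, ...) {
  .withSeed(seed, igraph::membership(
    igraph::cluster_louvain(graph, weights = igraph::E(graph)$weight)))
})

# offered by the method's pluggable-miner design but not implemented here
.RESERVED_BACKENDS <- c("genlouvain", "abacus", "clique_percolation", "mdlp")

#' List registered community-detection backends
#'
#' @return Character vector of backend names accepted by [detectCommunities()].
#' @export
miningBackends <- function() sort(ls(.backendRegistry))

#' Mine communities on the alignment graph
#'
#' Partitions the pair nodes of a [MultilayerAlignmentGraph-class] into
#' communities — the candidate local regions of similarity — by running a
#' weighted community-detection backend on the flattened graph. The default
#' backend is Infomap (two-level, undirected, weighted); `louvain` (weighted
#' modularity optimisation) is also registered. The miner is pluggable:
#' `genlouvain`, `abacus`, `clique_percolation` and `mdlp` are reserved names
#' that raise a not-implemented error.
#'
#' @param g A [MultilayerAlignmentGraph-class].
#' @param method Backend name; see [miningBackends()].
#' @param seed Integer RNG seed; the partition is deterministic given
#'   `(method, seed)`.
#' @param trials Number of Infomap optimisation trials.
#' @return A [CommunitySet-class]; empty if `g` has no pair nodes.
#' @examples
#' net <- generateMultilayer(10, 2, 14, seed = 1)
#' g <- buildMultilayerAlignmentGraph(net, net, identitySeeds(net))
#' detectCommunities(g, seed = 42)
#' @export
detectCommunities <- function(g, method = "infomap", seed = 42L, trials = 10L) {
  stopifnot(is(g, "MultilayerAlignmentGraph"))
  if (method %in% .RESERVED_BACKENDS)
    stop(sprintf("backend '%s' is reserved but not implemented; available: %s",
                 method, paste(miningBackends(), collapse = ", ")))
  if (!method %in% miningBackends())
    stop(sprintf("unknown mining backend '%s'; available: %s",
                 method, paste(miningBackends(), collapse = ", ")))
  pn <- g@pairNodes
  if (nrow(pn) == 0)
    return(new("CommunitySet",
               membership = data.frame(layer = character(0), u = character(0),
                                       v = character(0), community = integer(0),
                                       stringsAsFactors = FALSE),
               method = method, seed = as.integer(seed)))
  graph <- .flattenAlignmentGraph(g)
  fn <- get(method, envir = .backendRegistry)
  memb <- if (identical(method, "infomap")) fn(graph, seed, trials) else fn(graph, seed)
  keys <- .pairKey(pn$layer, pn$u, pn$v)
  comm <- as.integer(memb[keys])
  # renumber communities in first-appearance order for stable output
  comm <- as.integer(factor(comm, levels = unique(comm)))
  out <- data.frame(layer = pn$layer, u = pn$u, v = pn$v, community = comm,
                    stringsAsFactors = FALSE)
  new("CommunitySet", membership = out, method = method, seed = as.integer(seed))
}

#' Community sizes of a CommunitySet
#'
#' @param communities A [CommunitySet-class].
#' @return Named integer vector of community sizes, indexed by community id.
#' @export
communitySizes <- function(communities) {
  stopifnot(is(communities, "CommunitySet"))
  m <- communities@membership
  if (nrow(m) == 0) return(stats::setNames(integer(0), character(0)))
  table(m$community)
}

#' Convert mined communities into a local alignment mapping
#'
#' The local alignment is the union of all communities of at least `minSize`
#' pair nodes, projected to `(layer, u, v)` node pairs. The default
#' `minSize = 2` drops singleton communities: a local region of similarity of
#' one node is vacuous.
#'
#' @param communities A [CommunitySet-class].
#' @param minSize Minimum community size retained (>= 1).
#' @return `data.frame(layer, u, v)`: the partial node mapping, one-to-one
#'   within each layer.
#' @export
communitiesToAlignment <- function(communities, minSize = 2L) {
  stopifnot(is(communities, "CommunitySet"), minSize >= 1)
  m <- communities@membership
  if (nrow(m) == 0) return(.df0("layer", "u", "v"))
  keep <- names(which(table(m$community) >= minSize))
  out <- m[m$community %in% as.integer(keep), c("layer", "u", "v"), drop = FALSE]
  out <- out[order(out$layer, out$u, out$v), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.KIND_STRINGS <- c(HOM_MATCH = "homogeneous match",
                   HOM_MISMATCH = "homogeneous mismatch",
                   HOM_GAP = "homogeneous gap",
                   HET_MATCH = "heterogeneous match",
                   HET_MISMATCH = "heterogeneous mismatch")

.COMMUNITIES_HEADER <- "#multiloal-communities v1"

#' Write mined communities to TSV
#'
#' For each community (sorted by id): member lines
#' `C<id><TAB>layer<TAB>u|v` and internal-edge lines
#' `C<id><TAB>layer_p:u1|v1<TAB>layer_q:u2|v2<TAB>weight<TAB>kind-string`,
#' where the kind string spells out the edge class (e.g. "homogeneous match").
#' Only edges with both endpoints inside the community are listed. Lines are
#' sorted, so output is byte-deterministic.
#'
#' @param communities A [CommunitySet-class] mined from `g`.
#' @param g The [MultilayerAlignmentGraph-class] the communities came from.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [readCommunities()] for the inverse.
#' @export
writeCommunities <- function(communities, g, path) {
  stopifnot(is(communities, "CommunitySet"),
            is(g, "MultilayerAlignmentGraph"))
  m <- communities@membership
  ed <- g@edges
  commOf <- stats::setNames(m$community, .pairKey(m$layer, m$u, m$v))
  lines <- character()
  if (nrow(m) > 0) {
    c1 <- commOf[.pairKey(ed$layer1, ed$u1, ed$v1)]
    c2 <- commOf[.pairKey(ed$layer2, ed$u2, ed$v2)]
    internal <- !is.na(c1) & !is.na(c2) & c1 == c2
    for (cid in sort(unique(m$community))) {
      sub <- m[m$community == cid, , drop = FALSE]
      memberLines <- sort(paste(paste0("C", cid), sub$layer,
                                paste(sub$u, sub$v, sep = "|"), sep = "\t"))
      es <- ed[internal & c1 == cid, , drop = FALSE]
      edgeLines <- if (nrow(es)) sort(paste(
        paste0("C", cid),
        paste0(es$layer1, ":", es$u1, "|", es$v1),
        paste0(es$layer2, ":", es$u2, "|", es$v2),
        format(es$weight, trim = TRUE),
        unname(.KIND_STRINGS[es$kind]), sep = "\t")) else character()
      lines <- c(lines, memberLines, edgeLines)
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(.COMMUNITIES_HEADER, lines), con, sep = "\n")
  invisible(path)
}

#' Read a communities file back into tables
#'
#' Parses the output of [writeCommunities()] into the member and internal-edge
#' tables, so written results can be re-loaded (e.g. for evaluation).
#'
#' @param path Path to a communities TSV.
#' @return List with `membership` (`data.frame(layer, u, v, community)`) and
#'   `edges` (`data.frame(community, layer1, u1, v1, layer2, u2, v2, weight,
#'   kind)`).
#' @export
readCommunities <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || trimws(lines[1]) != .COMMUNITIES_HEADER)
    stop(sprintf("%s: missing or unknown header directive (expected '%s')",
                 path, .COMMUNITIES_HEADER))
  memb <- list(); edges <- list()
  kindOf <- stats::setNames(names(.KIND_STRINGS), .KIND_STRINGS)
  splitPair <- function(s) strsplit(s, "|", fixed = TRUE)[[1]]
  for (i in seq_along(lines)[-1]) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    cid <- as.integer(sub("^C", "", f[1]))
    if (length(f) == 3) {
      uv <- splitPair(f[3])
      memb[[length(memb) + 1L]] <- data.frame(
        layer = f[2], u = uv[1], v = uv[2], community = cid,
        stringsAsFactors = FALSE)
    } else if (length(f) == 5) {
      p1 <- strsplit(f[2], ":", fixed = TRUE)[[1]]
      p2 <- strsplit(f[3], ":", fixed = TRUE)[[1]]
      uv1 <- splitPair(p1[2]); uv2 <- splitPair(p2[2])
      edges[[length(edges) + 1L]] <- data.frame(
        community = cid, layer1 = p1[1], u1 = uv1[1], v1 = uv1[2],
        layer2 = p2[1], u2 = uv2[1], v2 = uv2[2],
        weight = as.numeric(f[4]), kind = unname(kindOf[f[5]]),
        stringsAsFactors = FALSE)
    } else {
      stop(sprintf("%s:%d: wrong column count (%d)", path, i, length(f)))
    }
  }
  list(
    membership = if (length(memb)) do.call(rbind, memb) else
      data.frame(layer = character(0), u = character(0), v = character(0),
                 community = integer(0), stringsAsFactors = FALSE),
    edges = if (length(edges)) do.call(rbind, edges) else NULL)
}
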