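## File I/O for the multilayer edge-list and seed-map TSV dialects.

.EDGELIST_HEADER <- "#multiloal-edgelist v1"
.SEEDS_HEADER <- "#multiloal-seeds v1"

#' Read a multilayer network from an edge-list file
#'
#' Parses the tab-separated multilayer edge-list dialect: a header line
#' `#multiloal-edgelist v1`, then one record per line. A 4-column line
#' `layer_u<TAB>id_u<TAB>layer_v<TAB>id_v` declares an edge (intra-layer iff
#' `layer_u == layer_v`); a 2-column line `layer<TAB>id` declares a node
#' (used to carry isolated nodes); a 5th column, if present, is an input edge
#' weight, which is parsed and ignored with a warning (alignment uses only
#' topology). Lines starting with `#` are comments. Duplicate edge lines
#' collapse to one edge with a warning; malformed lines and self-loops raise
#' errors naming the offending line.
#'
#' @param path Path to the edge-list file.
#' @param name Name for the resulting network (default: file base name).
#' @return A [MultilayerNetwork-class] whose layer order is first-appearance
#'   order in the file.
#' @seealso [writeMultilayerEdgelist()] for the inverse.
#' @export
readMultilayerEdgelist <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || trimws(lines[1]) != .EDGELIST_HEADER)
    stop(sprintf("%s: missing or unknown header directive (expected '%s')",
                 path, .EDGELIST_HEADER))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))

  layers <- character()
  nodes <- list()
  intra <- list()
  interRows <- list()
  seenIntra <- new.env(parent = emptyenv())
  seenInter <- new.env(parent = emptyenv())
  dupCount <- 0L
  weightSeen <- FALSE

  addLayer <- function(ly) {
    if (!ly %in% layers) {
      layers <<- c(layers, ly)
      nodes[[ly]] <<- character()
      intra[[ly]] <<- list()
    }
  }
  addNode <- function(ly, id) {
    addLayer(ly)
    if (!id %in% nodes[[ly]]) nodes[[ly]] <<- c(nodes[[ly]], id)
  }

  for (i in seq_along(lines)[-1]) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) == 2) {
      if (any(!nzchar(f)))
        stop(sprintf("%s:%d: empty field in node line", path, i))
      addNode(f[1], f[2])
    } else if (length(f) %in% c(4L, 5L)) {
      if (any(!nzchar(f[1:4])))
        stop(sprintf("%s:%d: empty field in edge line", path, i))
      if (length(f) == 5L) weightSeen <- TRUE
      lu <- f[1]; u <- f[2]; lv <- f[3]; v <- f[4]
      if (lu == lv && u == v)
        stop(sprintf("%s:%d: self-loop edge (%s:%s)", path, i, lu, u))
      addNode(lu, u); addNode(lv, v)
      if (lu == lv) {
        key <- .intraKey(lu, min(u, v), max(u, v))
        if (exists(key, envir = seenIntra)) { dupCount <- dupCount + 1L; next }
        assign(key, TRUE, envir = seenIntra)
        intra[[lu]][[length(intra[[lu]]) + 1L]] <- c(min(u, v), max(u, v))
      } else {
        ce <- .canonInter(lu, u, lv, v)
        key <- .interKey(ce$layer1, ce$id1, ce$layer2, ce$id2)
        if (exists(key, envir = seenInter)) { dupCount <- dupCount + 1L; next }
        assign(key, TRUE, envir = seenInter)
        interRows[[length(interRows) + 1L]] <-
          c(ce$layer1, ce$id1, ce$layer2, ce$id2)
      }
    } else {
      stop(sprintf("%s:%d: wrong column count (%d); expected 2, 4 or 5 columns",
                   path, i, length(f)))
    }
  }
  if (dupCount > 0)
    warning(sprintf("%s: collapsed %d duplicate edge line(s)", path, dupCount))
  if (weightSeen)
    warning(sprintf("%s: 5th-column edge weights present; parsed and ignored", path))

  intraDf <- lapply(intra, function(rows) {
    if (length(rows) == 0) return(.df0("from", "to"))
    m <- do.call(rbind, rows)
    data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE)
  })
  interDf <- if (length(interRows) == 0) NULL else {
    m <- do.call(rbind, interRows)
    data.frame(layer1 = m[, 1], id1 = m[, 2], layer2 = m[, 3], id2 = m[, 4],
               stringsAsFactors = FALSE)
  }
  MultilayerNetwork(name = name, layers = layers, nodes = nodes,
                    intraEdges = intraDf, interEdges = interDf)
}

#' Write a multilayer network to an edge-list file
#'
#' Deterministic inverse of [readMultilayerEdgelist()]: emits the header, one
#' node line per declared node, and one line per edge sorted lexicographically
#' by `(layer_u, id_u, layer_v, id_v)`. Writing the same network twice yields
#' byte-identical files, and a read/write round trip reproduces the network
#' exactly (including isolated nodes).
#'
#' @param net A [MultilayerNetwork-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMultilayerEdgelist <- function(net, path) {
  stopifnot(is(net, "MultilayerNetwork"))
  nodeLines <- character()
  for (ly in sort(net@layers))
    nodeLines <- c(nodeLines, paste(ly, net@nodes[[ly]], sep = "\t"))
  edgeRows <- list()
  for (ly in net@layers) {
    e <- net@intraEdges[[ly]]
    if (nrow(e)) edgeRows[[length(edgeRows) + 1L]] <-
        data.frame(l1 = ly, i1 = e$from, l2 = ly, i2 = e$to,
                   stringsAsFactors = FALSE)
  }
  ie <- net@interEdges
  if (nrow(ie)) edgeRows[[length(edgeRows) + 1L]] <-
      data.frame(l1 = ie$layer1, i1 = ie$id1, l2 = ie$layer2, i2 = ie$id2,
                 stringsAsFactors = FALSE)
  edgeLines <- character()
  if (length(edgeRows)) {
    ed <- do.call(rbind, edgeRows)
    ed <- ed[order(ed$l1, ed$i1, ed$l2, ed$i2), , drop = FALSE]
    edgeLines <- paste(ed$l1, ed$i1, ed$l2, ed$i2, sep = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(.EDGELIST_HEADER, nodeLines, edgeLines), con, sep = "\n")
  invisible(path)
}

#' Read a seed-similarity map and validate it against two networks
#'
#' Parses the seed-map TSV dialect (header `#multiloal-seeds v1`, then lines
#' `layer<TAB>id_in_net1<TAB>id_in_net2<TAB>similarity`) and checks every
#' entry: the layer must exist in both networks, `id1` in `net1`'s layer node
#' set, `id2` in `net2`'s, and the similarity must parse to a real in `[0,1]`.
#'
#' @param path Path to the seed file.
#' @param net1,net2 The two [MultilayerNetwork-class] objects the seeds pair.
#' @return A [SeedMap-class].
#' @seealso [writeSeedMap()], [identitySeeds()].
#' @export
readSeedMap <- function(path, net1, net2) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || trimws(lines[1]) != .SEEDS_HEADER)
    stop(sprintf("%s: missing or unknown header directive (expected '%s')",
                 path, .SEEDS_HEADER))
  rows <- list()
  for (i in seq_along(lines)[-1]) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 4)
      stop(sprintf("%s:%d: wrong column count (%d); expected 4", path, i, length(f)))
    sim <- suppressWarnings(as.numeric(f[4]))
    if (is.na(sim) || sim < 0 || sim > 1)
      stop(sprintf("%s:%d: similarity '%s' is not a real in [0,1]", path, i, f[4]))
    ly <- f[1]
    if (!ly %in% layerNames(net1) || !ly %in% layerNames(net2))
      stop(sprintf("%s:%d: layer '%s' is not present in both networks", path, i, ly))
    if (!f[2] %in% nodeIds(net1, ly))
      stop(sprintf("%s:%d: node '%s' not in network 1 layer '%s'", path, i, f[2], ly))
    if (!f[3] %in% nodeIds(net2, ly))
      stop(sprintf("%s:%d: node '%s' not in network 2 layer '%s'", path, i, f[3], ly))
    rows[[length(rows) + 1L]] <- data.frame(
      layer = ly, id1 = f[2], id2 = f[3], similarity = sim,
      stringsAsFactors = FALSE)
  }
  SeedMap(if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Write a seed map to the seed TSV dialect
#'
#' @param seeds A [SeedMap-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeSeedMap <- function(seeds, path) {
  stopifnot(is(seeds, "SeedMap"))
  e <- seeds@entries
  e <- e[order(e$layer, e$id1, e$id2), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(.SEEDS_HEADER,
               if (nrow(e)) paste(e$layer, e$id1, e$id2,
                                  format(e$similarity, trim = TRUE), sep = "\t")),
             con, sep = "\n")
  invisible(path)
}
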