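## End-to-end orchestration: one-shot alignment and the noise-degradation
## proof-of-concept experiment.

.msg <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Run a complete local alignment
#'
#' Builds the multilayer alignment graph from two networks and a seed map,
#' mines communities, converts them into a local alignment mapping, and
#' (optionally) writes the alignment-graph and community files.
#'
#' @param net1,net2 [MultilayerNetwork-class] objects or paths to edge-list
#'   files.
#' @param seeds A [SeedMap-class] or a path to a seed TSV (validated against
#'   the two networks).
#' @param cfg A [ScoringConfig-class].
#' @param method Mining backend name (see [miningBackends()]).
#' @param minSize Minimum community size retained in the mapping.
#' @param seed Integer seed for the miner.
#' @param outDir If non-`NULL`, directory to write `alignment_graph.tsv` and
#'   `communities.tsv` into.
#' @param verbose Log progress counts via `message()`.
#' @return List with elements `graph` ([MultilayerAlignmentGraph-class]),
#'   `communities` ([CommunitySet-class]), `mapping`
#'   (`data.frame(layer, u, v)`) and `files` (paths written, or `NULL`).
#' @examples
#' net <- generateMultilayer(10, 2, 14, seed = 1)
#' res <- runAlignment(net, net, identitySeeds(net), seed = 42)
#' nrow(res$mapping)
#' @export
runAlignment <- function(net1, net2, seeds, cfg = ScoringConfig(),
                         method = "infomap", minSize = 2L, seed = 42L,
                         outDir = NULL, verbose = FALSE) {
  if (is.character(net1)) net1 <- readMultilayerEdgelist(net1)
  if (is.character(net2)) net2 <- readMultilayerEdgelist(net2)
  if (is.character(seeds)) seeds <- readSeedMap(seeds, net1, net2)
  g <- buildMultilayerAlignmentGraph(net1, net2, seeds, cfg)
  kinds <- table(factor(g@edges$kind, levels = .EDGE_KINDS))
  .msg(verbose, "alignment graph: %d pair nodes, %d edges (%s)",
       nrow(g@pairNodes), nrow(g@edges),
       paste(sprintf("%s=%d", names(kinds), as.integer(kinds)), collapse = " "))
  com <- detectCommunities(g, method = method, seed = seed)
  .msg(verbose, "mining (%s): %d communities", method, length(communitySizes(com)))
  mapping <- communitiesToAlignment(com, minSize = minSize)
  files <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- c(graph = file.path(outDir, "alignment_graph.tsv"),
               communities = file.path(outDir, "communities.tsv"))
    writeAlignmentGraph(g, files[["graph"]])
    writeCommunities(com, g, files[["communities"]])
  }
  list(graph = g, communities = com, mapping = mapping, files = files)
}

#' Run the noise-degradation proof-of-concept experiment
#'
#' For each benchmark network (two layers, 30 nodes, edge counts from
#' `edgeCounts`) and each noise level, degrades the network by random edge
#' removal, aligns the original against the degraded copy with identity seeds,
#' mines communities, and scores the alignment against the identity true
#' mapping. The default grid (10 networks x 6 noise levels x 1 method) records
#' 60 alignment runs.
#'
#' @param masterSeed Master integer seed; all per-run streams derive from it
#'   via [stableSeed()].
#' @param edgeCounts Named vector of total edge counts per network (default
#'   [benchmarkEdgeCounts]).
#' @param noiseLevels Noise levels; 0 is the self-alignment condition.
#' @param methods Mining backend names to run.
#' @param interFraction Inter-layer edge fraction for the generator.
#' @param cfg A [ScoringConfig-class].
#' @param minSize Minimum community size retained in the mapping.
#' @param verbose Log per-run progress.
#' @return `data.frame` with one row per run: `network, noise, method,
#'   multilayer_ncv_gs3, multilayer_f_nc, interlayer_ncv_gs3, interlayer_f_nc,
#'   n_communities, status`. Failed runs are kept with `status = "error"` and
#'   `NA` scores.
#' @seealso [experimentSummary()] for per-network mean/sd tables.
#' @export
runExperiment <- function(masterSeed = 1L,
                          edgeCounts = benchmarkEdgeCounts,
                          noiseLevels = c(0, 0.05, 0.10, 0.15, 0.20, 0.25),
                          methods = "infomap",
                          interFraction = 0.2,
                          cfg = ScoringConfig(),
                          minSize = 2L,
                          verbose = FALSE) {
  if (any(noiseLevels < 0 | noiseLevels > 1))
    stop("noise levels must lie in [0, 1]")
  if (is.null(names(edgeCounts)))
    names(edgeCounts) <- sprintf("N%d", seq_along(edgeCounts))
  rows <- list()
  for (nm in names(edgeCounts)) {
    net <- generateMultilayer(30, 2, edgeCounts[[nm]],
                              interFraction = interFraction,
                              seed = stableSeed(masterSeed, nm, 0),
                              name = nm)
    truth <- identityTrueMapping(net)
    seeds <- identitySeeds(net)
    for (p in noiseLevels) {
      noisy <- if (p == 0) net else
        degradeNetwork(net, p, seed = stableSeed(masterSeed, nm, p))
      for (method in methods) {
        res <- tryCatch({
          al <- runAlignment(net, noisy, seeds, cfg = cfg, method = method,
                             minSize = minSize,
                             seed = stableSeed(masterSeed, nm, p, method))
          rep <- evaluateAlignment(net, noisy, truth, al$mapping)
          data.frame(network = nm, noise = p, method = method,
                     multilayer_ncv_gs3 = rep@multilayerNcvGs3,
                     multilayer_f_nc = rep@multilayerFNC,
                     interlayer_ncv_gs3 = rep@interlayerNcvGs3,
                     interlayer_f_nc = rep@interlayerFNC,
                     n_communities = length(communitySizes(al$communities)),
                     status = "ok", stringsAsFactors = FALSE)
        }, error = function(e) {
          warning(sprintf("run %s/noise=%g/%s failed: %s",
                          nm, p, method, conditionMessage(e)))
          data.frame(network = nm, noise = p, method = method,
                     multilayer_ncv_gs3 = NA_real_, multilayer_f_nc = NA_real_,
                     interlayer_ncv_gs3 = NA_real_, interlayer_f_nc = NA_real_,
                     n_communities = NA_integer_,
                     status = "error", stringsAsFactors = FALSE)
        })
        .msg(verbose, "%s noise=%.2f %s: NCV-GS3=%.3f F-NC=%.3f",
             nm, p, method, res$multilayer_ncv_gs3, res$multilayer_f_nc)
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise experiment results per network
#'
#' Collapses the per-run table of [runExperiment()] into per-network (and
#' per-method) mean and standard deviation of each score across noise levels.
#'
#' @param results Result `data.frame` from [runExperiment()].
#' @return `data.frame` with columns `network, method` and `<score>_mean`,
#'   `<score>_sd` for each of the four scores.
#' @export
experimentSummary <- function(results) {
  scores <- c("multilayer_ncv_gs3", "multilayer_f_nc",
              "interlayer_ncv_gs3", "interlayer_f_nc")
  ok <- results[results$status == "ok", , drop = FALSE]
  groups <- unique(ok[, c("network", "method")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- ok[ok$network == groups$network[i] & ok$method == groups$method[i], ]
    row <- data.frame(network = groups$network[i], method = groups$method[i],
                      stringsAsFactors = FALSE)
    for (s in scores) {
      row[[paste0(s, "_mean")]] <- mean(sub[[s]])
      row[[paste0(s, "_sd")]] <- stats::sd(sub[[s]])
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
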