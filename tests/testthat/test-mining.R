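# Community mining on the alignment graph and conversion to alignments.

# an alignment graph consisting of two 4-cliques of match edges joined by one
# weak gap edge, all within one layer
twoCliqueGraph <- function() {
  ids <- sprintf("p%d", 1:8)
  pn <- data.frame(layer = "L1", u = ids, v = ids, similarity = 1,
                   stringsAsFactors = FALSE)
  mkClique <- function(members) {
    pr <- t(combn(members, 2))
    data.frame(layer1 = "L1", u1 = pr[, 1], v1 = pr[, 1],
               layer2 = "L1", u2 = pr[, 2], v2 = pr[, 2],
               kind = "HOM_MATCH", weight = 1, stringsAsFactors = FALSE)
  }
  bridge <- data.frame(layer1 = "L1", u1 = "p4", v1 = "p4",
                       layer2 = "L1", u2 = "p5", v2 = "p5",
                       kind = "HOM_GAP", weight = 0.2, stringsAsFactors = FALSE)
  new("MultilayerAlignmentGraph", layers = "L1", pairNodes = pn,
      edges = rbind(mkClique(ids[1:4]), mkClique(ids[5:8]), bridge))
}

test_that("all backends split the two-clique instance as exhaustive modularity does", {
  g <- twoCliqueGraph()
  # independent oracle: best 2-partition by exhaustive weighted modularity
  ed <- data.frame(from = g@edges$u1, to = g@edges$u2,
                   weight = g@edges$weight, stringsAsFactors = FALSE)
  oracle <- bestTwoPartitionModularity(sprintf("p%d", 1:8), ed)
  expect_identical(unname(oracle$side), c(rep(TRUE, 4), rep(FALSE, 4)))

  for (method in miningBackends()) {
    com <- detectCommunities(g, method = method, seed = 5)
    m <- com@membership
    expect_identical(length(unique(m$community)), 2L, info = method)
    expect_identical(length(unique(m$community[m$u %in% sprintf("p%d", 1:4)])),
                     1L, info = method)
    expect_identical(length(unique(m$community[m$u %in% sprintf("p%d", 5:8)])),
                     1L, info = method)
  }
})

test_that("community detection yields a partition of all pair nodes", {
  net <- generateMultilayer(30, 2, 90, seed = 31)
  g <- buildMultilayerAlignmentGraph(net, net, identitySeeds(net))
  com <- detectCommunities(g, seed = 7)
  m <- com@membership
  expect_identical(nrow(m), nrow(g@pairNodes))
  expect_identical(sum(communitySizes(com)), nrow(g@pairNodes))
  expect_false(anyDuplicated(paste(m$layer, m$u, m$v)) > 0)
})

test_that("isolated pair nodes become singleton communities", {
  pn <- data.frame(layer = "L1", u = c("a", "b", "c"), v = c("a", "b", "c"),
                   similarity = 1, stringsAsFactors = FALSE)
  ed <- data.frame(layer1 = "L1", u1 = "a", v1 = "a",
                   layer2 = "L1", u2 = "b", v2 = "b",
                   kind = "HOM_MATCH", weight = 1, stringsAsFactors = FALSE)
  g <- new("MultilayerAlignmentGraph", layers = "L1", pairNodes = pn, edges = ed)
  com <- detectCommunities(g, seed = 1)
  m <- com@membership
  expect_identical(m$community[m$u == "c"],
                   setdiff(m$community, m$community[m$u != "c"]))
  expect_identical(unname(communitySizes(com)[as.character(m$community[m$u == "c"])]),
                   1L)
})

test_that("mining is deterministic given a seed and errors on unknown backends", {
  net <- generateMultilayer(30, 2, 96, seed = 33)
  noisy <- degradeNetwork(net, 0.15, seed = 34)
  g <- buildMultilayerAlignmentGraph(net, noisy, identitySeeds(net))
  a <- detectCommunities(g, seed = 99)
  b <- detectCommunities(g, seed = 99)
  expect_identical(a@membership, b@membership)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeCommunities(a, g, f1)
  writeCommunities(b, g, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_error(detectCommunities(g, method = "nope"), "unknown")
  expect_error(detectCommunities(g, method = "abacus"), "reserved")
})

test_that("communities convert to alignments by the min-size rule", {
  memb <- data.frame(
    layer = "L1",
    u = sprintf("u%d", 1:9), v = sprintf("v%d", 1:9),
    community = c(rep(1L, 5), rep(2L, 3), 3L),
    stringsAsFactors = FALSE)
  com <- new("CommunitySet", membership = memb, method = "infomap", seed = 1L)
  expect_identical(nrow(communitiesToAlignment(com, minSize = 2)), 8L)
  expect_identical(nrow(communitiesToAlignment(com, minSize = 1)), 9L)
  expect_identical(nrow(communitiesToAlignment(com, minSize = 4)), 5L)
  empty <- new("CommunitySet",
               membership = memb[0, ], method = "infomap", seed = 1L)
  expect_identical(nrow(communitiesToAlignment(empty)), 0L)
})

test_that("community files round-trip and use the spelled-out kind strings", {
  net <- generateMultilayer(20, 2, 40, seed = 35)
  noisy <- degradeNetwork(net, 0.2, seed = 36)
  g <- buildMultilayerAlignmentGraph(net, noisy, identitySeeds(net))
  com <- detectCommunities(g, seed = 3)
  f <- withr::local_tempfile()
  writeCommunities(com, g, f)
  back <- readCommunities(f)

  m1 <- com@membership[order(com@membership$layer, com@membership$u), ]
  m2 <- back$membership[order(back$membership$layer, back$membership$u), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_identical(m1, m2)
  if (!is.null(back$edges))
    expect_true(all(back$edges$kind %in%
                      c("HOM_MATCH", "HOM_MISMATCH", "HOM_GAP",
                        "HET_MATCH", "HET_MISMATCH")))
  # kind strings in the file itself are the spelled-out forms
  lines <- readLines(f)
  edgeLines <- lines[lengths(strsplit(lines, "\t")) == 5]
  if (length(edgeLines))
    expect_true(all(grepl("homogeneous|heterogeneous", edgeLines)))

  # a 2-member, 1-match-edge community writes 3 lines after the header
  pn <- data.frame(layer = "L1", u = c("a", "b"), v = c("a", "b"),
                   similarity = 1, stringsAsFactors = FALSE)
  ed <- data.frame(layer1 = "L1", u1 = "a", v1 = "a", layer2 = "L1",
                   u2 = "b", v2 = "b", kind = "HOM_MATCH", weight = 1,
                   stringsAsFactors = FALSE)
  g2 <- new("MultilayerAlignmentGraph", layers = "L1", pairNodes = pn, edges = ed)
  com2 <- detectCommunities(g2, seed = 1)
  f2 <- withr::local_tempfile()
  writeCommunities(com2, g2, f2)
  lines2 <- readLines(f2)
  expect_identical(length(lines2), 4L)
  expect_match(lines2[4], "homogeneous match")

  # empty community set writes header only
  gEmpty <- new("MultilayerAlignmentGraph", layers = character(0),
                pairNodes = pn[0, ], edges = ed[0, ])
  comEmpty <- detectCommunities(gEmpty, seed = 1)
  f3 <- withr::local_tempfile()
  writeCommunities(comEmpty, gEmpty, f3)
  expect_identical(readLines(f3), "#multiloal-communities v1")
})
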