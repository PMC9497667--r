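# Data model, validation and edge-list / seed-map file I/O.

test_that("edge-list files round-trip through write/read for generated networks", {
  for (s in c(1, 7, 23)) {
    net <- generateMultilayer(30, 2, 90, seed = s, name = "rt")
    f <- withr::local_tempfile(fileext = ".tsv")
    writeMultilayerEdgelist(net, f)
    back <- readMultilayerEdgelist(f, name = "rt")
    expect_identical(layerNames(back), layerNames(net))
    expect_identical(nodeIds(back), nodeIds(net))
    expect_identical(intraEdges(back), intraEdges(net))
    expect_identical(interEdges(back), interEdges(net))
  }
  # isolated nodes survive the round trip
  noisy <- degradeNetwork(generateMultilayer(30, 2, 90, seed = 1), 1, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMultilayerEdgelist(noisy, f)
  back <- readMultilayerEdgelist(f)
  expect_identical(nodeIds(back), nodeIds(noisy))
  expect_identical(numEdges(back), 0L)
})

test_that("writing the same network twice is byte-identical", {
  net <- generateMultilayer(20, 2, 40, seed = 3)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeMultilayerEdgelist(net, f1)
  writeMultilayerEdgelist(net, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a small edge-list parses to the declared structure", {
  f <- withr::local_tempfile()
  writeLines(c("#multiloal-edgelist v1",
               "L1\ta\tL1\tb",
               "L1\tb\tL2\tc"), f)
  net <- readMultilayerEdgelist(f)
  expect_identical(layerNames(net), c("L1", "L2"))
  expect_identical(numEdges(net, "intra"), 1L)
  expect_identical(numEdges(net, "inter"), 1L)
  # header-only file: empty network
  f2 <- withr::local_tempfile()
  writeLines("#multiloal-edgelist v1", f2)
  empty <- readMultilayerEdgelist(f2)
  expect_identical(length(layerNames(empty)), 0L)
  expect_identical(numNodes(empty), 0L)
  expect_identical(numEdges(empty), 0L)
})

test_that("malformed edge-list lines raise line-numbered errors", {
  writeTmp <- function(lines) {
    f <- tempfile()
    writeLines(lines, f)
    f
  }
  # wrong column count
  f <- writeTmp(c("#multiloal-edgelist v1", "L1\ta\tL1"))
  expect_error(readMultilayerEdgelist(f), ":2:.*column count")
  # self-loop
  f <- writeTmp(c("#multiloal-edgelist v1", "L1\ta\tL1\tb", "L1\tc\tL1\tc"))
  expect_error(readMultilayerEdgelist(f), ":3:.*self-loop")
  # unknown header directive
  f <- writeTmp(c("#some-other-format v9", "L1\ta\tL1\tb"))
  expect_error(readMultilayerEdgelist(f), "header")
  # missing file
  expect_error(readMultilayerEdgelist(tempfile()), "not found")
})

test_that("duplicate edge lines collapse with a warning; weights are ignored with a warning", {
  f <- tempfile()
  writeLines(c("#multiloal-edgelist v1",
               "L1\ta\tL1\tb",
               "L1\tb\tL1\ta"), f)
  expect_warning(net <- readMultilayerEdgelist(f), "duplicate")
  expect_identical(numEdges(net), 1L)

  f2 <- tempfile()
  writeLines(c("#multiloal-edgelist v1", "L1\ta\tL1\tb\t0.7"), f2)
  expect_warning(net2 <- readMultilayerEdgelist(f2), "weight")
  expect_identical(numEdges(net2), 1L)
})

test_that("validateNetwork reports each violation and is silent on valid input", {
  expect_identical(validateNetwork(generateMultilayer(30, 2, 90, seed = 5)),
                   character(0))
  base <- list(
    layers = c("L1", "L2"),
    nodes = list(L1 = c("a", "b"), L2 = c("x", "y")),
    intraEdges = list(L1 = data.frame(from = "a", to = "b"),
                      L2 = data.frame(from = character(0), to = character(0))),
    interEdges = data.frame(layer1 = "L1", id1 = "a", layer2 = "L2", id2 = "x"))
  expect_identical(validateNetwork(base), character(0))

  withinLayer <- base
  withinLayer$interEdges <- data.frame(layer1 = "L1", id1 = "a",
                                       layer2 = "L1", id2 = "b")
  v <- validateNetwork(withinLayer)
  expect_length(v, 1)
  expect_match(v, "within one layer")

  undeclared <- base
  undeclared$intraEdges$L1 <- data.frame(from = "a", to = "zzz")
  v <- validateNetwork(undeclared)
  expect_length(v, 1)
  expect_match(v, "undeclared")

  # constructing an invalid S4 object is refused outright
  expect_error(MultilayerNetwork(
    layers = "L1", nodes = list(L1 = "a"),
    intraEdges = list(L1 = data.frame(from = "a", to = "a"))), "self-loop")
})

test_that("edge queries are symmetric in endpoint order", {
  net <- toyNet()
  expect_true(hasIntraEdge(net, "L1", "a", "b"))
  expect_true(hasIntraEdge(net, "L1", "b", "a"))
  expect_false(hasIntraEdge(net, "L1", "a", "c"))
  expect_true(hasInterEdge(net, "L1", "a", "L2", "b"))
  expect_true(hasInterEdge(net, "L2", "b", "L1", "a"))
  expect_false(hasInterEdge(net, "L1", "b", "L2", "a"))
})

test_that("seed maps read, validate and round-trip against the two networks", {
  net <- generateMultilayer(10, 2, 14, seed = 2)
  f <- withr::local_tempfile()
  writeSeedMap(identitySeeds(net), f)
  seeds <- readSeedMap(f, net, net)
  expect_identical(nrow(seeds@entries), numNodes(net))
  expect_true(all(seeds@entries$similarity == 1))

  # entry referencing a node absent from net2
  bad <- tempfile()
  writeLines(c("#multiloal-seeds v1", "L1\tn01\tnope\t0.5"), bad)
  expect_error(readSeedMap(bad, net, net), "not in network 2")

  # similarity outside [0,1]
  bad2 <- tempfile()
  writeLines(c("#multiloal-seeds v1", "L1\tn01\tn02\t1.5"), bad2)
  expect_error(readSeedMap(bad2, net, net), "\\[0,1\\]")

  # row count is preserved for arbitrary valid files
  k3 <- tempfile()
  writeLines(c("#multiloal-seeds v1",
               "L1\tn01\tn02\t0.9",
               "L1\tn02\tn01\t0.8",
               "L2\tn03\tn03\t0.5"), k3)
  expect_identical(nrow(readSeedMap(k3, net, net)@entries), 3L)
})

test_that("scoring config enforces positive weights and delta >= 2", {
  cfg <- ScoringConfig()
  expect_equal(c(cfg@wMatch, cfg@wMismatch, cfg@wGap,
                 cfg@wHetMatch, cfg@wHetMismatch), c(1, 0.5, 0.2, 0.9, 0.4))
  expect_identical(cfg@delta, 2L)
  expect_error(ScoringConfig(delta = 1), "delta")
  expect_error(ScoringConfig(wMatch = 0), "positive")
})
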