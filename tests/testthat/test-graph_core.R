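test_that("graph construction collapses duplicates and drops self-loops", {
  g <- spreaderGraph(rbind(c("a", "b"), c("b", "a"), c("a", "b")))
  expect_equal(numEdges(g), 1L)
  expect_warning(g2 <- spreaderGraph(rbind(c("a", "a"), c("a", "b"))),
                 "self-loop")
  expect_equal(numEdges(g2), 1L)
  expect_true(validObject(g2))
})

test_that("degrees match construction on fixtures", {
  star <- fixtureGraph("star4")
  expect_equal(nodeDegree(star, "hub"), 3L)
  expect_equal(nodeDegree(fixtureGraph("path3"), "b"), 2L)
  iso <- spreaderGraph(rbind(c("a", "b")), nodes = "x")
  expect_equal(nodeDegree(iso, "x"), 0L)
  expect_error(nodeDegree(star, "nope"), "unknown node label")
})

test_that("geodesic distances: fixtures and Floyd-Warshall oracle", {
  d <- allPairsDistances(fixtureGraph("path3"))
  expect_equal(d["a", "c"], 2)
  disj <- spreaderGraph(rbind(c("a", "b"), c("c", "d")))
  expect_identical(allPairsDistances(disj)["a", "c"], UNREACHABLE)
  k4 <- spreaderGraph(t(combn(letters[1:4], 2)))
  dk4 <- allPairsDistances(k4)
  expect_true(all(dk4[upper.tri(dk4)] == 1))
  for (s in 1:10) {
    g <- randomGraph(n = 4 + s %% 9, p = 0.3, seed = 100 + s)
    expect_equal(allPairsDistances(g), oracleFloyd(adjacencyMatrix(g)))
  }
})

test_that("geodesic counts match exhaustive path enumeration", {
  p3 <- fixtureGraph("path3")
  gc <- geodesicCounts(p3)
  expect_equal(gc$sigma["a", "c"], 1)
  expect_equal(gc$through["a", "c", "b"], 1)

  c4 <- spreaderGraph(rbind(c("1", "2"), c("2", "3"), c("3", "4"), c("4", "1")))
  expect_equal(geodesicCounts(c4)$sigma["1", "3"], 2)

  k4 <- spreaderGraph(t(combn(letters[1:4], 2)))
  expect_true(all(geodesicCounts(k4)$through == 0))

  for (s in 1:8) {
    g <- randomGraph(n = 4 + s %% 4, p = 0.45, seed = 200 + s)
    got <- geodesicCounts(g)
    want <- oracleGeodesics(g)
    expect_equal(got$sigma, want$sigma)
    expect_equal(unname(got$through), unname(want$through))
  }
})

test_that("connected components partition the labels", {
  expect_length(connectedComponents(fixtureGraph("path3")), 1)
  disj <- spreaderGraph(rbind(c("a", "b"), c("c", "d")))
  expect_length(connectedComponents(disj), 2)
  empty3 <- spreaderGraph(nodes = c("x", "y", "z"))
  expect_length(connectedComponents(empty3), 3)
  comp <- connectedComponents(disj)
  expect_setequal(unlist(comp), nodeLabels(disj))
})

test_that("summary statistics: k = 2m/n, d averages reachable pairs", {
  s <- graphSummary(fixtureGraph("path3"))
  expect_equal(s$average_degree, 4 / 3)
  expect_equal(s$average_distance, 4 / 3)
  k4 <- spreaderGraph(t(combn(letters[1:4], 2)))
  expect_equal(graphSummary(k4)$average_degree, 3)
  expect_equal(graphSummary(k4)$average_distance, 1)
  e <- graphSummary(spreaderGraph(rbind(c("a", "b"))))
  expect_equal(e$average_degree, 1)
  expect_equal(e$average_distance, 1)
  disj <- spreaderGraph(rbind(c("a", "b"), c("c", "d")))
  expect_warning(sd <- graphSummary(disj), "disconnected")
  expect_equal(sd$average_distance, 1)   # only the two within-edge pairs
  expect_false(sd$connected)
  g <- randomGraph(12, 0.3, seed = 5)
  expect_equal(graphSummary(g)$average_degree, mean(nodeDegree(g)))
})

test_that("degree histogram counts sum to n and probabilities to 1", {
  h <- degreeHistogram(fixtureGraph("star4"))
  expect_equal(h$counts, c(`1` = 3L, `3` = 1L))
  expect_equal(degreeHistogram(fixtureGraph("cycle5"))$counts, c(`2` = 5L))
  empty2 <- spreaderGraph(nodes = c("u", "v"))
  expect_equal(degreeHistogram(empty2)$counts, c(`0` = 2L))
  g <- randomGraph(15, 0.25, seed = 9)
  h2 <- degreeHistogram(g)
  expect_equal(sum(h2$counts), numNodes(g))
  expect_equal(sum(h2$probability), 1)
  expect_equal(nrow(h2$degrees), numNodes(g))
})
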