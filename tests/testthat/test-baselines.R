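k4 <- spreaderGraph(t(combn(letters[1:4], 2)))

test_that("degree and betweenness centrality match hand values and oracle", {
  expect_equal(scores(degreeCentrality(fixtureGraph("star4")))[["hub"]], 3)
  expect_true(all(scores(degreeCentrality(fixtureGraph("cycle5"))) == 2))
  expect_true(all(scores(degreeCentrality(spreaderGraph(nodes = c("a", "b")))) == 0))

  bp <- scores(betweennessCentrality(fixtureGraph("path3")))
  expect_equal(bp[["b"]], 1)
  expect_equal(bp[["a"]], 0)
  expect_equal(scores(betweennessCentrality(fixtureGraph("star4")))[["hub"]], 3)
  expect_true(all(scores(betweennessCentrality(k4)) == 0))

  for (s in 1:6) {
    g <- randomGraph(n = 5 + s %% 3, p = 0.4, seed = 400 + s)
    expect_equal(scores(betweennessCentrality(g)), oracleBetweenness(g),
                 tolerance = 1e-12)
  }
})

test_that("closeness centrality: classic and harmonic variants", {
  expect_true(all(scores(closenessCentrality(k4)) == 1))
  ccp <- scores(closenessCentrality(fixtureGraph("path3")))
  expect_equal(ccp[["b"]], 1)
  expect_equal(ccp[["a"]], 2 / 3)
  disj <- spreaderGraph(rbind(c("a", "b"), c("c", "d")))
  expect_error(closenessCentrality(disj), "harmonic")
  # unreachable pairs contribute 0 under the harmonic variant
  h <- scores(closenessCentrality(disj, variant = "harmonic"))
  expect_equal(h[["a"]], 1)
})

test_that("eigenvector centrality: closed forms, symmetry, igraph cross-check", {
  ecK <- eigenvectorCentrality(k4)
  expect_equal(unname(scores(ecK)), rep(1 / 2, 4), tolerance = 1e-8)
  expect_equal(ecK@eigen$lambda, 3, tolerance = 1e-8)

  star <- fixtureGraph("star4")
  es <- scores(eigenvectorCentrality(star))
  expect_equal(es[["hub"]] / es[["leaf1"]], sqrt(3), tolerance = 1e-8)

  tsb <- scores(eigenvectorCentrality(fixtureGraph("two_stars_bridge")))
  expect_equal(tsb[["a0"]], tsb[["b0"]], tolerance = 1e-9)
  expect_equal(tsb[["a1"]], tsb[["b4"]], tolerance = 1e-9)

  g <- randomGraph(15, 0.3, seed = 11)
  mine <- scores(eigenvectorCentrality(g))
  ref <- igraph::eigen_centrality(
    igraph::graph_from_adjacency_matrix(adjacencyMatrix(g), mode = "undirected"))$vector
  expect_gt(stats::cor(mine, ref[names(mine)]), 0.999999)

  expect_error(eigenvectorCentrality(spreaderGraph(nodes = c("a", "b"))),
               "at least one edge")
  expect_error(eigenvectorCentrality(fixtureGraph("star4"), maxIter = 1),
               "did not converge")
})

test_that("gravity centrality evaluates the degree/distance interaction sum", {
  gp <- scores(gravityCentrality(fixtureGraph("path3")))
  expect_equal(gp[["b"]], 4)
  expect_equal(gp[["a"]], 2.25)
  gs <- scores(gravityCentrality(fixtureGraph("star4")))
  expect_equal(gs[["hub"]], 9)
  expect_equal(gs[["leaf2"]], 3.5)
  expect_true(all(scores(gravityCentrality(spreaderGraph(nodes = c("a", "b")))) == 0))
})

test_that("weighted gravity combines the Perron weights with gravity", {
  wk <- scores(weightedGravityCentrality(k4))
  expect_true(max(wk) - min(wk) < 1e-9)
  wp <- scores(weightedGravityCentrality(fixtureGraph("path3")))
  expect_equal(wp[["a"]], wp[["c"]], tolerance = 1e-10)
  ws <- weightedGravityCentrality(fixtureGraph("star4"))
  expect_equal(scoreTable(ws)$node[1], "hub")
})

test_that("automorphism-equivalent nodes tie under every measure", {
  tsb <- fixtureGraph("two_stars_bridge")
  pairs <- rbind(c("a0", "b0"), c("a1", "b1"), c("a2", "a3"))
  for (m in centralityMethods()) {
    s <- scores(suppressWarnings(computeCentrality(tsb, m)))
    for (r in seq_len(nrow(pairs)))
      expect_equal(s[[pairs[r, 1]]], s[[pairs[r, 2]]], tolerance = 1e-9,
                   label = paste(m, "score of", pairs[r, 1]))
  }
})

test_that("all measures are constant on vertex-transitive graphs", {
  for (fx in c("cycle5", "complete5")) {
    g <- fixtureGraph(fx)
    for (m in centralityMethods()) {
      s <- scores(suppressWarnings(computeCentrality(g, m)))
      expect_lt(max(s) - min(s), 1e-9 * max(1, max(abs(s))))
    }
  }
})

test_that("the star center is the unique argmax of every measure", {
  star <- fixtureGraph("star4")
  for (m in setdiff(centralityMethods(), "bc")) {
    s <- scores(suppressWarnings(computeCentrality(star, m)))
    expect_equal(names(which.max(s)), "hub", label = m)
    expect_gt(s[["hub"]], max(s[setdiff(names(s), "hub")]))
  }
  # bc separately: leaves are all 0, center positive
  b <- scores(betweennessCentrality(star))
  expect_gt(b[["hub"]], max(b[setdiff(names(b), "hub")]))
})
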