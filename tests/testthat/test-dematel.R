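test_that("direct-relation matrix holds gravity interactions", {
  D <- directRelationMatrix(fixtureGraph("path3"))
  expect_equal(D["a", "b"], 2)
  expect_equal(D["b", "c"], 2)
  expect_equal(D["a", "c"], 0.25)
  expect_true(all(diag(D) == 0))
  expect_equal(D, t(D))
  expect_true(all(directRelationMatrix(spreaderGraph(nodes = c("u", "v"))) == 0))
})

test_that("normalization divides by the max row/column sum", {
  D <- directRelationMatrix(fixtureGraph("path3"))
  nr <- normalizeRelationMatrix(D)
  expect_equal(nr$scale, 4)
  expect_equal(nr$Nm["a", "b"], 0.5)
  expect_equal(nr$Nm["a", "c"], 0.0625)
  z <- normalizeRelationMatrix(matrix(0, 3, 3))
  expect_equal(z$scale, 0)
  expect_true(all(z$Nm == 0))
  # symmetric D: max row sum equals max column sum
  expect_equal(max(rowSums(D)), max(colSums(D)))
  expect_error(normalizeRelationMatrix(matrix(-1, 2, 2)), "nonnegative")
})

test_that("total-relation matrix: geometric closed form and series agree", {
  expect_true(all(totalRelationMatrix(matrix(0, 3, 3)) == 0))

  Nm2 <- matrix(c(0, 0.5, 0.5, 0), 2)
  T2 <- totalRelationMatrix(Nm2)
  expect_equal(T2[1, 2], 2 / 3, tolerance = 1e-12)
  expect_equal(T2[1, 1], 1 / 3, tolerance = 1e-12)
  expect_equal(attr(T2, "method"), "closed_form")

  Nm3 <- normalizeRelationMatrix(directRelationMatrix(fixtureGraph("path3")))$Nm
  closed <- totalRelationMatrix(Nm3, mode = "closed_form")
  expect_lt(max(abs(closed - oracleSeries(Nm3, 200))), 1e-8)
  series <- totalRelationMatrix(Nm3, mode = "series")
  expect_lt(max(abs(closed - series)), 1e-8)
})

test_that("partial sums of the influence series are entrywise non-decreasing", {
  Nm <- normalizeRelationMatrix(
    directRelationMatrix(randomGraph(8, 0.35, seed = 21)))$Nm
  prev <- matrix(0, 8, 8)
  for (terms in c(1, 2, 5, 10, 50)) {
    cur <- oracleSeries(Nm, terms)
    expect_true(all(cur >= prev - 1e-15))
    prev <- cur
  }
})

test_that("causal parameters are row and column sums", {
  T2 <- matrix(c(1 / 3, 2 / 3, 2 / 3, 1 / 3), 2)
  cp <- causalParameters(T2)
  expect_equal(unname(cp$R), c(1, 1))
  expect_equal(cp$R, cp$C)
  z <- causalParameters(matrix(0, 3, 3))
  expect_true(all(z$R == 0) && all(z$C == 0))
})

test_that("full pipeline ranks the structural center first", {
  res <- rankDematel(fixtureGraph("path3"))
  a <- scores(res$importance)
  expect_gt(a[["b"]], a[["a"]])
  expect_equal(a[["a"]], a[["c"]])

  star <- rankDematel(fixtureGraph("star4"))
  expect_equal(star$importance@labels[star$importance@ranking[1]], "hub")
  # verify against an independent 200-term series route
  Nm <- normalizeRelationMatrix(directRelationMatrix(fixtureGraph("star4")))$Nm
  Ts <- oracleSeries(Nm, 200)
  expect_equal(unname(scores(star$importance)),
               unname(rowSums(Ts) + colSums(Ts)), tolerance = 1e-8)
})

test_that("degenerate normalizations warn but keep symmetric scores equal", {
  expect_warning(r5 <- rankDematel(fixtureGraph("cycle5")), "not converged")
  a5 <- scores(r5$importance)
  expect_lt(max(a5) - min(a5), 1e-9 * max(a5))
  expect_false(r5$relations@converged)

  expect_warning(r2 <- rankDematel(spreaderGraph(rbind(c("a", "b")))),
                 "not converged")
  a2 <- scores(r2$importance)
  expect_equal(a2[["a"]], a2[["b"]])
})

test_that("undirected inputs give symmetric matrices, R = C and a = 2R", {
  for (s in 1:50) {
    g <- randomGraph(n = 3 + s %% 10, p = 0.35, seed = 500 + s)
    res <- suppressWarnings(rankDematel(g))
    rel <- res$relations
    expect_equal(rel@D, t(rel@D))
    expect_equal(rel@Nm, t(rel@Nm))
    expect_equal(rel@T, t(rel@T))
    imp <- res$importance
    tolAbs <- 1e-9 * max(imp@R, 1)
    expect_lt(max(abs(imp@R - imp@C)), tolAbs)
    expect_lt(max(abs(imp@a - 2 * imp@R)), tolAbs)
  }
})

test_that("scaling the direct-relation matrix leaves Nm, T and ranking fixed", {
  D <- directRelationMatrix(randomGraph(10, 0.3, seed = 31))
  base <- normalizeRelationMatrix(D)
  for (c in c(1e-3, 7, 1e6)) {
    sc <- normalizeRelationMatrix(c * D)
    expect_equal(sc$Nm, base$Nm, tolerance = 1e-12)
    expect_equal(sc$scale, c * base$scale, tolerance = 1e-12)
  }
})

test_that("closed form equals the 200-term series on subcritical graphs", {
  found <- 0
  for (s in 1:40) {
    g <- randomGraph(n = 5 + s %% 16, p = 0.3, seed = 600 + s)
    Nm <- normalizeRelationMatrix(directRelationMatrix(g))$Nm
    rho <- max(abs(eigen(Nm, only.values = TRUE)$values))
    if (rho >= 0.95) next
    found <- found + 1
    closed <- totalRelationMatrix(Nm, mode = "closed_form")
    expect_lt(max(abs(closed - oracleSeries(Nm, 200))), 1e-8)
  }
  expect_gt(found, 5)
})
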