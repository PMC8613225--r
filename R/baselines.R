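#' @include graph.R
NULL

.centralityResult <- function(method, scores, labels, params = list(),
                              eigen = list()) {
  names(scores) <- labels
  new("CentralityResult", method = method, params = params,
      scores = scores, eigen = eigen)
}

#' @rdname scores
#' @export
setMethod("scores", "CentralityResult", function(x, ...) x@scores)

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "CentralityResult", function(x, ...) {
  s <- x@scores
  ord <- .tieOrder(s, names(s))
  data.frame(node = names(s)[ord], method = x@method,
             score = unname(s[ord]), rank = seq_along(s), row.names = NULL)
})

setMethod("show", "CentralityResult", function(object) {
  cat("CentralityResult [", object@method, "] for ",
      length(object@scores), " nodes\n", sep = "")
  top <- utils::head(scoreTable(object), 5)
  cat("  top nodes:", paste(top$node, collapse = ", "), "\n")
})

#' Degree centrality
#'
#' Score of node i is its degree: the number of adjacent nodes.
#'
#' @param g a [SpreaderGraph-class]
#' @return a [CentralityResult-class] with method tag `"dc"`
#' @export
degreeCentrality <- function(g) {
  .centralityResult("dc", as.numeric(nodeDegree(g)), g@labels)
}

#' Betweenness centrality
#'
#' b_i = sum over unordered pairs \{m, n\} with m != i != n of
#' p_mn(i) / p_mn, where p_mn counts geodesics between m and n and
#' p_mn(i) counts those passing through i. Unnormalized.
#'
#' @param g a [SpreaderGraph-class]
#' @return a [CentralityResult-class] with method tag `"bc"`
#' @export
betweennessCentrality <- function(g) {
  b <- if (numNodes(g)) igraph::betweenness(.asIgraph(g), directed = FALSE,
                                            normalized = FALSE)
       else numeric()
  .centralityResult("bc", as.numeric(b), g@labels)
}

#' Closeness centrality
#'
#' Classic variant: CC(i) = (n - 1) / sum_j d_ij, the inverse mean
#' geodesic distance to all other nodes; defined only on connected
#' graphs. Harmonic variant: sum_j 1/d_ij with unreachable pairs
#' contributing 0, usable on any graph.
#'
#' @param g a [SpreaderGraph-class]
#' @param variant `"classic"` (default) or `"harmonic"`
#' @return a [CentralityResult-class] with method tag `"cc"`
#' @export
closenessCentrality <- function(g, variant = c("classic", "harmonic")) {
  variant <- match.arg(variant)
  d <- allPairsDistances(g)
  n <- numNodes(g)
  if (variant == "classic") {
    if (n > 1 && any(!is.finite(d[upper.tri(d)])))
      stop("classic closeness is undefined on a disconnected graph; ",
           "use variant = \"harmonic\"")
    tot <- rowSums(d)
    cc <- ifelse(tot > 0, (n - 1) / tot, 0)
  } else {
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0   # diagonal and unreachable pairs
    cc <- rowSums(inv)
  }
  .centralityResult("cc", as.numeric(cc), g@labels,
                    params = list(variant = variant))
}

#' Eigenvector centrality
#'
#' Entries of the principal (Perron) eigenvector of the adjacency matrix,
#' nonnegative and scaled to unit Euclidean norm, with the leading
#' eigenvalue recorded. Computed by power iteration; the iteration runs
#' on A + I, which shares A's eigenvectors while guaranteeing convergence
#' on bipartite graphs, and the reported eigenvalue is the Rayleigh
#' quotient with A itself.
#'
#' @param g a [SpreaderGraph-class] with at least one edge
#' @param tol convergence threshold on the max-abs difference of
#'   successive normalized iterates (default 1e-10)
#' @param maxIter iteration budget (default 1000)
#' @return a [CentralityResult-class] with method tag `"ec"`; slot
#'   `eigen` holds `lambda` and the eigenvector.
#' @export
eigenvectorCentrality <- function(g, tol = 1e-10, maxIter = 1000) {
  stopifnot(is(g, "SpreaderGraph"))
  n <- numNodes(g)
  if (numEdges(g) < 1) stop("eigenvector centrality needs at least one edge")
  A <- g@adjacency
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(maxIter)) {
    y <- as.vector(A %*% x) + x          # shifted: (A + I) x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) {
      lambda <- as.numeric(crossprod(y, A %*% y))
      y <- pmax(y, 0)
      y <- y / sqrt(sum(y^2))
      return(.centralityResult("ec", y, g@labels,
                               params = list(tol = tol, iterations = it),
                               eigen = list(lambda = lambda, vector = y)))
    }
    x <- y
  }
  stop("eigenvector centrality did not converge within ", maxIter,
       " iterations")
}

## gravity interaction matrix: k_i k_j / d_ij^2, zero diagonal,
## unreachable pairs exactly 0 (division by Inf^2)
.gravityMatrix <- function(g, distances) {
  k <- as.numeric(nodeDegree(g))
  W <- outer(k, k) / distances^2
  W[!is.finite(W)] <- 0        # diagonal (d = 0) -> drop
  dimnames(W) <- list(g@labels, g@labels)
  W
}

#' Gravity centrality
#'
#' CG(i) = sum over reachable j != i of k_i k_j / d_ij^2 — degree plays
#' the role of mass and geodesic distance the role of separation, so the
#' score combines local (degree) and path (distance) information.
#' Unreachable pairs contribute exactly 0.
#'
#' @param g a [SpreaderGraph-class]
#' @param distances optional precomputed [allPairsDistances()] matrix
#' @return a [CentralityResult-class] with method tag `"gravity"`
#' @export
gravityCentrality <- function(g, distances = allPairsDistances(g)) {
  .centralityResult("gravity", rowSums(.gravityMatrix(g, distances)), g@labels)
}

#' Eigenvector-weighted gravity centrality
#'
#' WG(i) = e_i * CG(i), where e is the unit-norm nonnegative principal
#' eigenvector of the adjacency matrix and CG is [gravityCentrality()].
#'
#' @inheritParams gravityCentrality
#' @param tol,maxIter passed to [eigenvectorCentrality()]
#' @return a [CentralityResult-class] with method tag `"wgravity"`
#' @export
weightedGravityCentrality <- function(g, distances = allPairsDistances(g),
                                      tol = 1e-10, maxIter = 1000) {
  ec <- eigenvectorCentrality(g, tol = tol, maxIter = maxIter)
  cg <- gravityCentrality(g, distances)
  .centralityResult("wgravity", ec@scores * cg@scores, g@labels,
                    eigen = ec@eigen)
}

#' Compute a centrality by registry name
#'
#' Central dispatch used by the evaluation harness and the command-line
#' interface. Valid names: `dc`, `bc`, `cc`, `ec`, `gravity`, `wgravity`,
#' `dematel-gravity`.
#'
#' @param g a [SpreaderGraph-class]
#' @param method registry name
#' @return a [CentralityResult-class]
#' @export
computeCentrality <- function(g, method) {
  switch(method,
    "dc" = degreeCentrality(g),
    "bc" = betweennessCentrality(g),
    "cc" = closenessCentrality(g),
    "ec" = eigenvectorCentrality(g),
    "gravity" = gravityCentrality(g),
    "wgravity" = weightedGravityCentrality(g),
    "dematel-gravity" = asCentrality(rankDematel(g)$importance),
    stop("unknown method '", method, "'; valid: dc, bc, cc, ec, gravity, ",
         "wgravity, dematel-gravity"))
}

#' Names of all implemented centrality methods
#' @return character vector of registry names
#' @export
centralityMethods <- function() {
  c("dc", "bc", "cc", "ec", "gravity", "wgravity", "dematel-gravity")
}
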