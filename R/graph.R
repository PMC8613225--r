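#' @include AllGenerics.R
NULL

#' Sentinel for unreachable node pairs
#'
#' Geodesic distances between nodes in different connected components are
#' reported as `UNREACHABLE` (`Inf`), never as a large finite number, so
#' that gravity terms k_i k_j / d^2 for such pairs are exactly 0.
#' @export
UNREACHABLE <- Inf

## order nodes by descending score, ties by ascending label (radix: locale-stable)
.tieOrder <- function(score, labels) order(-score, labels, method = "radix")

#' Construct an undirected simple graph
#'
#' Duplicate edges collapse to one; self-loops are dropped with a warning.
#' Isolated nodes are introduced via `nodes`.
#'
#' @param edges two-column character matrix or data.frame of endpoint
#'   labels (may have zero rows).
#' @param nodes optional character vector of labels to include even when
#'   they touch no edge; also fixes label order for the ones listed.
#' @return a [SpreaderGraph-class]
#' @examples
#' g <- spreaderGraph(cbind(c("a", "b"), c("b", "c")))
#' numEdges(g)
#' @export
spreaderGraph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) edges <- matrix(character(), ncol = 2)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2 && nrow(edges) > 0)
    stop("edges must have two columns")
  storage.mode(edges) <- "character"
  labels <- unique(c(as.character(nodes), as.vector(t(edges))))
  n <- length(labels)
  adj <- matrix(0, n, n, dimnames = list(labels, labels))
  if (nrow(edges)) {
    loops <- edges[, 1] == edges[, 2]
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped")
      edges <- edges[!loops, , drop = FALSE]
    }
    i <- match(edges[, 1], labels)
    j <- match(edges[, 2], labels)
    adj[cbind(i, j)] <- 1
    adj[cbind(j, i)] <- 1
  }
  new("SpreaderGraph", labels = labels, adjacency = adj)
}

## igraph view of a SpreaderGraph (internal; keeps igraph behind the surface)
.asIgraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g@adjacency, mode = "undirected")
}

#' @describeIn spreaderGraph edge list as a two-column character matrix
#'   (each unordered pair once, endpoints sorted, rows sorted) — the
#'   canonical serialization used by [writeEdgeList()].
#' @param g a [SpreaderGraph-class]
#' @export
edgeMatrix <- function(g) {
  idx <- which(upper.tri(g@adjacency) & g@adjacency == 1, arr.ind = TRUE)
  e <- cbind(g@labels[idx[, 1]], g@labels[idx[, 2]])
  swap <- e[, 1] > e[, 2]
  e[swap, ] <- e[swap, c(2, 1)]
  e[order(e[, 1], e[, 2], method = "radix"), , drop = FALSE]
}

#' @rdname numNodes
#' @export
setMethod("numNodes", "SpreaderGraph", function(x) length(x@labels))

#' @rdname numEdges
#' @export
setMethod("numEdges", "SpreaderGraph", function(x) as.integer(sum(x@adjacency) / 2))

#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "SpreaderGraph", function(x) x@labels)

#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "SpreaderGraph", function(x) x@adjacency)

setMethod("show", "SpreaderGraph", function(object) {
  cat("SpreaderGraph with", numNodes(object), "nodes and",
      numEdges(object), "edges\n")
  if (numNodes(object)) {
    lab <- object@labels
    cat("  labels:", paste(utils::head(lab, 6), collapse = ", "),
        if (length(lab) > 6) "...", "\n")
  }
})

#' Degree of one node or all nodes
#'
#' @param g a [SpreaderGraph-class]
#' @param node optional single node label; when missing, all degrees.
#' @return integer degree (named vector when `node` is missing)
#' @export
nodeDegree <- function(g, node) {
  stopifnot(is(g, "SpreaderGraph"))
  deg <- as.integer(rowSums(g@adjacency))
  names(deg) <- g@labels
  if (missing(node)) return(deg)
  if (!node %in% g@labels) stop("unknown node label: ", node)
  deg[[node]]
}

#' All-pairs geodesic distances
#'
#' Unweighted BFS hop counts; unreachable pairs get [UNREACHABLE] (`Inf`).
#'
#' @param g a [SpreaderGraph-class]
#' @return symmetric numeric matrix, zero diagonal, labels as dimnames
#' @export
allPairsDistances <- function(g) {
  stopifnot(is(g, "SpreaderGraph"))
  if (numNodes(g) == 0) return(matrix(numeric(), 0, 0))
  d <- igraph::distances(.asIgraph(g))
  dimnames(d) <- list(g@labels, g@labels)
  d
}

#' Counts of geodesics and of geodesics through each node
#'
#' For every ordered pair (m, n) the number of shortest paths `sigma[m, n]`
#' (1 on the diagonal, 0 for unreachable pairs), and for every interior
#' node i the count `through[m, n, i]` of those geodesics passing through
#' i (0 when i is an endpoint). Memory is O(n^3): intended for small and
#' medium graphs and for oracle-style verification.
#'
#' @param g a [SpreaderGraph-class]
#' @param distances optional precomputed [allPairsDistances()] matrix
#' @return list with elements `sigma` (n x n) and `through` (n x n x n)
#' @export
geodesicCounts <- function(g, distances = allPairsDistances(g)) {
  stopifnot(is(g, "SpreaderGraph"))
  n <- numNodes(g)
  lab <- g@labels
  A <- g@adjacency
  sigma <- matrix(0, n, n, dimnames = list(lab, lab))
  for (s in seq_len(n)) {
    ds <- distances[s, ]
    sigma[s, s] <- 1
    reach <- order(ds)
    for (v in reach) {
      if (v == s || !is.finite(ds[v])) next
      pred <- A[, v] == 1 & ds == ds[v] - 1
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  through <- array(0, dim = c(n, n, n), dimnames = list(lab, lab, lab))
  for (i in seq_len(n)) {
    # geodesics m -> n through i decompose as (m -> i) x (i -> n)
    onpath <- outer(distances[, i], distances[i, ], "+") == distances
    onpath[!is.finite(distances)] <- FALSE
    cnt <- outer(sigma[, i], sigma[i, ]) * onpath
    cnt[i, ] <- 0
    cnt[, i] <- 0
    diag(cnt) <- 0
    through[, , i] <- cnt
  }
  list(sigma = sigma, through = through)
}

#' Connected components
#'
#' @param g a [SpreaderGraph-class]
#' @return list of character vectors partitioning the labels
#' @export
connectedComponents <- function(g) {
  stopifnot(is(g, "SpreaderGraph"))
  if (numNodes(g) == 0) return(list())
  comp <- igraph::components(.asIgraph(g))
  unname(split(g@labels, comp$membership))
}

#' Network summary statistics
#'
#' Node count n, edge count m, average degree k = 2m/n and average
#' geodesic distance d over unordered pairs of distinct reachable nodes.
#' On a disconnected graph the average distance is restricted to reachable
#' pairs, with a warning.
#'
#' @param g a [SpreaderGraph-class]
#' @return list with n, m, average_degree, average_distance, connected
#' @export
graphSummary <- function(g) {
  stopifnot(is(g, "SpreaderGraph"))
  n <- numNodes(g)
  m <- numEdges(g)
  d <- allPairsDistances(g)
  up <- d[upper.tri(d)]
  connected <- n <= 1 || all(is.finite(up))
  if (!connected) {
    warning("graph is disconnected; average distance restricted to reachable pairs")
    up <- up[is.finite(up)]
  }
  list(n = n, m = m,
       average_degree = if (n) 2 * m / n else NA_real_,
       average_distance = if (length(up)) mean(up) else NA_real_,
       connected = connected)
}

#' Degree histogram and per-node degree table
#'
#' @param g a [SpreaderGraph-class]
#' @return list: `counts` (named integer, degree -> node count),
#'   `probability` (counts / n), `degrees` (per-node degree table as a
#'   data.frame with columns node, degree)
#' @export
degreeHistogram <- function(g) {
  deg <- nodeDegree(g)
  tab <- table(factor(deg, levels = sort(unique(deg))))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  list(counts = counts,
       probability = counts / max(1L, numNodes(g)),
       degrees = data.frame(node = names(deg), degree = as.integer(deg),
                            row.names = NULL))
}
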