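#' @include graph.R
NULL

.fixtureNames <- c("path3", "star4", "cycle5", "complete5",
                   "two_stars_bridge", "grid4x4")

#' Deterministic fixture graphs
#'
#' Small hand-defined graphs with known exact properties, used for
#' worked examples and verification: `path3` (a-b-c), `star4` (a hub
#' with 3 leaves), `cycle5`, `complete5`, `two_stars_bridge` (two 4-leaf
#' stars whose hubs are joined by a bridge edge; the mirror symmetry
#' makes corresponding nodes tie under every measure), and `grid4x4`
#' (4 x 4 square lattice).
#'
#' @param name fixture name
#' @return a [SpreaderGraph-class]
#' @export
fixtureGraph <- function(name) {
  if (!name %in% .fixtureNames)
    stop("unknown fixture '", name, "'; available: ",
         paste(.fixtureNames, collapse = ", "))
  ring <- function(lab) cbind(lab, lab[c(2:length(lab), 1)])
  switch(name,
    path3 = spreaderGraph(rbind(c("a", "b"), c("b", "c"))),
    star4 = spreaderGraph(cbind("hub", c("leaf1", "leaf2", "leaf3"))),
    cycle5 = spreaderGraph(ring(paste0("n", 1:5))),
    complete5 = {
      lab <- paste0("k", 1:5)
      spreaderGraph(t(utils::combn(lab, 2)))
    },
    two_stars_bridge = spreaderGraph(rbind(
      cbind("a0", paste0("a", 1:4)),
      cbind("b0", paste0("b", 1:4)),
      c("a0", "b0"))),
    grid4x4 = {
      lab <- outer(1:4, 1:4, function(r, c) paste0("g", r, c))
      horiz <- cbind(as.vector(lab[, 1:3]), as.vector(lab[, 2:4]))
      vert <- cbind(as.vector(lab[1:3, ]), as.vector(lab[2:4, ]))
      spreaderGraph(rbind(horiz, vert))
    })
}

.erGraph <- function(n, p) {
  lab <- as.character(seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  spreaderGraph(cbind(lab[e[, 1]], lab[e[, 2]]), nodes = lab)
}

.baGraph <- function(n, mAttach) {
  if (mAttach >= n) stop("mAttach must be smaller than n")
  if (n < 4 || mAttach < 1 || mAttach > 3)
    stop("BA generator needs n >= 4 and 1 <= mAttach <= 3 (triangle seed core)")
  deg <- integer(n)
  deg[1:3] <- 2L                       # complete triangle seed core
  edges <- matrix(c(1L, 2L, 1L, 3L, 2L, 3L), ncol = 2, byrow = TRUE)
  for (v in 4:n) {
    existing <- seq_len(v - 1)
    targets <- sample(existing, mAttach, prob = deg[existing])
    edges <- rbind(edges, cbind(v, targets))
    deg[targets] <- deg[targets] + 1L
    deg[v] <- mAttach
  }
  lab <- as.character(seq_len(n))
  spreaderGraph(cbind(lab[edges[, 1]], lab[edges[, 2]]), nodes = lab)
}

.wsGraph <- function(n, kRing, pRewire) {
  if (kRing %% 2 != 0 || kRing < 2 || kRing >= n)
    stop("kRing must be even, >= 2 and < n")
  adj <- matrix(0L, n, n)
  for (j in seq_len(kRing / 2)) {
    tgt <- (seq_len(n) + j - 1) %% n + 1
    adj[cbind(seq_len(n), tgt)] <- 1L
    adj[cbind(tgt, seq_len(n))] <- 1L
  }
  # rewire the far endpoint of each lattice edge with prob pRewire,
  # resampling to avoid self-loops and duplicate edges
  for (j in seq_len(kRing / 2)) {
    for (i in seq_len(n)) {
      old <- (i + j - 1) %% n + 1
      if (stats::runif(1) < pRewire && adj[i, old] == 1L) {
        if (sum(adj[i, ]) >= n - 1) next   # node saturated, nothing to rewire to
        repeat {
          new <- sample.int(n, 1)
          if (new != i && adj[i, new] == 0L) break
        }
        adj[i, old] <- adj[old, i] <- 0L
        adj[i, new] <- adj[new, i] <- 1L
      }
    }
  }
  lab <- as.character(seq_len(n))
  dimnames(adj) <- list(lab, lab)
  new("SpreaderGraph", labels = lab, adjacency = adj + 0)
}

#' Seeded synthetic network generators
#'
#' Deterministic given `seed`. Models: `er` — Erdős–Rényi G(n, p), each
#' unordered pair present independently with probability `p`; `ba` —
#' Barabási–Albert preferential attachment starting from a complete
#' triangle seed core, each arriving node attaching `mAttach` edges to
#' distinct existing nodes sampled with probability proportional to
#' degree (so m = 3 + mAttach (n - 3) edges); `ws` — Watts–Strogatz
#' ring lattice (each node linked to `kRing`/2 neighbours per side)
#' with each edge's far endpoint rewired with probability `pRewire`.
#'
#' @param model `"er"`, `"ba"` or `"ws"`
#' @param n number of nodes
#' @param seed RNG seed
#' @param p ER edge probability
#' @param mAttach BA edges per arriving node (1..3)
#' @param kRing WS ring degree (even)
#' @param pRewire WS rewiring probability
#' @return a [SpreaderGraph-class] with labels "1".."n"
#' @examples
#' g <- generateGraph("ba", n = 50, mAttach = 2, seed = 7)
#' numEdges(g)   # 3 + 2 * 47
#' @export
generateGraph <- function(model = c("er", "ba", "ws"), n, seed = 1L,
                          p = NULL, mAttach = NULL, kRing = NULL,
                          pRewire = NULL) {
  model <- match.arg(model)
  if (n < 1) stop("n must be >= 1")
  .withSeed(as.integer(seed), switch(model,
    er = {
      if (is.null(p) || p < 0 || p > 1)
        stop("er model needs edge probability p in [0, 1]")
      .erGraph(n, p)
    },
    ba = {
      if (is.null(mAttach)) stop("ba model needs mAttach")
      .baGraph(n, mAttach)
    },
    ws = {
      if (is.null(kRing) || is.null(pRewire) || pRewire < 0 || pRewire > 1)
        stop("ws model needs kRing and pRewire in [0, 1]")
      .wsGraph(n, kRing, pRewire)
    }))
}
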