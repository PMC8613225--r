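#' @include graph.R
NULL

#' Build an SI simulation configuration
#'
#' @param beta per-contact infection probability per step, in [0, 1]
#' @param steps number of synchronous steps (the "simulation time")
#' @param runs repetitions per seed node
#' @param seed master RNG seed (integer)
#' @return an [SIConfig-class]
#' @export
siConfig <- function(beta, steps, runs, seed = 1L) {
  new("SIConfig", beta = as.numeric(beta), steps = as.integer(steps),
      runs = as.integer(runs), seed = as.integer(seed))
}

## independent RNG stream per (seed node, run): affine map mod 2^31 - 1
## keeps results independent of iteration order and below .Machine$integer.max
.streamSeed <- function(master, nodeIdx, run) {
  as.integer((as.numeric(master) * 48271 + nodeIdx * 100003 + run * 7919) %%
             2147483587)
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## one synchronous SI trajectory from an adjacency matrix; returns the
## cumulative infected count at t = 0..steps
.siTrajectory <- function(A, seedIdx, beta, steps) {
  n <- nrow(A)
  infected <- logical(n)
  infected[seedIdx] <- TRUE
  series <- integer(steps + 1)
  series[1] <- 1L
  for (t in seq_len(steps)) {
    if (!all(infected)) {
      # susceptible j is hit with prob 1 - (1 - beta)^(# infected neighbours):
      # the aggregate of independent per-contact Bernoulli(beta) trials
      cnt <- as.vector(A %*% infected)
      sus <- which(!infected & cnt > 0)
      if (length(sus)) {
        p <- 1 - (1 - beta)^cnt[sus]
        infected[sus[stats::runif(length(sus)) < p]] <- TRUE
      }
    }
    series[t + 1] <- sum(infected)
  }
  series
}

#' One SI run from a single seed node
#'
#' Discrete-time synchronous susceptible-infected dynamics: at every step
#' each currently infected node independently infects each susceptible
#' neighbour with probability `beta`; the newly infected become
#' infectious at the next step; nobody recovers. Fully reproducible from
#' (config seed, seed node, run index).
#'
#' @param g a [SpreaderGraph-class]
#' @param seedNode label of the initially infected node
#' @param config an [SIConfig-class]
#' @param runIndex repetition index (selects the RNG stream)
#' @return integer vector of cumulative infected counts, length
#'   `steps + 1`, starting at 1
#' @export
siRun <- function(g, seedNode, config, runIndex = 1L) {
  stopifnot(is(g, "SpreaderGraph"), is(config, "SIConfig"))
  idx <- match(seedNode, g@labels)
  if (is.na(idx)) stop("unknown seed node label: ", seedNode)
  .withSeed(.streamSeed(config@seed, idx, runIndex),
            .siTrajectory(g@adjacency, idx, config@beta, config@steps))
}

#' Simulate spreading from a set of seed nodes
#'
#' Runs `config@runs` independent SI trajectories from each seed and
#' collects the cumulative infection curves, their per-seed means, and
#' each seed's spreading capacity (mean final infected count, seed
#' included).
#'
#' @param g a [SpreaderGraph-class]
#' @param nodes seed labels (default: all nodes)
#' @param config an [SIConfig-class]
#' @return a [SpreadResult-class]
#' @export
simulateSpread <- function(g, nodes = nodeLabels(g), config) {
  stopifnot(is(g, "SpreaderGraph"), is(config, "SIConfig"))
  bad <- setdiff(nodes, g@labels)
  if (length(bad)) stop("unknown seed node label(s): ", paste(bad, collapse = ", "))
  A <- g@adjacency
  curves <- vector("list", length(nodes))
  names(curves) <- nodes
  meanCurves <- matrix(0, length(nodes), config@steps + 1,
                       dimnames = list(nodes, NULL))
  for (s in seq_along(nodes)) {
    idx <- match(nodes[s], g@labels)
    m <- matrix(0L, config@runs, config@steps + 1)
    for (r in seq_len(config@runs))
      m[r, ] <- .withSeed(.streamSeed(config@seed, idx, r),
                          .siTrajectory(A, idx, config@beta, config@steps))
    curves[[s]] <- m
    meanCurves[s, ] <- colMeans(m)
  }
  capacity <- meanCurves[, config@steps + 1]
  names(capacity) <- nodes
  new("SpreadResult", seeds = as.character(nodes), curves = curves,
      meanCurves = meanCurves, capacity = capacity, config = config)
}

#' @rdname capacity
#' @export
setMethod("capacity", "SpreadResult", function(x) x@capacity)

setMethod("show", "SpreadResult", function(object) {
  cfg <- object@config
  cat("SpreadResult:", length(object@seeds), "seed(s), beta =", cfg@beta,
      ", steps =", cfg@steps, ", runs =", cfg@runs, "\n")
  cat("  capacity range: [", format(min(object@capacity)), ",",
      format(max(object@capacity)), "]\n")
})

#' Spreading capacity of a set of nodes
#'
#' Mean over runs of the final cumulative infected count when seeding at
#' each node — the ground truth against which centrality rankings are
#' evaluated.
#'
#' @inheritParams simulateSpread
#' @return named numeric vector, one capacity per node
#' @export
spreadingCapacity <- function(g, nodes = nodeLabels(g), config) {
  capacity(simulateSpread(g, nodes, config))
}

#' Summed mean infection curve of the top-k ranked nodes
#'
#' For each of the k highest-ranked nodes the per-seed mean curve over
#' runs is computed, then the k mean curves are summed pointwise — the
#' ordinate of the top-spreader effectiveness experiment.
#'
#' @param g a [SpreaderGraph-class]
#' @param ranking a [CentralityResult-class], [ImportanceResult-class],
#'   or character vector of labels already in rank order
#' @param k number of top nodes to seed
#' @param config an [SIConfig-class]
#' @return numeric vector of length `steps + 1` (position 1 equals k)
#' @export
topkAverageCurve <- function(g, ranking, k, config) {
  lab <- if (is.character(ranking)) ranking
         else scoreTable(ranking)$node
  if (k > numNodes(g)) stop("k exceeds the number of nodes")
  top <- utils::head(lab, k)
  res <- simulateSpread(g, top, config)
  colSums(res@meanCurves)
}
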