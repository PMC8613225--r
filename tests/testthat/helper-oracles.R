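# Independent brute-force oracles used to verify the package's
# algorithmic routes. These deliberately share no code with R/.

# all-pairs distances by Floyd-Warshall (package route is BFS)
oracleFloyd <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  dimnames(d) <- dimnames(A)
  d
}

# every simple path from s to t by exhaustive DFS
allSimplePaths <- function(A, s, t) {
  paths <- list()
  recurse <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in which(A[v, ] == 1))
      if (!w %in% path) recurse(c(path, w))
  }
  recurse(s)
  paths
}

# geodesic counts by exhaustive path enumeration (n <= 7 territory)
oracleGeodesics <- function(g) {
  A <- adjacencyMatrix(g)
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  through <- array(0, c(n, n, n))
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- allSimplePaths(A, s, t)
    if (!length(paths)) next
    len <- vapply(paths, length, 0L) - 1L
    sp <- paths[len == min(len)]
    sigma[s, t] <- length(sp)
    for (p in sp)
      for (i in setdiff(p, c(s, t)))
        through[s, t, i] <- through[s, t, i] + 1
  }
  dimnames(sigma) <- dimnames(A)
  list(sigma = sigma, through = through)
}

# unnormalized betweenness from the enumeration oracle:
# each unordered pair counted once, endpoints excluded
oracleBetweenness <- function(g) {
  oc <- oracleGeodesics(g)
  n <- nrow(oc$sigma)
  b <- numeric(n)
  for (i in seq_len(n))
    for (s in seq_len(n - 1))
      for (t in (s + 1):n)
        if (s != i && t != i && oc$sigma[s, t] > 0)
          b[i] <- b[i] + oc$through[s, t, i] / oc$sigma[s, t]
  names(b) <- nodeLabels(g)
  b
}

# Kendall statistics by direct double-loop pair counting
oracleTau <- function(x, y, variant = "tau_a") {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- (x[i] - x[j]) * (y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  den <- switch(variant, tau_a = n * (n - 1) / 2, paper = n * (n - 1))
  (conc - disc) / den
}

# seeded ER graph shorthand for property loops
randomGraph <- function(n, p, seed) generateGraph("er", n = n, seed = seed, p = p)

# truncated Neumann partial sum, written independently of the package route
oracleSeries <- function(Nm, terms) {
  acc <- matrix(0, nrow(Nm), ncol(Nm))
  P <- diag(nrow(Nm))
  for (k in seq_len(terms)) {
    P <- P %*% Nm
    acc <- acc + P
  }
  acc
}
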