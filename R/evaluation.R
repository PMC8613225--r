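#' @include si.R
NULL

#' Kendall rank correlation between two sequences
#'
#' A pair (i, j) is concordant when (x_i - x_j)(y_i - y_j) > 0 and
#' discordant when it is < 0; tied pairs count as neither. Variants
#' differ only in the denominator: `tau_a` uses n(n-1)/2; `paper` uses
#' n(n-1) (so its range is [-0.5, 0.5] and it equals tau_a / 2 on
#' tie-free data); `tau_b` (default) applies the standard tie
#' correction, which is appropriate for spreading capacities and scores
#' that contain ties. When a tie-corrected denominator is 0 (a constant
#' sequence) the statistic is NaN, with a warning.
#'
#' @param x,y equal-length numeric vectors, length >= 2
#' @param variant `"tau_b"`, `"tau_a"` or `"paper"`
#' @return a [TauResult-class]
#' @examples
#' kendallTau(c(1, 2, 3), c(1, 3, 2), variant = "tau_a")
#' @export
kendallTau <- function(x, y, variant = c("tau_b", "tau_a", "paper")) {
  variant <- match.arg(variant)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("sequences must have length >= 2")
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  prod <- dx[up] * dy[up]
  conc <- sum(prod > 0)
  disc <- sum(prod < 0)
  n0 <- n * (n - 1) / 2
  tau <- switch(variant,
    tau_a = (conc - disc) / n0,
    paper = (conc - disc) / (n * (n - 1)),
    tau_b = {
      tiesOf <- function(v) {
        t <- table(v)
        sum(t * (t - 1) / 2)
      }
      den <- sqrt((n0 - tiesOf(x)) * (n0 - tiesOf(y)))
      if (den == 0) {
        warning("tau_b undefined: at least one sequence is constant")
        NaN
      } else (conc - disc) / den
    })
  new("TauResult", tau = tau, concordant = as.numeric(conc),
      discordant = as.numeric(disc), n = as.integer(n), variant = variant)
}

setMethod("show", "TauResult", function(object) {
  cat("Kendall tau (", object@variant, ") = ", format(object@tau),
      "  [concordant ", object@concordant, ", discordant ",
      object@discordant, ", n = ", object@n, "]\n", sep = "")
})

#' Rank agreement of centralities with SI spreading capacity
#'
#' For every infection probability in `betaGrid`, spreading capacities
#' are simulated once for all nodes (shared across methods), then the
#' Kendall correlation between each method's score vector and the
#' capacity vector is computed, node-aligned. The default grid runs from
#' 0.05 to 1 in steps of 0.05; beta = 0 is excluded because every
#' capacity is then 1 and the tie-corrected tau is undefined.
#'
#' @param g a [SpreaderGraph-class]
#' @param methods character vector of registry names (see
#'   [centralityMethods()])
#' @param betaGrid numeric vector of infection probabilities
#' @param steps,runs SI horizon and repetitions per seed
#' @param seed master RNG seed
#' @param variant tau variant, default `"tau_b"`
#' @return data.frame with columns method, beta, tau
#' @export
correlationExperiment <- function(g, methods, betaGrid = seq(0.05, 1, 0.05),
                                  steps = 20, runs = 100, seed = 1L,
                                  variant = "tau_b") {
  stopifnot(is(g, "SpreaderGraph"))
  scoreList <- lapply(methods, function(m) scores(computeCentrality(g, m)))
  names(scoreList) <- methods
  out <- vector("list", length(betaGrid))
  for (b in seq_along(betaGrid)) {
    cfg <- siConfig(betaGrid[b], steps, runs,
                    seed = .streamSeed(seed, 0, b))
    cap <- spreadingCapacity(g, config = cfg)
    taus <- vapply(methods, function(m) {
      s <- scoreList[[m]][names(cap)]
      kendallTau(as.numeric(s), as.numeric(cap), variant = variant)@tau
    }, numeric(1))
    out[[b]] <- data.frame(method = methods, beta = betaGrid[b], tau = taus,
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Top-k node table and pairwise overlap between methods
#'
#' Per method, the k highest-scoring node labels in rank order (ties by
#' ascending label), together with the pairwise counts of shared labels
#' among the top-k sets.
#'
#' @param results a single [CentralityResult-class] /
#'   [ImportanceResult-class] or a list of them
#' @param k number of top nodes
#' @return list: `top` (data.frame, column rank plus one column per
#'   method) and `overlap` (symmetric integer matrix of shared-label
#'   counts, diagonal k)
#' @export
topTable <- function(results, k) {
  if (!is.list(results)) results <- list(results)
  tabs <- lapply(results, scoreTable)
  methods <- vapply(tabs, function(t) t$method[1], character(1))
  if (k > nrow(tabs[[1]])) stop("k exceeds the number of nodes")
  tops <- lapply(tabs, function(t) utils::head(t$node, k))
  names(tops) <- methods
  top <- data.frame(rank = seq_len(k), tops, check.names = FALSE)
  overlap <- outer(seq_along(tops), seq_along(tops),
                   Vectorize(function(i, j) length(intersect(tops[[i]], tops[[j]]))))
  dimnames(overlap) <- list(methods, methods)
  list(top = top, overlap = overlap)
}
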