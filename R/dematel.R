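#' @include baselines.R
NULL

## Perron root of a nonnegative matrix by shifted power iteration:
## iterating (M + I) makes the Perron eigenvalue strictly dominant, so the
## norm ratio converges even when M has eigenvalue pairs of equal modulus.
.spectralRadius <- function(M, tol = 1e-10, maxIter = 10000) {
  n <- nrow(M)
  if (n == 0 || max(M) == 0) return(0)
  x <- rep(1 / sqrt(n), n)
  rOld <- Inf
  for (it in seq_len(maxIter)) {
    y <- as.vector(M %*% x) + x
    r <- sqrt(sum(y^2))
    y <- y / r
    if (abs(r - rOld) < tol && max(abs(y - x)) < sqrt(tol)) return(r - 1)
    x <- y
    rOld <- r
  }
  r - 1
}

#' Gravity direct-relation matrix
#'
#' Entry (i, j), i != j, is the gravity interaction g_ij =
#' k_i k_j / d_ij^2 — the direct influence of node i on node j. The
#' diagonal is zero and unreachable pairs contribute exactly 0.
#'
#' @param g a [SpreaderGraph-class]
#' @param distances optional precomputed [allPairsDistances()] matrix
#' @return numeric matrix with node labels as dimnames
#' @export
directRelationMatrix <- function(g, distances = allPairsDistances(g)) {
  stopifnot(is(g, "SpreaderGraph"))
  .gravityMatrix(g, distances)
}

#' Normalize a direct-relation matrix
#'
#' Divides D by the single global scalar s = max(largest row sum,
#' largest column sum), the standard DEMATEL normalization; this keeps
#' the Neumann series of matrix powers meaningful. An all-zero D is
#' returned unchanged with s = 0.
#'
#' @param D nonnegative matrix with zero diagonal
#' @return list with `Nm` (normalized matrix) and `scale` (s)
#' @export
normalizeRelationMatrix <- function(D) {
  if (any(D < 0) || any(diag(D) != 0))
    stop("D must be nonnegative with a zero diagonal")
  s <- max(max(rowSums(D)), max(colSums(D)), 0)
  list(Nm = if (s > 0) D / s else D, scale = s)
}

#' Total-relation matrix
#'
#' T = sum_{k >= 1} Nm^k accumulates direct (k = 1) and indirect
#' (k >= 2) influence chains. When the spectral radius of Nm is safely
#' below 1 the series is summed in closed form as Nm (I - Nm)^-1;
#' otherwise (or on request) a truncated partial sum is used, stopping
#' when the max-abs increment falls below `tol` or `maxTerms` is
#' reached — the latter triggers a degeneracy warning, since for some
#' regular structures (e.g. cycles) the normalized matrix has spectral
#' radius exactly 1 and the series diverges while preserving the
#' symmetry of the scores.
#'
#' @param Nm normalized relation matrix (nonnegative, zero diagonal)
#' @param mode `"auto"` (closed form when safe), `"closed_form"`, or
#'   `"series"`
#' @param tol series stopping threshold on the max-abs increment
#' @param maxTerms series term budget
#' @return matrix T with attributes `method` (`"closed_form"` or
#'   `"series"`) and `converged`
#' @export
totalRelationMatrix <- function(Nm, mode = c("auto", "closed_form", "series"),
                                tol = 1e-12, maxTerms = 1000) {
  mode <- match.arg(mode)
  n <- nrow(Nm)
  if (mode != "series") {
    rho <- .spectralRadius(Nm)
    if (mode == "closed_form" || rho < 1 - 1e-9) {
      T <- Nm %*% solve(diag(n) - Nm)
      if (any(!is.finite(T)))
        stop("total-relation matrix is not finite (singular I - Nm?)")
      attr(T, "method") <- "closed_form"
      attr(T, "converged") <- TRUE
      return(T)
    }
    # spectral radius at or above 1: fall through to the truncated series
  }
  T <- Nm
  P <- Nm
  converged <- max(abs(P)) < tol
  k <- 1
  while (!converged && k < maxTerms) {
    P <- P %*% Nm
    T <- T + P
    k <- k + 1
    converged <- max(abs(P)) < tol
  }
  if (any(!is.finite(T))) stop("total-relation series produced non-finite entries")
  if (!converged)
    warning("total-relation series not converged after ", k,
            " terms (spectral radius at or above 1); ",
            "scores remain comparable across symmetric nodes")
  attr(T, "method") <- "series"
  attr(T, "converged") <- converged
  T
}

#' Causal parameters R and C
#'
#' R_i (row sums of T) is the total influence node i exerts; C_j
#' (column sums) is the total influence node j receives.
#'
#' @param T total-relation matrix
#' @return list with numeric vectors `R` and `C`
#' @export
causalParameters <- function(T) {
  list(R = rowSums(T), C = colSums(T))
}

#' Rank nodes with the DEMATEL gravity model
#'
#' Full pipeline: gravity direct-relation matrix from degrees and
#' geodesic distances, scalar normalization, total-relation matrix
#' (direct + indirect influence), causal parameters R and C, and node
#' importance a = R + C. On an undirected graph all three matrices are
#' symmetric, so R = C and a = 2R.
#'
#' @param g a [SpreaderGraph-class] with at least 2 nodes
#' @param mode,tol,maxTerms passed to [totalRelationMatrix()]
#' @return list with `relations` ([RelationMatrices-class]) and
#'   `importance` ([ImportanceResult-class])
#' @examples
#' g <- fixtureGraph("star4")
#' res <- rankDematel(g)
#' scoreTable(res$importance)
#' @export
rankDematel <- function(g, mode = "auto", tol = 1e-12, maxTerms = 1000) {
  stopifnot(is(g, "SpreaderGraph"))
  if (numNodes(g) < 2) stop("DEMATEL ranking needs at least 2 nodes")
  D <- directRelationMatrix(g)
  nr <- normalizeRelationMatrix(D)
  T <- totalRelationMatrix(nr$Nm, mode = mode, tol = tol, maxTerms = maxTerms)
  cp <- causalParameters(T)
  a <- cp$R + cp$C
  rel <- new("RelationMatrices", D = D, Nm = nr$Nm,
             T = structure(T, method = NULL, converged = NULL),
             scale = nr$scale, method = attr(T, "method"),
             converged = attr(T, "converged"))
  # initialize() rather than new(): a slot named "C" would partial-match
  # new()'s Class formal
  imp <- initialize(new("ImportanceResult"), labels = g@labels,
                    R = unname(cp$R), C = unname(cp$C), a = unname(a),
                    ranking = .tieOrder(a, g@labels))
  list(relations = rel, importance = imp)
}

#' @rdname scores
#' @export
setMethod("scores", "ImportanceResult", function(x, ...) {
  structure(x@a, names = x@labels)
})

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "ImportanceResult", function(x, ...) {
  ord <- x@ranking
  data.frame(node = x@labels[ord], method = "dematel-gravity",
             score = x@a[ord], rank = seq_along(ord), row.names = NULL)
})

setMethod("show", "ImportanceResult", function(object) {
  cat("ImportanceResult (dematel-gravity) for", length(object@labels),
      "nodes\n")
  cat("  top nodes:",
      paste(utils::head(object@labels[object@ranking], 5), collapse = ", "),
      "\n")
})

setMethod("show", "RelationMatrices", function(object) {
  cat("RelationMatrices: n =", nrow(object@D),
      "| scale s =", format(object@scale),
      "| method =", object@method,
      "| converged =", object@converged, "\n")
})

#' View DEMATEL importance as a centrality result
#'
#' @param imp an [ImportanceResult-class]
#' @return a [CentralityResult-class] with method tag `"dematel-gravity"`
#' @export
asCentrality <- function(imp) {
  stopifnot(is(imp, "ImportanceResult"))
  .centralityResult("dematel-gravity", imp@a, imp@labels)
}

#' Write the D, Nm and T matrices as labelled TSV files
#'
#' @param rel a [RelationMatrices-class]
#' @param prefix path prefix; files `<prefix>_D.tsv`, `<prefix>_Nm.tsv`,
#'   `<prefix>_T.tsv` are written with node labels as row/column headers
#' @return the three paths, invisibly
#' @export
dumpRelationMatrices <- function(rel, prefix) {
  stopifnot(is(rel, "RelationMatrices"))
  paths <- character(3)
  nms <- c("D", "Nm", "T")
  for (k in seq_along(nms)) {
    paths[k] <- paste0(prefix, "_", nms[k], ".tsv")
    m <- slot(rel, nms[k])
    utils::write.table(m, paths[k], sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(paths)
}
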