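#' @import methods
NULL

#' SpreaderGraph: an undirected simple graph
#'
#' Holds node labels and a symmetric 0/1 adjacency matrix with an empty
#' diagonal. All analyses in the package (centralities, the DEMATEL gravity
#' model, SI simulation) start from this container. Construct with
#' [spreaderGraph()], [readPajek()], [readEdgeList()], [generateGraph()] or
#' [fixtureGraph()].
#'
#' @slot labels character vector of unique node identifiers.
#' @slot adjacency numeric matrix, symmetric, entries in \{0, 1\}, zero
#'   diagonal, dimnames equal to `labels`.
#'
#' @aliases SpreaderGraph-class
#' @exportClass SpreaderGraph
setClass("SpreaderGraph",
  representation(labels = "character", adjacency = "matrix"))

setValidity("SpreaderGraph", function(object) {
  a <- object@adjacency
  lab <- object@labels
  msgs <- character()
  if (anyDuplicated(lab)) msgs <- c(msgs, "node labels must be unique")
  if (nrow(a) != length(lab) || ncol(a) != length(lab))
    msgs <- c(msgs, "adjacency dimensions must match label count")
  else {
    if (!all(a %in% c(0, 1))) msgs <- c(msgs, "adjacency entries must be 0 or 1")
    if (!isTRUE(all.equal(a, t(a)))) msgs <- c(msgs, "adjacency must be symmetric")
    if (length(lab) && any(diag(a) != 0)) msgs <- c(msgs, "self-loops are not allowed")
    if (!identical(rownames(a), lab)) msgs <- c(msgs, "adjacency dimnames must equal labels")
  }
  if (length(msgs)) msgs else TRUE
})

#' CentralityResult: per-node scores of one centrality measure
#'
#' @slot method short method tag, e.g. `"dc"`, `"bc"`, `"cc"`, `"ec"`,
#'   `"gravity"`, `"wgravity"`, `"dematel-gravity"`.
#' @slot params list of parameters the method was run with.
#' @slot scores named numeric vector, one finite score per node.
#' @slot eigen list with elements `lambda` and `vector` when the method is
#'   eigenvector-based, otherwise empty.
#'
#' @aliases CentralityResult-class
#' @exportClass CentralityResult
setClass("CentralityResult",
  representation(method = "character", params = "list",
                 scores = "numeric", eigen = "list"),
  prototype(params = list(), eigen = list()))

setValidity("CentralityResult", function(object) {
  if (length(object@method) != 1L) return("method must be a single string")
  if (is.null(names(object@scores))) return("scores must be named by node label")
  if (!all(is.finite(object@scores))) return("scores must be finite")
  TRUE
})

#' RelationMatrices: direct, normalized and total relation matrices
#'
#' The three matrices of the DEMATEL stage: the gravity direct-relation
#' matrix D with entries k_i k_j / d_ij^2, its scalar normalization Nm = D/s,
#' and the total-relation matrix T = sum_{k>=1} Nm^k capturing direct plus
#' indirect influence.
#'
#' @slot D direct relation matrix (zero diagonal, nonnegative).
#' @slot Nm normalized relation matrix.
#' @slot T total relation matrix.
#' @slot scale the normalization scalar s (max of row/column sums of D).
#' @slot method `"closed_form"` (Neumann series summed via solve(I - Nm)) or
#'   `"series"` (truncated partial sum).
#' @slot converged FALSE when the truncated series hit its term budget
#'   without the increment dropping below tolerance.
#'
#' @aliases RelationMatrices-class
#' @exportClass RelationMatrices
setClass("RelationMatrices",
  representation(D = "matrix", Nm = "matrix", T = "matrix",
                 scale = "numeric", method = "character",
                 converged = "logical"))

setValidity("RelationMatrices", function(object) {
  msgs <- character()
  for (nm in c("D", "Nm")) {
    m <- slot(object, nm)
    if (length(m) && any(m < 0)) msgs <- c(msgs, paste(nm, "must be nonnegative"))
    if (length(m) && any(diag(m) != 0)) msgs <- c(msgs, paste(nm, "diagonal must be zero"))
  }
  if (length(object@Nm) && any(object@Nm > 1 + 1e-12))
    msgs <- c(msgs, "normalized entries must not exceed 1")
  if (length(msgs)) msgs else TRUE
})

#' ImportanceResult: DEMATEL causal parameters and node importance
#'
#' @slot labels node labels.
#' @slot R influence exerted: row sums of the total relation matrix.
#' @slot C influence received: column sums of the total relation matrix.
#' @slot a importance a = R + C.
#' @slot ranking integer permutation ordering nodes by decreasing `a`,
#'   ties broken by ascending label.
#'
#' @aliases ImportanceResult-class
#' @exportClass ImportanceResult
setClass("ImportanceResult",
  representation(labels = "character", R = "numeric", C = "numeric",
                 a = "numeric", ranking = "integer"))

setValidity("ImportanceResult", function(object) {
  n <- length(object@labels)
  if (length(object@R) != n || length(object@C) != n || length(object@a) != n)
    return("R, C and a must have one entry per node")
  if (n == 0) return(TRUE)
  if (max(abs(object@a - (object@R + object@C))) > 1e-12 * max(1, max(abs(object@a))))
    return("a must equal R + C")
  if (!identical(sort(object@ranking), seq_len(n)))
    return("ranking must be a permutation of the node indices")
  TRUE
})

#' SIConfig: parameters of the discrete-time SI simulation
#'
#' @slot beta per-contact infection probability per step, in [0, 1].
#' @slot steps number of synchronous update steps (the "simulation time").
#' @slot runs number of independent repetitions per seed node.
#' @slot seed master RNG seed; per-(seed node, run) streams are derived
#'   from it so results do not depend on iteration order.
#'
#' @aliases SIConfig-class
#' @exportClass SIConfig
setClass("SIConfig",
  representation(beta = "numeric", steps = "integer",
                 runs = "integer", seed = "integer"))

setValidity("SIConfig", function(object) {
  if (length(object@beta) != 1L || is.na(object@beta) ||
      object@beta < 0 || object@beta > 1)
    return("beta must be a single probability in [0, 1]")
  if (object@steps < 1L) return("steps must be >= 1")
  if (object@runs < 1L) return("runs must be >= 1")
  TRUE
})

#' SpreadResult: SI infection curves and spreading capacity
#'
#' @slot seeds seed node labels.
#' @slot curves list, one runs x (steps+1) matrix of cumulative infected
#'   counts per seed (column 1 is the initial state, always 1).
#' @slot meanCurves matrix seeds x (steps+1): per-seed mean curve over runs.
#' @slot capacity named numeric: mean final infected count per seed node
#'   ("average infected nodes", seed included).
#' @slot config the [SIConfig-class] used.
#'
#' @aliases SpreadResult-class
#' @exportClass SpreadResult
setClass("SpreadResult",
  representation(seeds = "character", curves = "list",
                 meanCurves = "matrix", capacity = "numeric",
                 config = "SIConfig"))

setValidity("SpreadResult", function(object) {
  if (length(object@curves) != length(object@seeds))
    return("one curve matrix per seed required")
  for (m in object@curves) {
    if (any(m[, 1] != 1)) return("every run must start with 1 infected node")
    if (ncol(m) > 1 && any(m[, -1, drop = FALSE] < m[, -ncol(m), drop = FALSE]))
      return("cumulative infected counts must be non-decreasing")
  }
  TRUE
})

#' TauResult: Kendall rank-correlation statistic
#'
#' @slot tau the statistic. Range [-1, 1] for `tau_a`/`tau_b`; the
#'   `paper` variant divides by n(n-1) instead of n(n-1)/2 and so lives in
#'   [-0.5, 0.5].
#' @slot concordant number of concordant (positive) pairs.
#' @slot discordant number of discordant (negative) pairs.
#' @slot n sequence length.
#' @slot variant one of `"tau_b"`, `"tau_a"`, `"paper"`.
#'
#' @aliases TauResult-class
#' @exportClass TauResult
setClass("TauResult",
  representation(tau = "numeric", concordant = "numeric",
                 discordant = "numeric", n = "integer", variant = "character"))

setValidity("TauResult", function(object) {
  if (object@concordant + object@discordant > object@n * (object@n - 1) / 2)
    return("concordant + discordant cannot exceed the number of pairs")
  TRUE
})
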