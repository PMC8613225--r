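#' @include AllClasses.R
NULL

#' Number of nodes
#' @param x a [SpreaderGraph-class]
#' @return integer node count
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' Number of edges (unordered adjacent pairs)
#' @param x a [SpreaderGraph-class]
#' @return integer edge count
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Node labels
#' @param x a [SpreaderGraph-class] or result object
#' @return character vector of labels
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' Adjacency matrix
#' @param x a [SpreaderGraph-class]
#' @return symmetric 0/1 matrix with labels as dimnames
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' Per-node scores of a result
#' @param x a [CentralityResult-class] or [ImportanceResult-class]
#' @param ... unused
#' @return named numeric vector
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' Spreading capacity (mean final infected count per seed)
#' @param x a [SpreadResult-class]
#' @return named numeric vector
#' @export
setGeneric("capacity", function(x) standardGeneric("capacity"))

#' Convert a result to a score table
#'
#' Rows are ordered by descending score with ties broken by ascending
#' label; ranks are the 1-based positions in that order.
#'
#' @param x a [CentralityResult-class] or [ImportanceResult-class]
#' @param ... unused
#' @return data.frame with columns node, method, score, rank
#' @export
setGeneric("scoreTable", function(x, ...) standardGeneric("scoreTable"))
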