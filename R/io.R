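#' @include graph.R
NULL

## turn a path / single string with newlines / character vector into lines
.asLines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  } else if (length(x) == 1) {
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  }
  sub("\r$", "", x)
}

#' Read a Pajek .net network file
#'
#' Recognizes `*Vertices`, `*Edges`, `*Arcs`, `*Edgeslist` and `*Arcslist`
#' sections (case-insensitive); any other section is skipped with a
#' warning. Arcs are symmetrized to undirected edges and trailing edge
#' weights are ignored. Vertex labels come from the quoted names in the
#' `*Vertices` section, falling back to the 1-based vertex number as a
#' string.
#'
#' @param file path to a .net file, or the file content as a single
#'   string / character vector of lines.
#' @return a [SpreaderGraph-class]
#' @export
readPajek <- function(file) {
  lines <- .asLines(file)
  lines <- lines[trimws(lines) != ""]
  headers <- grep("^\\s*\\*", lines)
  if (!length(headers)) stop("Pajek format error: no *Vertices section")
  first <- tolower(trimws(lines[headers[1]]))
  if (!grepl("^\\*vertices", first))
    stop("Pajek format error: file must start with a *Vertices section")
  nv <- suppressWarnings(as.integer(sub("^\\*vertices\\s+(\\d+).*$", "\\1", first)))
  if (is.na(nv)) stop("Pajek format error: *Vertices must declare a count")
  labels <- as.character(seq_len(nv))

  bounds <- c(headers, length(lines) + 1L)
  sections <- lapply(seq_along(headers), function(k) {
    body <- if (headers[k] + 1 <= bounds[k + 1] - 1)
      lines[(headers[k] + 1):(bounds[k + 1] - 1)] else character()
    list(name = tolower(sub("^\\s*\\*(\\S+).*$", "\\1", lines[headers[k]])),
         body = body)
  })

  checkId <- function(id) {
    if (any(is.na(id)) || any(id < 1) || any(id > nv))
      stop("Pajek format error: vertex id out of declared range 1..", nv)
    id
  }

  edges <- list()
  for (sec in sections) {
    body <- trimws(sec$body)
    body <- body[body != ""]
    if (sec$name == "vertices") {
      for (ln in body) {
        id <- checkId(as.integer(sub("^(\\d+).*$", "\\1", ln)))
        m <- regmatches(ln, regexec('^\\d+\\s+"([^"]*)"', ln))[[1]]
        if (length(m) == 2) labels[id] <- m[2]
        else {
          tok <- strsplit(ln, "\\s+")[[1]]
          if (length(tok) >= 2 && !grepl("^[0-9.+-]+$", tok[2]))
            labels[id] <- tok[2]
        }
      }
    } else if (sec$name %in% c("edges", "arcs")) {
      for (ln in body) {
        tok <- strsplit(ln, "[\\s,]+", perl = TRUE)[[1]]
        if (length(tok) < 2) stop("Pajek format error: bad edge line: ", ln)
        ij <- checkId(as.integer(tok[1:2]))   # trailing weights ignored
        edges[[length(edges) + 1L]] <- ij
      }
    } else if (sec$name %in% c("edgeslist", "arcslist")) {
      for (ln in body) {
        tok <- checkId(as.integer(strsplit(ln, "\\s+")[[1]]))
        if (length(tok) >= 2)
          for (j in tok[-1]) edges[[length(edges) + 1L]] <- c(tok[1], j)
      }
    } else {
      warning("Pajek section *", sec$name, " skipped")
    }
  }
  if (anyDuplicated(labels)) {
    warning("duplicate vertex names; falling back to numeric ids")
    labels <- as.character(seq_len(nv))
  }
  em <- if (length(edges)) {
    ij <- do.call(rbind, edges)
    cbind(labels[ij[, 1]], labels[ij[, 2]])
  } else NULL
  spreaderGraph(em, nodes = labels)
}

#' Read a plain edge list
#'
#' Lines hold two whitespace- or comma-separated node labels; a line with
#' a single label introduces an isolated node. `#` starts a comment;
#' blank lines are skipped.
#'
#' @inheritParams readPajek
#' @return a [SpreaderGraph-class]
#' @export
readEdgeList <- function(file) {
  lines <- .asLines(file)
  lines <- sub("#.*$", "", lines)
  edges <- list()
  nodes <- character()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[\\s,]+", perl = TRUE)[[1]]
    tok <- tok[tok != ""]
    if (length(tok) == 0) next
    if (length(tok) == 1) nodes <- c(nodes, tok)
    else if (length(tok) == 2) edges[[length(edges) + 1L]] <- tok
    else stop("edge-list format error at line ", i, ": expected 1 or 2 tokens, got ",
              length(tok))
  }
  spreaderGraph(if (length(edges)) do.call(rbind, edges) else NULL, nodes = nodes)
}

#' Write a graph as a plain edge list
#'
#' Canonical form: one `a b` line per unordered edge (endpoints sorted,
#' rows sorted), then one line per isolated node. `readEdgeList()` is the
#' inverse up to label order.
#'
#' @param g a [SpreaderGraph-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeEdgeList <- function(g, path) {
  stopifnot(is(g, "SpreaderGraph"))
  em <- edgeMatrix(g)
  iso <- setdiff(g@labels, unique(as.vector(em)))
  writeLines(c(if (nrow(em)) paste(em[, 1], em[, 2]), sort(iso)), path)
  invisible(path)
}

#' Write a score table as TSV
#'
#' Columns node, method, score, rank; scores printed with 10 significant
#' digits. Within each method, rows are ordered by descending score with
#' ties in ascending label order.
#'
#' @param table a data.frame with columns node, method, score, rank
#'   (as produced by [scoreTable()]); results from several methods may be
#'   row-bound together.
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeScores <- function(table, path) {
  need <- c("node", "method", "score", "rank")
  if (!all(need %in% names(table)))
    stop("score table must have columns ", paste(need, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("node\tmethod\tscore\trank", con)
  if (nrow(table)) {
    ord <- order(table$method, -table$score, table$node, method = "radix")
    t2 <- table[ord, ]
    writeLines(sprintf("%s\t%s\t%s\t%d", t2$node, t2$method,
                       sprintf("%.10g", t2$score), as.integer(t2$rank)), con)
  }
  invisible(path)
}

#' Read back a TSV score table written by [writeScores()]
#'
#' @param path file path
#' @return data.frame with columns node, method, score, rank
#' @export
readScores <- function(path) {
  utils::read.delim(path, colClasses = c("character", "character",
                                         "numeric", "integer"))
}
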