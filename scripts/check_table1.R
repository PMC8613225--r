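#!/usr/bin/env Rscript
# Compares summary statistics of the three real benchmark networks (Jazz
# musician collaborations, network-science coauthorships, US airline
# routes) against their published reference values. The datasets are not
# redistributed with this package; download the Pajek .net files from the
# Pajek dataset site (http://pajek.imfm.si) and pass them as arguments:
#
#   Rscript scripts/check_table1.R jazz.net ns.net usair.net
#
# Notes: the NS network is taken as the largest connected component of
# the coauthorship graph (n = 379). The published Jazz edge count (2472)
# is inconsistent with its published average degree (27.70 with n = 198
# implies m = 2742) and is therefore not checked.

suppressPackageStartupMessages(library(spreadRank))

reference <- list(
  jazz  = list(n = 198, m = NA,   k = 27.70, d = 2.24),
  ns    = list(n = 379, m = 914,  k = 4.82,  d = 6.04),
  usair = list(n = 332, m = 2126, k = 12.81, d = 2.74))

paths <- commandArgs(trailingOnly = TRUE)
if (length(paths) != 3)
  stop("usage: check_table1.R <jazz.net> <ns.net> <usair.net>")

largestComponent <- function(g) {
  comp <- connectedComponents(g)
  keep <- comp[[which.max(lengths(comp))]]
  em <- edgeMatrix(g)
  spreaderGraph(em[em[, 1] %in% keep & em[, 2] %in% keep, , drop = FALSE],
                nodes = keep)
}

for (i in seq_along(reference)) {
  name <- names(reference)[i]
  ref <- reference[[i]]
  g <- readPajek(paths[i])
  if (name == "ns") g <- largestComponent(g)
  s <- graphSummary(g)
  cat(sprintf("%-6s n %4d (ref %4d)  m %5d (ref %5s)  k %6.2f (ref %6.2f)  d %5.2f (ref %5.2f)\n",
              name, s$n, ref$n, s$m, as.character(ref$m),
              s$average_degree, ref$k, s$average_distance, ref$d))
}
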