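## TFKO regulatory relation network and modified breadth-first search.

# Internal constructor; dedup = FALSE keeps parallel edges (degree-preserving
# random networks must conserve the degree multiset exactly).
.newRegNet <- function(from, to, dedup = TRUE) {
  if (length(from) != length(to)) stop("from/to length mismatch")
  if (dedup && length(from)) {
    keep <- !duplicated(paste(from, to, sep = "\r"))
    from <- from[keep]; to <- to[keep]
  }
  nodes <- sort(unique(c(from, to)))
  edges <- matrix(c(from, to), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  adj <- lapply(stats::setNames(nodes, nodes), function(n) character(0))
  if (length(from)) {
    sp <- split(to, factor(from, levels = nodes))
    nz <- names(sp)[lengths(sp) > 0L]
    adj[nz] <- lapply(sp[nz], function(s) sort(unique(s)))
  }
  new("RegulatoryNetwork", nodes = nodes, edges = edges, adj = adj)
}

#' Build the TFKO regulatory relation network
#'
#' Adds a directed edge from each TF to each of its regulatory target genes.
#' The node set is the union of all edge endpoints; duplicate input edges
#' are collapsed.
#'
#' @param edges data.frame with columns `from` (TF) and `to` (target gene),
#'   e.g. from [readEdgeList()].
#' @return a [RegulatoryNetwork-class] object.
#' @examples
#' net <- buildNetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
#' numNodes(net)  # 3
#' numEdges(net)  # 2
#' @export
buildNetwork <- function(edges) {
  .newRegNet(as.character(edges$from), as.character(edges$to), dedup = TRUE)
}

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("numNodes", "RegulatoryNetwork", function(object)
  length(object@nodes))

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("numEdges", "RegulatoryNetwork", function(object)
  nrow(object@edges))

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("nodeIds", "RegulatoryNetwork", function(object) object@nodes)

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("edgeTable", "RegulatoryNetwork", function(object)
  data.frame(from = unname(object@edges[, 1L]),
             to = unname(object@edges[, 2L]), row.names = NULL))

setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork with", length(object@nodes), "nodes and",
      nrow(object@edges), "directed edges\n")
  nSelf <- sum(object@edges[, 1L] == object@edges[, 2L])
  if (nSelf) cat("  (", nSelf, " self-loop(s))\n", sep = "")
  invisible(NULL)
})

#' Test for a direct (curated) TFKO regulation edge
#'
#' Direction matters: `hasDirectRegulation(net, tf, gene)` is `TRUE` iff the
#' edge tf -> gene is present. Nodes absent from the network yield `FALSE`.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param tf,gene node identifiers.
#' @return logical scalar.
#' @export
hasDirectRegulation <- function(net, tf, gene) {
  succ <- net@adj[[tf]]
  !is.null(succ) && gene %in% succ
}

#' Shortest regulation path by modified breadth-first search
#'
#' Searches the regulatory relation network for the shortest directed path
#' from `tf` to `gene`: length 1 is the curated TFKO regulation itself;
#' length >= 2 is a deduced hypostatic regulation, i.e. an epistatic
#' regulation cascade through intermediate TFs that can mask the knockout
#' effect of the TF on the gene. The search keeps a visited set and a
#' discovered set and expands discovered nodes first-in-first-out;
#' neighbours are expanded in lexicographic order, so among equal-length
#' shortest paths the lexicographically smallest node sequence is returned
#' (deterministic cascade reporting).
#'
#' @param net a [RegulatoryNetwork-class].
#' @param tf,gene distinct node identifiers. Nodes absent from the network
#'   are treated as isolated (no path) rather than errors, since ChIP tables
#'   contain genes never observed in TFKO data.
#' @param maxDepth maximum path length to search; `Inf` (default) searches
#'   to the network diameter.
#' @return character vector of path nodes from `tf` to `gene` (path length =
#'   number of nodes - 1), or `NULL` if no path exists within `maxDepth`.
#' @examples
#' net <- buildNetwork(data.frame(
#'   from = c("Leu3p", "Msn4p", "Rpn4p", "Yap1p", "Stp1p"),
#'   to   = c("Msn4p", "Rpn4p", "Yap1p", "Stp1p", "BAP2")))
#' shortestRegulationPath(net, "Leu3p", "BAP2")
#' @export
shortestRegulationPath <- function(net, tf, gene, maxDepth = Inf) {
  if (identical(tf, gene))
    stop("self-regulation query (tf == gene) is undefined", call. = FALSE)
  if (!(tf %in% net@nodes) || !(gene %in% net@nodes)) return(NULL)
  adj <- net@adj
  parent <- new.env(parent = emptyenv(), size = length(net@nodes))
  depth <- new.env(parent = emptyenv(), size = length(net@nodes))
  assign(tf, NA_character_, envir = parent)
  assign(tf, 0L, envir = depth)
  queue <- tf
  head <- 1L
  found <- FALSE
  while (head <= length(queue)) {
    cur <- queue[head]; head <- head + 1L
    d <- get(cur, envir = depth)
    if (d + 1L > maxDepth) break  # FIFO: all later nodes are as deep or deeper
    for (nb in adj[[cur]]) {       # lexicographic neighbour order
      if (!exists(nb, envir = parent, inherits = FALSE)) {
        assign(nb, cur, envir = parent)
        assign(nb, d + 1L, envir = depth)
        if (nb == gene) { found <- TRUE; break }
        queue <- c(queue, nb)
      }
    }
    if (found) break
  }
  if (!found) return(NULL)
  path <- gene
  while (!is.na(path[1L]))
    path <- c(get(path[1L], envir = parent), path)
  path[-1L]
}

# RegulatoryNetwork -> igraph, nodes in the stored (sorted) order.
.asIgraph <- function(net) {
  idx <- match(net@edges, net@nodes)
  dim(idx) <- dim(net@edges)
  igraph::make_graph(as.vector(t(idx)), n = length(net@nodes),
                     directed = TRUE)
}
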