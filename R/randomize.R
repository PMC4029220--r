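## Degree-preserving random regulatory networks and per-pair null
## distributions of shortest regulation path lengths.

#' Node frequency sequences of a network's degree sequences
#'
#' Expands the in- and out-degree sequences into node frequency sequences:
#' each node appears out-degree times in `out_seq` and in-degree times in
#' `in_seq` (e.g. an in-degree sequence {3,2,1} over nodes 1,2,3 expands to
#' the in-degree node frequency sequence {1,1,1,2,2,3}). Shuffling both
#' sequences and pairing them position-wise yields a degree-preserving
#' random network. Degrees count parallel edges and self-loops.
#'
#' @param net a [RegulatoryNetwork-class] with at least one edge.
#' @return list with character vectors `out_seq` and `in_seq`, each of
#'   length `numEdges(net)`, nodes in lexicographic order within each
#'   frequency block.
#' @export
degreeFrequencySequences <- function(net) {
  if (nrow(net@edges) == 0L)
    stop("network has no edges; degree sequences undefined", call. = FALSE)
  outDeg <- table(factor(net@edges[, 1L], levels = net@nodes))
  inDeg <- table(factor(net@edges[, 2L], levels = net@nodes))
  list(out_seq = rep(net@nodes, times = as.integer(outDeg)),
       in_seq = rep(net@nodes, times = as.integer(inDeg)))
}

# Shuffle both frequency sequences with the seeded generator and pair them
# position-wise. Returns an integer edge matrix (indices into sorted nodes).
# Shared by sampleRandomNetwork() and nullPathLengths() so both produce the
# identical network for the same seed. The caller's RNG state is untouched.
.shuffledEdges <- function(outIdx, inIdx, seed) {
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(seed)
  m <- length(outIdx)
  cbind(outIdx[sample.int(m)], inIdx[sample.int(m)])
}

#' Sample one degree-preserving random regulatory network
#'
#' Independently permutes the out-degree and in-degree node frequency
#' sequences with the seeded generator and pairs them position-wise into
#' directed edges. Every node keeps its exact in- and out-degree (counting
#' parallel edges and self-loops, which the stub pairing may create; they
#' cannot shorten any inter-node shortest path).
#'
#' @param net a [RegulatoryNetwork-class] with at least one edge.
#' @param seed integer seed for the permutation.
#' @return a [RegulatoryNetwork-class]; parallel edges are retained.
#' @export
sampleRandomNetwork <- function(net, seed) {
  freq <- degreeFrequencySequences(net)
  outIdx <- match(freq$out_seq, net@nodes)
  inIdx <- match(freq$in_seq, net@nodes)
  em <- .shuffledEdges(outIdx, inIdx, seed)
  .newRegNet(net@nodes[em[, 1L]], net@nodes[em[, 2L]], dedup = FALSE)
}

#' Null distributions of shortest path lengths over random networks
#'
#' Generates `R` degree-preserving random networks (network `r` uses seed
#' `seed + r`, so results are reproducible and independent of evaluation
#' order) and records the shortest-path length of every queried (tf, gene)
#' pair in each. Pairs unreachable in a random network are coded with the
#' cap value, keeping the sample size fixed at `R`; the default cap is the
#' node count of `net`.
#'
#' The defaults of downstream callers use R = 10000, which bounds the
#' sampling error of the null mean at roughly 1% with 95% confidence; R is
#' configurable for desk-scale runs.
#'
#' @param net a [RegulatoryNetwork-class] with at least one edge.
#' @param pairs data.frame with columns `tf` and `gene`.
#' @param R number of random networks (>= 2; the one-sample t-test sd is
#'   undefined below that).
#' @param seed integer master seed.
#' @param cap unreachable-pair coding value; `NULL` for `numNodes(net)`.
#' @return a [PathNulls-class] object.
#' @export
nullPathLengths <- function(net, pairs, R, seed, cap = NULL) {
  if (R < 2L) stop("R must be >= 2 (sd undefined otherwise)", call. = FALSE)
  if (nrow(net@edges) == 0L) stop("network has no edges", call. = FALSE)
  tf <- as.character(pairs$tf); gene <- as.character(pairs$gene)
  if (is.null(cap)) cap <- length(net@nodes)
  cap <- as.integer(cap)
  freq <- degreeFrequencySequences(net)
  outIdx <- match(freq$out_seq, net@nodes)
  inIdx <- match(freq$in_seq, net@nodes)
  n <- length(net@nodes)
  # query pairs mapped to node indices; nodes absent from net are never
  # reachable in a degree-preserving resample -> always cap
  srcAll <- match(tf, net@nodes)
  dstAll <- match(gene, net@nodes)
  ok <- !is.na(srcAll) & !is.na(dstAll)
  srcU <- sort(unique(srcAll[ok]))
  dstU <- sort(unique(dstAll[ok]))
  rowOf <- match(srcAll, srcU)
  colOf <- match(dstAll, dstU)
  lengths <- matrix(cap, nrow = length(tf), ncol = R)
  for (r in seq_len(R)) {
    em <- .shuffledEdges(outIdx, inIdx, seed + r)
    g <- igraph::make_graph(as.vector(t(em)), n = n, directed = TRUE)
    d <- igraph::distances(g, v = srcU, to = dstU, mode = "out",
                           algorithm = "unweighted")
    val <- d[cbind(rowOf[ok], colOf[ok])]
    val[!is.finite(val) | val > cap] <- cap
    lengths[ok, r] <- as.integer(val)
  }
  new("PathNulls", tf = tf, gene = gene, lengths = lengths, cap = cap,
      seed = as.integer(seed))
}

#' @rdname PathNulls-class
#' @export
setMethod("nullLengths", "PathNulls", function(object) object@lengths)

#' @rdname PathNulls-class
#' @export
setMethod("nullMean", "PathNulls", function(object)
  rowMeans(object@lengths))

#' @rdname PathNulls-class
#' @export
setMethod("nullSD", "PathNulls", function(object)
  apply(object@lengths, 1L, stats::sd))

#' @rdname PathNulls-class
#' @export
setMethod("nullSize", "PathNulls", function(object) ncol(object@lengths))

#' @rdname PathNulls-class
#' @export
setMethod("nullCap", "PathNulls", function(object) object@cap)

setMethod("show", "PathNulls", function(object) {
  cat("PathNulls:", length(object@tf), "pair(s) x", ncol(object@lengths),
      "degree-preserving random networks (cap ", object@cap, ")\n")
  invisible(NULL)
})
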