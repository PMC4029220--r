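#' @import methods
NULL

#' Directed TFKO regulatory relation network
#'
#' Holds the directed graph built from TF-knockout (TFKO) regulation pairs:
#' an edge runs from a TF to a gene whose expression changes when the TF is
#' deleted or mutated. Node identifiers are opaque, case-sensitive strings.
#' Networks built with [buildNetwork()] carry one edge per distinct
#' (source, target) pair; networks produced by degree-preserving resampling
#' ([sampleRandomNetwork()]) may carry parallel edges and self-loops, which
#' are retained so that the degree multiset is preserved exactly.
#'
#' @slot nodes character vector of node identifiers, lexicographically sorted.
#' @slot edges character matrix with columns `from`, `to`; one row per edge
#'   (parallel edges appear as repeated rows).
#' @slot adj named list mapping each node to its lexicographically sorted,
#'   deduplicated successor set; drives deterministic breadth-first search.
#'
#' @seealso [buildNetwork()], [shortestRegulationPath()],
#'   [sampleRandomNetwork()]
#' @export
setClass("RegulatoryNetwork",
  representation(nodes = "character", edges = "matrix", adj = "list"),
  prototype(
    nodes = character(0),
    edges = matrix(character(0), ncol = 2,
                   dimnames = list(NULL, c("from", "to"))),
    adj = list()
  )
)

setValidity("RegulatoryNetwork", function(object) {
  msgs <- character(0)
  if (ncol(object@edges) != 2L)
    msgs <- c(msgs, "edges must have exactly 2 columns (from, to)")
  if (nrow(object@edges) > 0L &&
      !all(as.vector(object@edges) %in% object@nodes))
    msgs <- c(msgs, "every edge endpoint must be a network node")
  if (is.unsorted(object@nodes, strictly = TRUE))
    msgs <- c(msgs, "nodes must be sorted and unique")
  if (!all(names(object@adj) == object@nodes))
    msgs <- c(msgs, "adjacency must be keyed by the sorted node set")
  if (length(msgs)) msgs else TRUE
})

#' Per-pair null distributions of shortest regulation path lengths
#'
#' One row of `lengths` per queried (TF, gene) pair, one column per
#' degree-preserving random network. Pairs unreachable in a given random
#' network are coded with the cap value (by default the node count of the
#' source network), keeping the sample size fixed at `R` across pairs.
#'
#' @slot tf,gene character vectors, one entry per queried pair.
#' @slot lengths integer matrix, pairs x R, of shortest-path lengths in the
#'   random networks (cap-coded where unreachable).
#' @slot cap integer, the unreachable-coding value.
#' @slot seed integer master seed; random network `r` used seed `seed + r`.
#'
#' @seealso [nullPathLengths()], [nullMean()], [nullSD()]
#' @export
setClass("PathNulls",
  representation(tf = "character", gene = "character", lengths = "matrix",
                 cap = "integer", seed = "integer")
)

setValidity("PathNulls", function(object) {
  msgs <- character(0)
  if (length(object@tf) != length(object@gene))
    msgs <- c(msgs, "tf and gene must have equal length")
  if (nrow(object@lengths) != length(object@tf))
    msgs <- c(msgs, "one row of lengths per queried pair required")
  if (ncol(object@lengths) < 2L)
    msgs <- c(msgs, "at least R = 2 random networks required (sd undefined)")
  if (length(msgs)) msgs else TRUE
})

#' Planted ground truth of a synthetic scenario
#'
#' Returned by [generateScenario()]: the label of every emitted binding
#' record (functional or not), the evidence planted for it (direct TFKO
#' edge, multi-step cascade, spurious decoy edge, or none), the intended
#' cascade chains, the generator parameters, and the paths of the emitted
#' files.
#'
#' @slot truth data.frame with columns `tf`, `gene`, `p_binding`,
#'   `functional` (logical), `evidence` (one of `"direct"`, `"cascade"`,
#'   `"decoy"`, `"none"`), `cascade` (node chain joined by `"->"`, or `NA`).
#' @slot params list echoing the [scenarioParams()] used.
#' @slot files named character vector of emitted file paths.
#' @export
setClass("ScenarioTruth",
  representation(truth = "data.frame", params = "list", files = "character")
)
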