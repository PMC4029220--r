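#' @rdname RegulatoryNetwork-class
#' @param object a `RegulatoryNetwork` or `PathNulls` object
#' @export
setGeneric("numNodes", function(object) standardGeneric("numNodes"))

#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("numEdges", function(object) standardGeneric("numEdges"))

#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))

#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname PathNulls-class
#' @param object a `PathNulls` object
#' @export
setGeneric("nullLengths", function(object) standardGeneric("nullLengths"))

#' @rdname PathNulls-class
#' @export
setGeneric("nullMean", function(object) standardGeneric("nullMean"))

#' @rdname PathNulls-class
#' @export
setGeneric("nullSD", function(object) standardGeneric("nullSD"))

#' @rdname PathNulls-class
#' @export
setGeneric("nullSize", function(object) standardGeneric("nullSize"))

#' @rdname PathNulls-class
#' @export
setGeneric("nullCap", function(object) standardGeneric("nullCap"))

#' @rdname ScenarioTruth-class
#' @param object a `ScenarioTruth` object
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))

#' @rdname ScenarioTruth-class
#' @export
setGeneric("scenarioFiles", function(object) standardGeneric("scenarioFiles"))
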