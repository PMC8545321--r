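#' @rdname PairGraph-class
#' @param object,x a `PairGraph`, `PathwaySet`, `RocTable` or `NetworkReport`
#' @export
setGeneric("numNodes", function(object) standardGeneric("numNodes"))

#' @rdname PairGraph-class
#' @export
setGeneric("numEdges", function(object) standardGeneric("numEdges"))

#' @rdname PairGraph-class
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))

#' @rdname PairGraph-class
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname PairGraph-class
#' @export
setGeneric("graphTransform", function(object) standardGeneric("graphTransform"))

#' @rdname PairGraph-class
#' @export
setGeneric("nodeMap", function(object) standardGeneric("nodeMap"))

#' @rdname PathwaySet-class
#' @param object a `PathwaySet`
#' @export
setGeneric("pathwayScores", function(object) standardGeneric("pathwayScores"))

#' @rdname PathwaySet-class
#' @export
setGeneric("averageCars", function(object) standardGeneric("averageCars"))

#' @rdname PathwaySet-class
#' @export
setGeneric("pathwayNodes", function(object) standardGeneric("pathwayNodes"))

#' @rdname RocTable-class
#' @param object a `RocTable`
#' @export
setGeneric("aucValue", function(object) standardGeneric("aucValue"))

#' @rdname RocTable-class
#' @export
setGeneric("optimalCutoff", function(object) standardGeneric("optimalCutoff"))

#' @rdname RocTable-class
#' @export
setGeneric("youdenMax", function(object) standardGeneric("youdenMax"))

#' @rdname RocTable-class
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))
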