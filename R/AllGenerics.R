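#' @rdname ProteinGraph-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname ProteinGraph-accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname ProteinGraph-accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname ProteinGraph-accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname ProteinGraph-accessors
#' @export
setGeneric("nodeCoords", function(x) standardGeneric("nodeCoords"))

#' @rdname ProteinGraph-accessors
#' @export
setGeneric("contactThreshold", function(x) standardGeneric("contactThreshold"))

#' @rdname ReferenceDatabase-accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname ReferenceDatabase-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname ReferenceDatabase-accessors
#' @export
setGeneric("rawMatrix", function(x) standardGeneric("rawMatrix"))

#' @rdname ReferenceDatabase-accessors
#' @export
setGeneric("normMatrix", function(x) standardGeneric("normMatrix"))

#' @rdname ReferenceDatabase-accessors
#' @export
setGeneric("activeAttributes", function(x) standardGeneric("activeAttributes"))

#' @rdname ReferenceDatabase-accessors
#' @export
setGeneric("activeAttributes<-",
           function(x, value) standardGeneric("activeAttributes<-"))

#' @rdname KnnPrediction-accessors
#' @export
setGeneric("predictedClass", function(x) standardGeneric("predictedClass"))

#' @rdname KnnPrediction-accessors
#' @export
setGeneric("neighborIds", function(x) standardGeneric("neighborIds"))

#' @rdname KnnPrediction-accessors
#' @export
setGeneric("neighborDistances",
           function(x) standardGeneric("neighborDistances"))

#' @rdname KnnPrediction-accessors
#' @export
setGeneric("voteCounts", function(x) standardGeneric("voteCounts"))

#' @rdname LooResult-accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname LooResult-accessors
#' @export
setGeneric("perProtein", function(x) standardGeneric("perProtein"))

#' @rdname RfeResult-accessors
#' @export
setGeneric("eliminationOrder", function(x) standardGeneric("eliminationOrder"))

#' @rdname RfeResult-accessors
#' @export
setGeneric("optimalSubset", function(x) standardGeneric("optimalSubset"))

#' @rdname RfeResult-accessors
#' @export
setGeneric("accuracyTrace", function(x) standardGeneric("accuracyTrace"))

#' @rdname RfeResult-accessors
#' @export
setGeneric("baselineAccuracy", function(x) standardGeneric("baselineAccuracy"))
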