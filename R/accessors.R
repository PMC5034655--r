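#' Accessors for ProteinGraph objects
#'
#' @param x a [ProteinGraph-class] object.
#' @return \code{numNodes}/\code{numEdges} return integers; \code{nodeLabels}
#'   the label vector; \code{adjacency} the symmetric 0/1 matrix;
#'   \code{nodeCoords} the n x 3 coordinate matrix (0 rows when the graph was
#'   not built from coordinates); \code{contactThreshold} the delta in
#'   angstroms (NA for abstract graphs).
#' @name ProteinGraph-accessors
NULL

#' @rdname ProteinGraph-accessors
#' @export
setMethod("numNodes", "ProteinGraph", function(x) nrow(x@adjacency))

#' @rdname ProteinGraph-accessors
#' @export
setMethod("numEdges", "ProteinGraph", function(x) sum(x@adjacency) %/% 2L)

#' @rdname ProteinGraph-accessors
#' @export
setMethod("nodeLabels", "ProteinGraph", function(x) x@nodeLabels)

#' @rdname ProteinGraph-accessors
#' @export
setMethod("adjacency", "ProteinGraph", function(x) x@adjacency)

#' @rdname ProteinGraph-accessors
#' @export
setMethod("nodeCoords", "ProteinGraph", function(x) x@coords)

#' @rdname ProteinGraph-accessors
#' @export
setMethod("contactThreshold", "ProteinGraph", function(x) x@delta)

setMethod("show", "ProteinGraph", function(object) {
  cat("ProteinGraph with", numNodes(object), "nodes and",
      numEdges(object), "edges\n")
  if (!is.na(object@delta))
    cat("  contact threshold:", object@delta, "angstroms\n")
  cat("  labels:", paste(utils::head(unique(object@nodeLabels), 8L),
                         collapse = " "),
      if (length(unique(object@nodeLabels)) > 8L) "..." else "", "\n")
})

#' Accessors for ReferenceDatabase objects
#'
#' @param x a [ReferenceDatabase-class] object.
#' @param value for \code{activeAttributes<-}, an integer vector of attribute
#'   indices to keep active.
#' @name ReferenceDatabase-accessors
NULL

#' @rdname ReferenceDatabase-accessors
#' @export
setMethod("proteinIds", "ReferenceDatabase", function(x) x@proteinIds)

#' @rdname ReferenceDatabase-accessors
#' @export
setMethod("classLabels", "ReferenceDatabase", function(x) {
  stats::setNames(x@classLabels, x@proteinIds)
})

#' @rdname ReferenceDatabase-accessors
#' @export
setMethod("rawMatrix", "ReferenceDatabase", function(x) x@rawMatrix)

#' @rdname ReferenceDatabase-accessors
#' @export
setMethod("normMatrix", "ReferenceDatabase", function(x) x@normMatrix)

#' @rdname ReferenceDatabase-accessors
#' @export
setMethod("activeAttributes", "ReferenceDatabase",
          function(x) x@activeAttributes)

#' @rdname ReferenceDatabase-accessors
#' @export
setReplaceMethod("activeAttributes", "ReferenceDatabase", function(x, value) {
  value <- sort(unique(as.integer(value)))
  x@activeAttributes <- value
  validObject(x)
  x
})

setMethod("show", "ReferenceDatabase", function(object) {
  cat("ReferenceDatabase:", length(object@proteinIds), "proteins,",
      length(unique(object@classLabels)), "classes,",
      length(object@activeAttributes), "of", ncol(object@rawMatrix),
      "attributes active\n")
})

#' Accessors for KnnPrediction objects
#'
#' @param x a [KnnPrediction-class] object.
#' @name KnnPrediction-accessors
NULL

#' @rdname KnnPrediction-accessors
#' @export
setMethod("predictedClass", "KnnPrediction", function(x) x@predictedClass)

#' @rdname KnnPrediction-accessors
#' @export
setMethod("neighborIds", "KnnPrediction", function(x) x@neighborIds)

#' @rdname KnnPrediction-accessors
#' @export
setMethod("neighborDistances", "KnnPrediction",
          function(x) x@neighborDistances)

#' @rdname KnnPrediction-accessors
#' @export
setMethod("voteCounts", "KnnPrediction", function(x) x@voteCounts)

setMethod("show", "KnnPrediction", function(object) {
  cat("KnnPrediction for", object@queryId, "->", object@predictedClass,
      sprintf("(k = %d, %s)\n", object@k, object@distanceMeasure))
  cat("  votes:", paste(names(object@voteCounts), object@voteCounts,
                        sep = ":", collapse = " "), "\n")
})

#' Accessors for evaluation results
#'
#' @param x a [LooResult-class] or [RfeResult-class] object.
#' @name LooResult-accessors
NULL

#' @rdname LooResult-accessors
#' @export
setMethod("accuracy", "LooResult", function(x) x@accuracy)

#' @rdname LooResult-accessors
#' @export
setMethod("perProtein", "LooResult", function(x) x@perProtein)

setMethod("show", "LooResult", function(object) {
  cat(sprintf("Leave-one-out accuracy %.4f over %d proteins (k = %d, %s)\n",
              object@accuracy, nrow(object@perProtein), object@k,
              object@distanceMeasure))
})

#' @name RfeResult-accessors
#' @rdname LooResult-accessors
NULL

#' @rdname LooResult-accessors
#' @export
setMethod("eliminationOrder", "RfeResult", function(x) x@eliminationOrder)

#' @rdname LooResult-accessors
#' @export
setMethod("optimalSubset", "RfeResult", function(x) x@optimalSubset)

#' @rdname LooResult-accessors
#' @export
setMethod("accuracyTrace", "RfeResult", function(x) x@accuracyTrace)

#' @rdname LooResult-accessors
#' @export
setMethod("baselineAccuracy", "RfeResult", function(x) x@baselineAccuracy)

setMethod("show", "RfeResult", function(object) {
  cat(sprintf(
    "RFE (k = %d, %s): baseline %.4f, %d attributes removed, %d retained\n",
    object@k, object@distanceMeasure, object@baselineAccuracy,
    length(object@eliminationOrder), length(object@optimalSubset)))
})
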