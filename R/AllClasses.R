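#' @import methods
NULL

#' Labeled protein contact graph
#'
#' An undirected, unweighted graph over amino-acid residues. Nodes carry the
#' residue's 3-letter amino-acid label; an edge joins two residues whose
#' alpha-carbon (C-alpha) Euclidean distance is at most the contact threshold
#' \code{delta} (in angstroms, inclusive). Graphs built directly from an
#' adjacency matrix (for descriptor work on abstract labeled graphs) have an
#' empty \code{coords} slot and \code{delta = NA}.
#'
#' @slot adjacency symmetric 0/1 integer matrix with zero diagonal.
#' @slot nodeLabels character vector of node labels, one per node.
#' @slot nodeIds character vector of node identifiers (residue keys or
#'   synthetic indices), unique within the graph.
#' @slot coords numeric matrix with one row per node and columns x, y, z
#'   (angstroms), or a 0-row matrix when the graph is not coordinate-derived.
#' @slot delta numeric contact threshold in angstroms, or \code{NA_real_}.
#'
#' @seealso [buildProteinGraph()], [labeledGraph()], [embedGraph()]
#' @export
setClass("ProteinGraph",
  representation(
    adjacency  = "matrix",
    nodeLabels = "character",
    nodeIds    = "character",
    coords     = "matrix",
    delta      = "numeric"
  )
)

setValidity("ProteinGraph", function(object) {
  A <- object@adjacency
  n <- nrow(A)
  msg <- character()
  if (n < 1L) msg <- c(msg, "graph must have at least one node")
  if (ncol(A) != n) msg <- c(msg, "adjacency must be square")
  if (n >= 1L) {
    if (!all(A %in% c(0L, 1L))) msg <- c(msg, "adjacency entries must be 0/1")
    if (any(diag(A) != 0L)) msg <- c(msg, "self-loops are not allowed")
    if (!isTRUE(all(A == t(A)))) msg <- c(msg, "adjacency must be symmetric")
  }
  if (length(object@nodeLabels) != n)
    msg <- c(msg, "nodeLabels length must equal node count")
  if (any(!nzchar(object@nodeLabels)))
    msg <- c(msg, "node labels must be non-empty")
  if (length(object@nodeIds) != n)
    msg <- c(msg, "nodeIds length must equal node count")
  if (anyDuplicated(object@nodeIds))
    msg <- c(msg, "nodeIds must be unique")
  if (nrow(object@coords) > 0L) {
    if (nrow(object@coords) != n || ncol(object@coords) != 3L)
      msg <- c(msg, "coords must be an n x 3 matrix (or empty)")
    else if (!all(is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
  }
  if (length(object@delta) != 1L)
    msg <- c(msg, "delta must be a single value")
  if (length(msg)) msg else TRUE
})

#' Normalized reference database of descriptor vectors
#'
#' Holds the raw 18-column descriptor matrix of a set of reference proteins,
#' its per-attribute min-max-normalized counterpart used for prediction, the
#' class label of each protein, the normalization statistics needed to map a
#' query onto the same scale, and the subset of attributes currently active
#' (backward feature elimination operates by shrinking this set).
#'
#' @slot proteinIds character, unique row identifiers.
#' @slot rawMatrix numeric matrix, one row per protein, 18 descriptor columns.
#' @slot normMatrix min-max-normalized copy of \code{rawMatrix}; constant raw
#'   columns map to all-zero columns.
#' @slot classLabels character, one class name per protein.
#' @slot attrMin,attrMax per-attribute normalization statistics.
#' @slot attrStd per-attribute standard deviation of the normalized columns
#'   (sample, n-1 denominator), used by the standardized Euclidean measure.
#' @slot activeAttributes integer indices into 1..18 of attributes in use.
#'
#' @seealso [buildReference()], [knnPredict()], [looAccuracy()]
#' @export
setClass("ReferenceDatabase",
  representation(
    proteinIds       = "character",
    rawMatrix        = "matrix",
    normMatrix       = "matrix",
    classLabels      = "character",
    attrMin          = "numeric",
    attrMax          = "numeric",
    attrStd          = "numeric",
    activeAttributes = "integer"
  )
)

setValidity("ReferenceDatabase", function(object) {
  n <- length(object@proteinIds)
  p <- ncol(object@rawMatrix)
  msg <- character()
  if (n < 1L) msg <- c(msg, "database must contain at least one protein")
  if (anyDuplicated(object@proteinIds))
    msg <- c(msg, "protein ids must be unique")
  if (nrow(object@rawMatrix) != n || nrow(object@normMatrix) != n)
    msg <- c(msg, "matrix row counts must equal the number of protein ids")
  if (ncol(object@normMatrix) != p)
    msg <- c(msg, "raw and normalized matrices must have equal column counts")
  if (length(object@classLabels) != n)
    msg <- c(msg, "one class label per protein is required")
  if (length(object@attrMin) != p || length(object@attrMax) != p ||
      length(object@attrStd) != p)
    msg <- c(msg, "normalization statistics must have one entry per attribute")
  if (length(object@activeAttributes) < 1L ||
      any(object@activeAttributes < 1L) || any(object@activeAttributes > p) ||
      anyDuplicated(object@activeAttributes))
    msg <- c(msg, "activeAttributes must be unique indices into the attribute columns")
  if (length(msg)) msg else TRUE
})

#' k-nearest-neighbor prediction for one query structure
#'
#' @slot queryId identifier of the query.
#' @slot predictedClass winning class.
#' @slot neighborIds the k nearest reference ids in ascending distance.
#' @slot neighborDistances matching distances (non-decreasing).
#' @slot voteCounts named integer vector of votes per class; votes sum to k.
#' @slot k number of neighbors used.
#' @slot distanceMeasure name of the distance measure used.
#' @export
setClass("KnnPrediction",
  representation(
    queryId           = "character",
    predictedClass    = "character",
    neighborIds       = "character",
    neighborDistances = "numeric",
    voteCounts        = "integer",
    k                 = "integer",
    distanceMeasure   = "character"
  )
)

setValidity("KnnPrediction", function(object) {
  msg <- character()
  k <- object@k
  if (length(object@neighborIds) != k || length(object@neighborDistances) != k)
    msg <- c(msg, "neighbor ids and distances must have length k")
  if (is.unsorted(object@neighborDistances))
    msg <- c(msg, "neighbor distances must be non-decreasing")
  if (sum(object@voteCounts) != k)
    msg <- c(msg, "votes must sum to k")
  if (length(object@voteCounts) &&
      object@voteCounts[object@predictedClass] != max(object@voteCounts))
    msg <- c(msg, "predicted class must have maximal votes")
  if (length(msg)) msg else TRUE
})

#' Leave-one-out evaluation result
#'
#' @slot accuracy fraction of correctly classified proteins in [0, 1].
#' @slot perProtein data.frame with columns \code{proteinId},
#'   \code{trueClass}, \code{predictedClass}; one row per protein.
#' @slot k,distanceMeasure the classifier settings evaluated.
#' @export
setClass("LooResult",
  representation(
    accuracy        = "numeric",
    perProtein      = "data.frame",
    k               = "integer",
    distanceMeasure = "character"
  )
)

setValidity("LooResult", function(object) {
  msg <- character()
  pp <- object@perProtein
  if (!all(c("proteinId", "trueClass", "predictedClass") %in% names(pp)))
    msg <- c(msg, "perProtein must have proteinId/trueClass/predictedClass")
  else {
    if (anyDuplicated(pp$proteinId))
      msg <- c(msg, "each protein must appear exactly once")
    acc <- mean(pp$trueClass == pp$predictedClass)
    if (abs(acc - object@accuracy) > 1e-12)
      msg <- c(msg, "accuracy must equal the fraction of correct predictions")
  }
  if (length(msg)) msg else TRUE
})

#' Recursive-feature-elimination result
#'
#' Greedy backward elimination over the database's active attributes, guided
#' by leave-one-out accuracy of the k-nearest-neighbor classifier.
#'
#' @slot eliminationOrder integer attribute indices in removal order.
#' @slot optimalSubset attribute indices remaining at the stop.
#' @slot accuracyTrace leave-one-out accuracy after each removal.
#' @slot baselineAccuracy accuracy with the full initial attribute set.
#' @slot k,distanceMeasure classifier settings used throughout.
#' @export
setClass("RfeResult",
  representation(
    eliminationOrder = "integer",
    optimalSubset    = "integer",
    accuracyTrace    = "numeric",
    baselineAccuracy = "numeric",
    k                = "integer",
    distanceMeasure  = "character"
  )
)

setValidity("RfeResult", function(object) {
  msg <- character()
  if (length(intersect(object@eliminationOrder, object@optimalSubset)))
    msg <- c(msg, "eliminated and retained attribute sets must be disjoint")
  if (length(object@accuracyTrace) != length(object@eliminationOrder))
    msg <- c(msg, "one accuracy per removal is required")
  if (length(msg)) msg else TRUE
})

#' Synthetic protein-family specification
#'
#' Parameters of one simulated family: how many structures, the chain-length
#' distribution, the compactness of the simulated fold (how strongly the
#' C-alpha random walk is pulled back onto itself, hence how dense the
#' contact graph is), and the amino-acid composition.
#'
#' @slot familyName class label attached to every generated structure.
#' @slot nStructures number of structures to generate.
#' @slot nResiduesMean,nResiduesSd chain-length distribution (residues).
#' @slot compactness in [0, 1]; 0 = extended, 1 = maximally globular.
#' @slot labelWeights named probability vector over the 20 standard residues.
#' @slot seed integer seed for this family's pseudo-random stream.
#' @seealso [familySpec()], [generateFamily()]
#' @export
setClass("FamilySpec",
  representation(
    familyName   = "character",
    nStructures  = "integer",
    nResiduesMean = "numeric",
    nResiduesSd  = "numeric",
    compactness  = "numeric",
    labelWeights = "numeric",
    seed         = "integer"
  )
)

setValidity("FamilySpec", function(object) {
  msg <- character()
  if (object@nStructures < 1L) msg <- c(msg, "nStructures must be >= 1")
  if (object@nResiduesMean < 3) msg <- c(msg, "nResiduesMean must be >= 3")
  if (object@nResiduesSd < 0) msg <- c(msg, "nResiduesSd must be >= 0")
  if (object@compactness < 0 || object@compactness > 1)
    msg <- c(msg, "compactness must lie in [0, 1]")
  w <- object@labelWeights
  if (is.null(names(w)) || any(!nzchar(names(w))))
    msg <- c(msg, "labelWeights must be named by residue code")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    msg <- c(msg, "labelWeights must be a probability distribution")
  if (length(msg)) msg else TRUE
})
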