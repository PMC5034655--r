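#' Build a C-alpha contact graph from residue records
#'
#' Nodes are residues (labeled by amino-acid type); an undirected edge joins
#' residues i and j (i != j) whenever the Euclidean distance between their
#' C-alpha atoms is less than or equal to \code{delta}. The threshold is
#' inclusive: a pair at exactly \code{delta} angstroms is an edge.
#' Consecutive backbone residues (about 3.8 angstroms apart) are therefore
#' always linked at the default threshold. No other edge rule is applied, so
#' chain breaks can leave the graph disconnected; disconnected graphs are
#' valid input for all descriptors.
#'
#' @param records residue records as returned by [readCalpha()].
#' @param delta contact threshold in angstroms (default 7.0).
#' @return a [ProteinGraph-class].
#' @examples
#' rec <- data.frame(chain = "A", resno = 1:3, insert = "",
#'                   resid = c("ALA", "GLY", "SER"),
#'                   x = 0, y = 0, z = c(0, 3.8, 7.6))
#' g <- buildProteinGraph(rec, delta = 7)
#' numEdges(g)  # 1-2 and 2-3 only: 1-3 is 7.6 A apart
#' @export
buildProteinGraph <- function(records, delta = 7.0) {
  .checkRecords(records)
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0)
    stop("delta must be a single positive number (angstroms)")
  xyz <- as.matrix(records[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  n <- nrow(xyz)
  D <- as.matrix(stats::dist(xyz, method = "euclidean"))
  A <- (D <= delta) * 1L
  diag(A) <- 0L
  storage.mode(A) <- "integer"
  dimnames(A) <- NULL
  ids <- paste0(records$chain, records$resno,
                ifelse(records$insert == "", "", records$insert))
  methods::new("ProteinGraph",
               adjacency = A,
               nodeLabels = as.character(records$resid),
               nodeIds = ids,
               coords = xyz,
               delta = delta)
}

#' Construct a labeled graph directly from an adjacency matrix
#'
#' For descriptor work on abstract labeled graphs (no coordinates). The
#' matrix is coerced to symmetric 0/1 with a zero diagonal; any nonzero
#' entry becomes an edge.
#'
#' @param adjacency square matrix; nonzero entries mark edges.
#' @param labels node labels, recycled if a single value; default "ALA".
#' @param nodeIds optional node identifiers (default "n1", "n2", ...).
#' @return a [ProteinGraph-class] with empty coordinates and delta = NA.
#' @examples
#' k4 <- labeledGraph(matrix(1, 4, 4))
#' numEdges(k4)  # 6
#' @export
labeledGraph <- function(adjacency, labels = "ALA", nodeIds = NULL) {
  A <- as.matrix(adjacency)
  n <- nrow(A)
  if (n < 1L || ncol(A) != n) stop("adjacency must be a square matrix")
  A <- (A != 0) * 1L
  A <- ((A + t(A)) > 0) * 1L
  diag(A) <- 0L
  storage.mode(A) <- "integer"
  dimnames(A) <- NULL
  labels <- rep_len(as.character(labels), n)
  if (is.null(nodeIds)) nodeIds <- paste0("n", seq_len(n))
  methods::new("ProteinGraph",
               adjacency = A, nodeLabels = labels,
               nodeIds = as.character(nodeIds),
               coords = matrix(numeric(0), 0L, 3L),
               delta = NA_real_)
}

.asIgraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g@adjacency, mode = "undirected",
                                      diag = FALSE)
}
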