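#' Names of the 18 structural and topological attributes
#'
#' The fixed attribute order used by [embedGraph()] and by every
#' [ReferenceDatabase-class] column: node/edge counts, average degree,
#' density, average clustering coefficient, the effective-eccentricity
#' family (mean, diameter, radius), average closeness centrality, the
#' fractions of central nodes and of endpoints, four adjacency-spectrum
#' summaries, and three amino-acid label statistics.
#'
#' @return character vector of length 18.
#' @export
descriptorNames <- function() {
  c("num_nodes", "num_edges", "avg_degree", "density",
    "avg_clustering",
    "avg_eff_eccentricity", "eff_diameter", "eff_radius",
    "avg_closeness", "pct_central", "pct_endpoints",
    "n_distinct_eigenvalues", "spectral_radius",
    "second_largest_eigenvalue", "energy",
    "neighborhood_impurity", "link_impurity", "label_entropy")
}

#' Size, degree and density descriptors
#'
#' @param g a [ProteinGraph-class].
#' @return named numeric vector: \code{num_nodes} |V|, \code{num_edges} |E|,
#'   \code{avg_degree} mean node degree, \code{density}
#'   2|E| / (|V|(|V|-1)); a single-node graph has density 0 by convention.
#' @export
basicDescriptors <- function(g) {
  stopifnot(methods::is(g, "ProteinGraph"))
  A <- g@adjacency
  n <- nrow(A)
  e <- sum(A) / 2
  deg <- rowSums(A)
  dens <- if (n > 1L) 2 * e / (n * (n - 1)) else 0
  c(num_nodes = n, num_edges = e, avg_degree = mean(deg), density = dens)
}

#' Average clustering coefficient
#'
#' Mean over nodes of c(u) = 2 e_u / (k_u (k_u - 1)), where k_u is the
#' degree of u and e_u the number of edges among its neighbors. Nodes of
#' degree < 2 contribute 0.
#'
#' @param g a [ProteinGraph-class].
#' @return a number in [0, 1].
#' @export
averageClustering <- function(g) {
  stopifnot(methods::is(g, "ProteinGraph"))
  ig <- .asIgraph(g)
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  if (length(cc) == 0L) cc <- 0
  mean(cc)
}

#' Shortest-path descriptors (effective eccentricity family)
#'
#' All quantities use unweighted shortest-path lengths restricted to
#' reachable node pairs ("effective"): the eccentricity of u is the largest
#' distance from u to any node reachable from u (0 for an isolated node);
#' closeness of u is (|V|-1) divided by the sum of distances to reachable
#' nodes (0 for an isolated node). On disconnected graphs closeness can
#' therefore exceed 1; values stay finite on every graph.
#'
#' @param g a [ProteinGraph-class].
#' @return named numeric vector: \code{avg_eff_eccentricity},
#'   \code{eff_diameter} (max eccentricity), \code{eff_radius} (min
#'   eccentricity), \code{avg_closeness}, \code{pct_central} (fraction of
#'   nodes whose eccentricity equals the effective radius),
#'   \code{pct_endpoints} (fraction of degree-1 nodes).
#' @export
pathDescriptors <- function(g) {
  stopifnot(methods::is(g, "ProteinGraph"))
  A <- g@adjacency
  n <- nrow(A)
  if (n == 1L) {
    return(c(avg_eff_eccentricity = 0, eff_diameter = 0, eff_radius = 0,
             avg_closeness = 0, pct_central = 1, pct_endpoints = 0))
  }
  D <- igraph::distances(.asIgraph(g))
  diag(D) <- NA_real_
  reach <- is.finite(D)
  ecc <- apply(D, 1L, function(d) {
    d <- d[is.finite(d)]
    if (length(d)) max(d) else 0
  })
  dsum <- rowSums(D * reach, na.rm = TRUE)
  clo <- ifelse(dsum > 0, (n - 1) / dsum, 0)
  rad <- min(ecc)
  c(avg_eff_eccentricity = mean(ecc),
    eff_diameter = max(ecc),
    eff_radius = rad,
    avg_closeness = mean(clo),
    pct_central = mean(ecc == rad),
    pct_endpoints = mean(rowSums(A) == 1))
}

#' Adjacency-spectrum descriptors
#'
#' Eigenvalues of the symmetric 0/1 adjacency matrix. Distinctness is
#' decided with an absolute tolerance of 1e-8 on the sorted spectrum
#' (floating-point eigenvalues of equal analytic value are never exactly
#' equal). The second-largest eigenvalue is taken from the descending
#' sorted multiset with multiplicity (a 1-node graph reports 0 by
#' convention). Energy is the sum of squared eigenvalues, which for a
#' simple graph equals trace(A^2) = 2|E|.
#'
#' @param g a [ProteinGraph-class].
#' @return named numeric vector: \code{n_distinct_eigenvalues},
#'   \code{spectral_radius} (largest |eigenvalue|),
#'   \code{second_largest_eigenvalue}, \code{energy}.
#' @export
spectralDescriptors <- function(g) {
  stopifnot(methods::is(g, "ProteinGraph"))
  A <- g@adjacency
  storage.mode(A) <- "double"
  ev <- tryCatch(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e)
                   stop("eigenvalue decomposition failed: ",
                        conditionMessage(e), call. = FALSE))
  ev <- sort(ev, decreasing = TRUE)
  distinct <- if (length(ev) == 1L) 1L else sum(abs(diff(ev)) > 1e-8) + 1L
  second <- if (length(ev) >= 2L) ev[2L] else 0
  c(n_distinct_eigenvalues = distinct,
    spectral_radius = max(abs(ev)),
    second_largest_eigenvalue = second,
    energy = sum(ev^2))
}

#' Amino-acid label descriptors
#'
#' \code{neighborhood_impurity} averages over nodes the number of distinct
#' labels found in the node's neighborhood that differ from the node's own
#' label (set semantics). Set \code{neighborImpurity = "count"} to count
#' differing neighbors instead of distinct differing labels.
#' \code{link_impurity} is the fraction of edges whose endpoints carry
#' different labels (0 when the graph has no edges). \code{label_entropy}
#' is the Shannon entropy, in bits, of the node-label distribution.
#'
#' @param g a [ProteinGraph-class].
#' @param neighborImpurity \code{"distinct"} (default) or \code{"count"}.
#' @return named numeric vector: \code{neighborhood_impurity},
#'   \code{link_impurity}, \code{label_entropy}.
#' @export
labelDescriptors <- function(g, neighborImpurity = c("distinct", "count")) {
  stopifnot(methods::is(g, "ProteinGraph"))
  neighborImpurity <- match.arg(neighborImpurity)
  A <- g@adjacency
  L <- g@nodeLabels
  n <- nrow(A)
  imp <- vapply(seq_len(n), function(u) {
    nb <- L[A[u, ] == 1L]
    nb <- nb[nb != L[u]]
    if (neighborImpurity == "distinct") length(unique(nb)) else length(nb)
  }, numeric(1))
  ij <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  linkImp <- if (nrow(ij)) mean(L[ij[, 1L]] != L[ij[, 2L]]) else 0
  p <- table(L) / n
  entropy <- -sum(ifelse(p > 0, p * log2(p), 0))
  c(neighborhood_impurity = mean(imp),
    link_impurity = linkImp,
    label_entropy = entropy)
}

#' Embed a protein graph as an 18-dimensional descriptor vector
#'
#' Concatenates the five descriptor groups in the fixed order given by
#' [descriptorNames()]. The embedding is deterministic and invariant under
#' node permutations (graph isomorphism on labeled graphs).
#'
#' @param g a [ProteinGraph-class].
#' @param neighborImpurity passed to [labelDescriptors()].
#' @return named numeric vector of length 18.
#' @examples
#' k3 <- labeledGraph(matrix(1, 3, 3))
#' embedGraph(k3)["energy"]  # 2 * |E| = 6
#' @export
embedGraph <- function(g, neighborImpurity = "distinct") {
  v <- c(basicDescriptors(g),
         avg_clustering = averageClustering(g),
         pathDescriptors(g),
         spectralDescriptors(g),
         labelDescriptors(g, neighborImpurity = neighborImpurity))
  stopifnot(identical(names(v), descriptorNames()))
  if (!all(is.finite(v))) stop("descriptor vector contains non-finite values")
  v
}
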