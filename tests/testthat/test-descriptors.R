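# hand-derived and closed-form expectations for each descriptor group, then
# randomized cross-checks against the brute-force oracles in the helpers

test_that("size/degree/density descriptors on canonical graphs", {
  expect_equal(unname(basicDescriptors(labeledGraph(adjComplete(4)))),
               c(4, 6, 3, 1))
  expect_equal(unname(basicDescriptors(labeledGraph(adjPath(4)))),
               c(4, 3, 1.5, 0.5))
  expect_equal(unname(basicDescriptors(labeledGraph(matrix(0, 1, 1)))),
               c(1, 0, 0, 0))
})

test_that("average clustering: triangle, star, K4 minus an edge", {
  expect_equal(averageClustering(labeledGraph(adjComplete(3))), 1)
  expect_equal(averageClustering(labeledGraph(adjStar(4))), 0)
  A <- adjComplete(4); A[1, 2] <- A[2, 1] <- 0L
  expect_equal(averageClustering(labeledGraph(A)), 5 / 6)  # c = (2/3,2/3,1,1)
})

test_that("shortest-path descriptors on cycle, path and disconnected graphs", {
  c4 <- pathDescriptors(labeledGraph(adjCycle(4)))
  expect_equal(unname(c4), c(2, 2, 2, 3 / 4, 1, 0))

  p5 <- pathDescriptors(labeledGraph(adjPath(5)))
  expect_equal(unname(p5[c("avg_eff_eccentricity", "eff_diameter",
                           "eff_radius", "pct_central", "pct_endpoints")]),
               c(3.2, 4, 2, 0.2, 0.4))
  expect_equal(unname(p5["avg_closeness"]),
               mean(4 / c(1 + 2 + 3 + 4, 1 + 1 + 2 + 3, 1 + 1 + 2 + 2,
                          1 + 1 + 2 + 3, 1 + 2 + 3 + 4)))

  # two disjoint edges: closeness uses the global |V|-1 numerator over
  # reachable nodes only, so it exceeds 1 on disconnected graphs
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1L
  d <- pathDescriptors(labeledGraph(A))
  expect_equal(unname(d), c(1, 1, 1, 3, 1, 1))
})

test_that("spectral descriptors match known spectra", {
  expect_equal(unname(spectralDescriptors(labeledGraph(adjComplete(4)))),
               c(2, 3, -1, 12))
  expect_equal(unname(spectralDescriptors(labeledGraph(adjPath(2)))),
               c(2, 1, -1, 2))
  expect_equal(unname(spectralDescriptors(labeledGraph(adjCycle(4)))),
               c(3, 2, 0, 8))
})

test_that("analytic spectra of the classic families are reproduced", {
  for (n in c(4, 7, 12)) {
    for (fam in list(list(adjComplete, spectrumComplete),
                     list(adjCycle, spectrumCycle),
                     list(adjPath, spectrumPath),
                     list(adjStar, spectrumStar))) {
      g <- labeledGraph(fam[[1]](n))
      sp <- sort(fam[[2]](n), decreasing = TRUE)
      d <- spectralDescriptors(g)
      expect_equal(unname(d["spectral_radius"]), max(abs(sp)),
                   tolerance = 1e-9)
      expect_equal(unname(d["second_largest_eigenvalue"]), sp[2],
                   tolerance = 1e-9)
      expect_equal(unname(d["energy"]), sum(sp^2), tolerance = 1e-9)
      expect_equal(unname(d["n_distinct_eigenvalues"]),
                   sum(abs(diff(sp)) > 1e-8) + 1)
    }
  }
})

test_that("label descriptors: uniform, two-label edge, mixed triangle", {
  g1 <- labeledGraph(adjComplete(5), labels = "ALA")
  expect_equal(unname(labelDescriptors(g1)), c(0, 0, 0))

  g2 <- labeledGraph(adjPath(2), labels = c("ALA", "GLY"))
  expect_equal(unname(labelDescriptors(g2)), c(1, 1, 1))

  g3 <- labeledGraph(adjComplete(3), labels = c("ALA", "ALA", "GLY"))
  d <- labelDescriptors(g3)
  expect_equal(unname(d["neighborhood_impurity"]), 1)
  expect_equal(unname(d["link_impurity"]), 2 / 3)
  expect_equal(unname(d["label_entropy"]),
               -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3))
})

test_that("neighborhood impurity option switches distinct to neighbor count", {
  # hub ALA with neighbors GLY, GLY, SER: 2 distinct labels, 3 neighbors
  g <- labeledGraph(adjStar(4), labels = c("ALA", "GLY", "GLY", "SER"))
  dDistinct <- labelDescriptors(g, neighborImpurity = "distinct")
  dCount <- labelDescriptors(g, neighborImpurity = "count")
  expect_equal(unname(dDistinct["neighborhood_impurity"]), (2 + 1 + 1 + 1) / 4)
  expect_equal(unname(dCount["neighborhood_impurity"]), (3 + 1 + 1 + 1) / 4)
})

test_that("the K3 embedding matches the entry-by-entry derivation", {
  v <- embedGraph(labeledGraph(adjComplete(3), labels = "ALA"))
  expect_equal(unname(v),
               c(3, 3, 2, 1, 1, 1, 1, 1, 1, 1, 0, 2, 2, -1, 6, 0, 0, 0))
  expect_identical(names(v), descriptorNames())
})

test_that("embedding is deterministic and permutation invariant", {
  for (s in 1:10) {
    g <- generateLabeledGraph(sample(2:30, 1), runif(1, 0.1, 0.9),
                              seed = 300 + s)
    v1 <- embedGraph(g)
    expect_identical(v1, embedGraph(g))
    n <- numNodes(g)
    for (rep in 1:3) {
      perm <- sample(n)
      gp <- labeledGraph(adjacency(g)[perm, perm], nodeLabels(g)[perm])
      expect_equal(embedGraph(gp), v1, tolerance = 1e-9)
    }
  }
})

test_that("descriptors agree with brute-force oracles on random graphs", {
  for (s in 1:25) {
    g <- generateLabeledGraph(sample(1:30, 1), runif(1, 0, 1),
                              seed = 400 + s)
    A <- adjacency(g)
    expect_equal(basicDescriptors(g), oracleBasic(A), tolerance = 1e-12)
    expect_equal(averageClustering(g), oracleClustering(A),
                 tolerance = 1e-12)
    expect_equal(pathDescriptors(g), oraclePath(A), tolerance = 1e-12)
    expect_equal(labelDescriptors(g), oracleLabels(A, nodeLabels(g)),
                 tolerance = 1e-12)
  }
})

test_that("spectrum invariants hold on random graphs", {
  for (s in 1:20) {
    g <- generateLabeledGraph(sample(2:30, 1), runif(1, 0.1, 0.9),
                              seed = 500 + s)
    d <- spectralDescriptors(g)
    ev <- eigen(adjacency(g), symmetric = TRUE, only.values = TRUE)$values
    # energy identity and zero trace
    expect_equal(unname(d["energy"]), 2 * numEdges(g), tolerance = 1e-6)
    expect_lt(abs(sum(ev)), 1e-8)
    # spectral radius bracketed by average and maximum degree
    deg <- rowSums(adjacency(g))
    expect_lte(d[["spectral_radius"]], max(deg) + 1e-9)
    comps <- igraph::components(
      igraph::graph_from_adjacency_matrix(adjacency(g), mode = "undirected"))
    if (comps$no == 1L && numNodes(g) > 1L)
      expect_gte(d[["spectral_radius"]], mean(deg) - 1e-9)
  }
})

test_that("vector invariants: value ranges and eccentricity ordering", {
  for (s in 1:15) {
    g <- generateLabeledGraph(sample(1:25, 1), runif(1, 0, 1),
                              seed = 600 + s)
    v <- embedGraph(g)
    expect_true(all(is.finite(v)))
    inUnit <- v[c("density", "avg_clustering", "pct_central",
                  "pct_endpoints", "link_impurity")]
    expect_true(all(inUnit >= 0 & inUnit <= 1))
    expect_lte(v[["eff_radius"]], v[["avg_eff_eccentricity"]] + 1e-12)
    expect_lte(v[["avg_eff_eccentricity"]], v[["eff_diameter"]] + 1e-12)
    nlab <- length(unique(nodeLabels(g)))
    expect_lte(v[["label_entropy"]], log2(max(nlab, 2)) + 1e-12)
  }
})
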