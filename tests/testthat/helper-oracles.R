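# Independent oracles used to validate descriptors and graph construction.
# These deliberately avoid the code paths of the package (igraph BFS,
# stats::dist, eigen-based shortcuts): Floyd-Warshall for shortest paths,
# explicit loops for triangles/impurities, closed-form spectra for the
# classic graph families.

# all-pairs shortest paths by Floyd-Warshall (Inf when unreachable)
fwDistances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, Dk)
  }
  D
}

oracleBasic <- function(A) {
  n <- nrow(A)
  e <- sum(A) / 2
  c(num_nodes = n, num_edges = e, avg_degree = mean(rowSums(A)),
    density = if (n > 1) 2 * e / (n * (n - 1)) else 0)
}

# clustering coefficient by brute-force neighbor-pair enumeration
oracleClustering <- function(A) {
  n <- nrow(A)
  cu <- numeric(n)
  for (u in seq_len(n)) {
    nb <- which(A[u, ] == 1)
    k <- length(nb)
    if (k < 2) next
    eu <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (A[nb[i], nb[j]] == 1) eu <- eu + 1
    cu[u] <- 2 * eu / (k * (k - 1))
  }
  mean(cu)
}

oraclePath <- function(A) {
  n <- nrow(A)
  D <- fwDistances(A)
  diag(D) <- NA
  ecc <- clo <- numeric(n)
  for (u in seq_len(n)) {
    d <- D[u, ]
    d <- d[!is.na(d) & is.finite(d)]
    ecc[u] <- if (length(d)) max(d) else 0
    clo[u] <- if (length(d) && sum(d) > 0) (n - 1) / sum(d) else 0
  }
  rad <- min(ecc)
  c(avg_eff_eccentricity = mean(ecc), eff_diameter = max(ecc),
    eff_radius = rad, avg_closeness = mean(clo),
    pct_central = mean(ecc == rad),
    pct_endpoints = mean(rowSums(A) == 1))
}

oracleLabels <- function(A, L) {
  n <- nrow(A)
  imp <- numeric(n)
  for (u in seq_len(n)) {
    nb <- L[which(A[u, ] == 1)]
    imp[u] <- length(unique(nb[nb != L[u]]))
  }
  bad <- tot <- 0
  for (u in seq_len(n - 1)) for (v in (u + 1):n) if (A[u, v] == 1) {
    tot <- tot + 1
    if (L[u] != L[v]) bad <- bad + 1
  }
  p <- as.numeric(table(L)) / n
  c(neighborhood_impurity = mean(imp),
    link_impurity = if (tot > 0) bad / tot else 0,
    label_entropy = -sum(p * log2(p)))
}

# closed-form adjacency spectra
spectrumComplete <- function(n) c(n - 1, rep(-1, n - 1))
spectrumCycle <- function(n) 2 * cos(2 * pi * (0:(n - 1)) / n)
spectrumPath <- function(n) 2 * cos((1:n) * pi / (n + 1))
spectrumStar <- function(n) c(sqrt(n - 1), rep(0, n - 2), -sqrt(n - 1))

# adjacency builders for the classic families
adjComplete <- function(n) { A <- matrix(1L, n, n); diag(A) <- 0L; A }
adjCycle <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    A[i, j] <- A[j, i] <- 1L
  }
  A
}
adjPath <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}
adjStar <- function(n) {
  A <- matrix(0L, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1L
  A
}

# exhaustive pairwise contact thresholding (inclusive)
oracleContactEdges <- function(xyz, delta) {
  n <- nrow(xyz)
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= delta) A[i, j] <- A[j, i] <- 1L
  }
  A
}

randomRecords <- function(n, seed, spread = 10) {
  set.seed(seed)
  data.frame(chain = "A", resno = seq_len(n), insert = "",
             resid = sample(c("ALA", "GLY", "SER"), n, replace = TRUE),
             x = runif(n, 0, spread), y = runif(n, 0, spread),
             z = runif(n, 0, spread), stringsAsFactors = FALSE)
}

# descriptor matrix for the RFE studies: the informative coordinates encode
# 2^3 = 8 class centroids as binary codes, so removing any informative
# attribute merges four class pairs at once; `noiseCols` columns carry
# uniform noise that destroys nearest-neighbor separation until eliminated.
# Every class pair differing in one code bit is vulnerable to noise, which
# keeps the elimination pressure on until all noise columns are gone.
rfeFixture <- function(seed = 1, nPerClass = 6, informative = c(1, 5, 9),
                       nAttr = 18, noiseCols = c(3, 7, 11, 14, 16, 18),
                       sdSignal = 0.02) {
  set.seed(seed)
  codes <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  classes <- rep(paste0("C", 1:8), each = nPerClass)
  n <- length(classes)
  raw <- matrix(0.5, n, nAttr)
  for (a in seq_along(informative)) {
    mu <- 0.42 + 0.16 * codes[rep(1:8, each = nPerClass), a]
    raw[, informative[a]] <- mu + rnorm(n, 0, sdSignal)
  }
  for (a in noiseCols) raw[, a] <- runif(n)
  # remaining columns stay exactly constant: min-max maps them to all-zero,
  # so they carry no signal and no noise (any jitter would be stretched to
  # full scale by the normalization)
  referenceFromMatrix(raw, sprintf("p%02d", seq_len(n)), classes)
}
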