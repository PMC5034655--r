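.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Create a synthetic protein-family specification
#'
#' @param familyName class label for the family.
#' @param nStructures number of structures.
#' @param nResiduesMean,nResiduesSd chain-length distribution; defaults sit
#'   in the 160-275 residue range typical of single-domain families.
#' @param compactness in [0, 1]: strength of the attraction pulling the
#'   simulated C-alpha walk back toward its centroid; high values yield
#'   globular, contact-dense folds, low values extended chains.
#' @param labelWeights named probability vector over the 20 standard
#'   residues (default uniform). Missing residues get weight 0.
#' @param seed integer seed; each structure derives its own stream from
#'   (seed, structure index), so partial regeneration is reproducible.
#' @return a [FamilySpec-class].
#' @export
familySpec <- function(familyName, nStructures = 20L, nResiduesMean = 200,
                       nResiduesSd = 15, compactness = 0.5,
                       labelWeights = NULL, seed = 1L) {
  if (is.null(labelWeights))
    labelWeights <- stats::setNames(rep(1 / 20, 20), .AA3)
  w <- stats::setNames(numeric(20), .AA3)
  if (is.null(names(labelWeights)) ||
      !all(names(labelWeights) %in% .AA3))
    stop("labelWeights must be named by standard 3-letter residue codes")
  w[names(labelWeights)] <- labelWeights
  w <- w / sum(w)
  methods::new("FamilySpec",
               familyName = as.character(familyName),
               nStructures = as.integer(nStructures),
               nResiduesMean = as.numeric(nResiduesMean),
               nResiduesSd = as.numeric(nResiduesSd),
               compactness = as.numeric(compactness),
               labelWeights = w,
               seed = as.integer(seed))
}

# one self-avoiding C-alpha walk: fixed 3.8 A virtual bonds, >= 4.0 A
# between non-consecutive residues; `compactness` mixes a pull toward the
# running centroid into the step direction
.selfAvoidingWalk <- function(n, compactness, maxTry = 400L,
                              maxRestart = 25L) {
  bond <- 3.8
  minSep <- 4.0
  unit <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  for (restart in seq_len(maxRestart)) {
    xyz <- matrix(NA_real_, n, 3L)
    xyz[1L, ] <- 0
    dir <- unit(stats::rnorm(3))
    xyz[2L, ] <- xyz[1L, ] + bond * dir
    ok <- TRUE
    for (i in seq_len(n - 2L) + 2L) {
      placed <- FALSE
      centroid <- colMeans(xyz[seq_len(i - 1L), , drop = FALSE])
      for (try in seq_len(maxTry)) {
        noise <- 0.6 + 0.02 * try      # widen the proposal as tries mount
        pull <- unit(centroid - xyz[i - 1L, ])
        d <- unit((1 - compactness) * dir + compactness * pull +
                  noise * stats::rnorm(3))
        cand <- xyz[i - 1L, ] + bond * d
        prev <- xyz[seq_len(i - 2L), , drop = FALSE]
        d2 <- (prev[, 1L] - cand[1L])^2 + (prev[, 2L] - cand[2L])^2 +
              (prev[, 3L] - cand[3L])^2
        if (min(d2) >= minSep^2) {
          xyz[i, ] <- cand
          dir <- d
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xyz)
  }
  stop("self-avoiding walk placement failed after ", maxRestart, " restarts")
}

#' Generate one synthetic protein family
#'
#' Each structure is a self-avoiding 3D random walk with a fixed C-alpha
#' virtual-bond length of 3.8 angstroms (trans-peptide standard) and a
#' minimum non-consecutive separation of 4.0 angstroms; residue labels are
#' drawn from the family's composition. Fully reproducible: structure j of
#' a family uses a pseudo-random stream derived from (seed, j).
#'
#' @param spec a [FamilySpec-class].
#' @return a list with one element per structure:
#'   \code{list(id, records, class)} where \code{records} is a residue
#'   data.frame consumable by [writeCalpha()] and [buildProteinGraph()].
#' @export
generateFamily <- function(spec) {
  stopifnot(methods::is(spec, "FamilySpec"))
  validObject(spec)
  lapply(seq_len(spec@nStructures), function(j) {
    streamSeed <- (spec@seed %% 1000003L) * 2048L + j
    set.seed(streamSeed %% 2147483647L)
    n <- max(3L, as.integer(round(stats::rnorm(1, spec@nResiduesMean,
                                               spec@nResiduesSd))))
    xyz <- .selfAvoidingWalk(n, spec@compactness)
    labels <- sample(names(spec@labelWeights), n, replace = TRUE,
                     prob = spec@labelWeights)
    records <- data.frame(chain = "A", resno = seq_len(n), insert = "",
                          resid = labels,
                          x = round(xyz[, 1L], 3L),
                          y = round(xyz[, 2L], 3L),
                          z = round(xyz[, 3L], 3L),
                          stringsAsFactors = FALSE)
    list(id = sprintf("%s_%03d", spec@familyName, j),
         records = records,
         class = spec@familyName)
  })
}

#' Generate a seeded random labeled graph
#'
#' Erdos-Renyi-style graph for descriptor testing: every unordered node
#' pair becomes an edge independently with probability \code{edgeProb};
#' labels are drawn uniformly from \code{labelAlphabet}.
#'
#' @param nNodes number of nodes (>= 1).
#' @param edgeProb edge probability in [0, 1].
#' @param labelAlphabet candidate node labels.
#' @param seed integer seed; the graph is deterministic given the seed.
#' @return a [ProteinGraph-class] (no coordinates, delta = NA).
#' @export
generateLabeledGraph <- function(nNodes, edgeProb,
                                 labelAlphabet = c("ALA", "GLY", "SER"),
                                 seed = 1L) {
  stopifnot(nNodes >= 1L, edgeProb >= 0, edgeProb <= 1)
  set.seed(as.integer(seed) %% 2147483647L)
  A <- matrix(0L, nNodes, nNodes)
  if (nNodes > 1L) {
    up <- upper.tri(A)
    A[up] <- as.integer(stats::runif(sum(up)) < edgeProb)
    A <- A + t(A)
  }
  labels <- sample(labelAlphabet, nNodes, replace = TRUE)
  labeledGraph(A, labels)
}

#' Simulate a multi-family benchmark dataset
#'
#' Default conditions: four families of 20 structures each whose mean chain
#' lengths (160, 185, 231, 275 residues) span the range of classic
#' single-domain protein-family benchmarks, with increasing fold
#' compactness and distinct amino-acid compositions, so families differ in
#' both geometric (degree/clustering/path) and label (impurity/entropy)
#' descriptor groups.
#'
#' @param seed master integer seed; family f uses seed + f.
#' @param nPerFamily structures per family.
#' @param outDir optional directory: when given, one PDB file per structure
#'   plus a \code{labels.tsv} (columns structure_id, file, class) are
#'   written there.
#' @return invisibly when \code{outDir} is given, else directly: a list of
#'   \code{list(id, records, class)} entries across all families.
#' @export
simulateDataset <- function(seed = 1L, nPerFamily = 20L, outDir = NULL) {
  comp <- function(major, boost = 0.12) {
    w <- stats::setNames(rep((1 - length(major) * boost) / 20, 20), .AA3)
    w[major] <- w[major] + boost
    w / sum(w)
  }
  fams <- list(
    familySpec("extended",    nPerFamily, 160, 12, compactness = 0.15,
               labelWeights = comp(c("GLY", "SER", "PRO")),
               seed = seed + 1L),
    familySpec("loose",       nPerFamily, 185, 12, compactness = 0.40,
               labelWeights = comp(c("LYS", "GLU", "ASP")),
               seed = seed + 2L),
    familySpec("globular",    nPerFamily, 231, 12, compactness = 0.65,
               labelWeights = comp(c("LEU", "ILE", "VAL")),
               seed = seed + 3L),
    familySpec("compact",     nPerFamily, 275, 12, compactness = 0.85,
               labelWeights = comp(c("ALA", "TRP", "PHE")),
               seed = seed + 4L)
  )
  dataset <- do.call(c, lapply(fams, generateFamily))
  if (is.null(outDir)) return(dataset)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset, function(s) {
    f <- file.path(outDir, paste0(s$id, ".pdb"))
    writeCalpha(s$records, f)
    data.frame(structure_id = s$id, file = basename(f), class = s$class,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), file.path(outDir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

#' Build a reference database from a simulated or on-disk dataset
#'
#' Convenience wrapper: embeds every structure's contact graph at the given
#' threshold and assembles the normalized reference database.
#'
#' @param dataset list of \code{list(id, records, class)} entries, as
#'   returned by [simulateDataset()] or [generateFamily()].
#' @param delta contact threshold in angstroms.
#' @return a [ReferenceDatabase-class].
#' @export
referenceFromDataset <- function(dataset, delta = 7.0) {
  graphs <- lapply(dataset, function(s) buildProteinGraph(s$records, delta))
  buildReference(graphs,
                 classes = vapply(dataset, `[[`, character(1), "class"),
                 ids = vapply(dataset, `[[`, character(1), "id"))
}
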