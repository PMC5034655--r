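.DB_FORMAT_VERSION <- "ContactGraphKNN-db-1"

# shared constructor: computes min-max statistics, the normalized matrix and
# the per-attribute standard deviations from a raw descriptor matrix
.makeDatabase <- function(ids, raw, classes, active = NULL) {
  ids <- as.character(ids)
  classes <- as.character(classes)
  if (length(ids) == 0L) stop("reference database cannot be empty")
  if (anyDuplicated(ids)) stop("duplicate protein id: ",
                               ids[duplicated(ids)][1L])
  if (length(classes) != length(ids))
    stop("one class label per protein is required")
  raw <- as.matrix(raw)
  storage.mode(raw) <- "double"
  if (nrow(raw) != length(ids))
    stop("raw matrix must have one row per protein")
  if (!all(is.finite(raw))) stop("descriptor matrix must be finite")
  if (is.null(colnames(raw)) && ncol(raw) == 18L)
    colnames(raw) <- descriptorNames()
  mins <- apply(raw, 2L, min)
  maxs <- apply(raw, 2L, max)
  rng <- maxs - mins
  norm <- sweep(raw, 2L, mins, "-")
  norm <- sweep(norm, 2L, ifelse(rng > 0, rng, 1), "/")
  norm[, rng == 0] <- 0         # constant attributes carry no information
  sds <- if (nrow(norm) > 1L) apply(norm, 2L, stats::sd) else
    rep(0, ncol(norm))
  if (is.null(active)) active <- seq_len(ncol(raw))
  rownames(raw) <- rownames(norm) <- ids
  methods::new("ReferenceDatabase",
               proteinIds = ids, rawMatrix = raw, normMatrix = norm,
               classLabels = classes,
               attrMin = stats::setNames(mins, colnames(raw)),
               attrMax = stats::setNames(maxs, colnames(raw)),
               attrStd = stats::setNames(sds, colnames(raw)),
               activeAttributes = as.integer(active))
}

#' Build a normalized reference database from labeled protein graphs
#'
#' Embeds every graph with [embedGraph()] and min-max-normalizes each of the
#' 18 attribute columns independently, x' = (x - min) / (max - min), so that
#' no attribute dominates the distance computation. A constant column maps
#' to all zeros. The per-attribute normalized standard deviation (sample,
#' n-1 denominator) is stored for the standardized Euclidean measure.
#'
#' @param graphs a list of [ProteinGraph-class] objects; its names are used
#'   as protein ids when \code{ids} is missing.
#' @param classes character vector of class labels, one per graph.
#' @param ids optional character vector of unique protein ids.
#' @return a [ReferenceDatabase-class].
#' @seealso [referenceFromMatrix()], [addProtein()], [knnPredict()]
#' @export
buildReference <- function(graphs, classes, ids = names(graphs)) {
  if (!is.list(graphs) || !length(graphs))
    stop("graphs must be a non-empty list of ProteinGraph objects")
  if (!all(vapply(graphs, methods::is, logical(1), "ProteinGraph")))
    stop("every element of graphs must be a ProteinGraph")
  if (is.null(ids)) ids <- paste0("protein", seq_along(graphs))
  raw <- t(vapply(graphs, embedGraph, numeric(18L)))
  .makeDatabase(ids, raw, classes)
}

#' Build a reference database from a precomputed descriptor matrix
#'
#' Lower-level companion of [buildReference()] for workflows that already
#' hold raw descriptor rows (persisted runs, simulation studies, attribute
#' ablation experiments).
#'
#' @param raw numeric matrix, one row per protein; 18 columns in
#'   [descriptorNames()] order (other widths are accepted for synthetic
#'   studies and keep their own column names).
#' @param ids unique protein ids.
#' @param classes class labels, one per row.
#' @return a [ReferenceDatabase-class].
#' @export
referenceFromMatrix <- function(raw, ids, classes) {
  .makeDatabase(ids, raw, classes)
}

#' Normalize a query descriptor vector with a database's statistics
#'
#' Applies the stored per-attribute min-max mapping. Values outside the
#' reference range are kept (possibly < 0 or > 1): clipping would destroy
#' the distance ordering for out-of-range queries. Attributes that were
#' constant in the reference map to 0 regardless of the query value.
#'
#' @param query raw descriptor vector (length = number of attribute
#'   columns) or a [ProteinGraph-class] to embed first.
#' @param db a [ReferenceDatabase-class].
#' @return normalized numeric vector.
#' @export
normalizeQuery <- function(query, db) {
  stopifnot(methods::is(db, "ReferenceDatabase"))
  if (methods::is(query, "ProteinGraph")) query <- embedGraph(query)
  v <- as.numeric(query)
  if (length(v) != ncol(db@rawMatrix))
    stop("query vector length must match the database attribute count")
  rng <- db@attrMax - db@attrMin
  out <- (v - db@attrMin) / ifelse(rng > 0, rng, 1)
  out[rng == 0] <- 0
  stats::setNames(out, colnames(db@rawMatrix))
}

#' Incrementally add a protein to a reference database
#'
#' Raw descriptor vectors of existing proteins are untouched; only the
#' cheap normalization pass is redone, so the result is identical to
#' rebuilding the database from scratch over the union.
#'
#' @param db a [ReferenceDatabase-class].
#' @param id new unique protein id.
#' @param x raw descriptor vector or a [ProteinGraph-class].
#' @param classLabel class of the new protein.
#' @return the enlarged [ReferenceDatabase-class].
#' @export
addProtein <- function(db, id, x, classLabel) {
  stopifnot(methods::is(db, "ReferenceDatabase"))
  if (id %in% db@proteinIds) stop("duplicate protein id: ", id)
  if (methods::is(x, "ProteinGraph")) x <- embedGraph(x)
  x <- as.numeric(x)
  if (length(x) != ncol(db@rawMatrix))
    stop("descriptor vector length must match the database")
  raw <- rbind(db@rawMatrix, x)
  .makeDatabase(c(db@proteinIds, id), raw, c(db@classLabels, classLabel),
                active = db@activeAttributes)
}

#' Persist a reference database as plain-text tables
#'
#' Writes a directory containing the raw descriptor matrix, the class
#' labels, the normalization statistics and a format-version stamp, all as
#' TSV. [loadReference()] reconstructs an identical database (the
#' normalized matrix is recomputed from the raw matrix and checked against
#' the stored statistics).
#'
#' @param db a [ReferenceDatabase-class].
#' @param path directory to create (or overwrite).
#' @return invisibly, \code{path}.
#' @export
saveReference <- function(db, path) {
  stopifnot(methods::is(db, "ReferenceDatabase"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeLines(.DB_FORMAT_VERSION, file.path(path, "VERSION"))
  # %.17g keeps doubles bit-exact through the text round-trip
  rawChr <- apply(db@rawMatrix, 2L, function(col) sprintf("%.17g", col))
  if (is.null(dim(rawChr))) rawChr <- matrix(rawChr, nrow = 1L)
  colnames(rawChr) <- colnames(db@rawMatrix)
  raw <- data.frame(protein_id = db@proteinIds, rawChr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(raw, file.path(path, "raw_vectors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lab <- data.frame(protein_id = db@proteinIds, class = db@classLabels)
  utils::write.table(lab, file.path(path, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stats <- data.frame(attribute = colnames(db@rawMatrix),
                      min = sprintf("%.17g", db@attrMin),
                      max = sprintf("%.17g", db@attrMax),
                      std = sprintf("%.17g", db@attrStd),
                      stringsAsFactors = FALSE)
  utils::write.table(stats, file.path(path, "stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(paste(db@activeAttributes, collapse = "\t"),
             file.path(path, "active_attributes.tsv"))
  invisible(path)
}

#' @rdname saveReference
#' @param strict if TRUE (default), fail when the stored normalization
#'   statistics disagree with the raw matrix (truncated or edited files).
#' @export
loadReference <- function(path, strict = TRUE) {
  need <- c("VERSION", "raw_vectors.tsv", "labels.tsv", "stats.tsv",
            "active_attributes.tsv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("not a reference database (missing ",
         paste(missing, collapse = ", "), "): ", path)
  ver <- readLines(file.path(path, "VERSION"), n = 1L)
  if (!identical(ver, .DB_FORMAT_VERSION))
    stop("unsupported reference-database version: ", ver)
  raw <- utils::read.table(file.path(path, "raw_vectors.tsv"), sep = "\t",
                           header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  lab <- utils::read.table(file.path(path, "labels.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  stats <- utils::read.table(file.path(path, "stats.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  if (!identical(raw$protein_id, lab$protein_id))
    stop("corrupt reference database: id mismatch between tables")
  active <- as.integer(strsplit(
    readLines(file.path(path, "active_attributes.tsv"), n = 1L),
    "\t", fixed = TRUE)[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (anyNA(m)) stop("corrupt reference database: non-numeric raw vectors")
  db <- .makeDatabase(raw$protein_id, m, lab$class, active = active)
  if (strict) {
    ok <- isTRUE(all.equal(unname(db@attrMin), stats$min, tolerance = 1e-9)) &&
      isTRUE(all.equal(unname(db@attrMax), stats$max, tolerance = 1e-9))
    if (!ok)
      stop("corrupt reference database: stored statistics do not match data")
  }
  db
}
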