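#' Read the alpha-carbon trace of a legacy PDB file
#'
#' Extracts one residue record per amino acid that carries exactly one
#' retained C-alpha atom. Only \code{ATOM} records with atom name \code{CA}
#' are considered: \code{HETATM} records (waters, ligands, and in particular
#' the calcium ion, whose atom name is also \code{CA}) never become nodes.
#' In multi-model files only the requested model (default: first) is read.
#' When a residue has alternate locations, the highest-occupancy C-alpha is
#' retained; occupancy ties go to the alphabetically first altloc code.
#' Selenomethionine (\code{MSE}) is relabeled \code{MET}; other nonstandard
#' residues keep their 3-letter code verbatim. Residues without a C-alpha
#' are skipped with a warning.
#'
#' @param file path to a legacy PDB-format file.
#' @param chains optional character vector restricting to these chain ids.
#' @param model 1-based model index for multi-model files.
#' @return a \code{data.frame} of residue records, in file order, with
#'   columns \code{chain} (character), \code{resno} (integer, author
#'   numbering), \code{insert} (character, \code{""} when absent),
#'   \code{resid} (3-letter amino-acid label), and C-alpha coordinates
#'   \code{x}, \code{y}, \code{z} in angstroms.
#' @examples
#' fam <- familySpec("demo", nStructures = 1, nResiduesMean = 10,
#'                   nResiduesSd = 0, seed = 1)
#' s <- generateFamily(fam)[[1]]
#' f <- tempfile(fileext = ".pdb")
#' writeCalpha(s$records, f)
#' head(readCalpha(f))
#' @seealso [writeCalpha()], [buildProteinGraph()]
#' @export
readCalpha <- function(file, chains = NULL, model = 1L) {
  if (!file.exists(file)) stop("PDB file not found: ", file)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE, maxlines = -1)),
    error = function(e) stop("failed to parse PDB file '", file, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- pdb$atom
  if (model > 1L) {
    # bio3d stores extra models only in $xyz; re-read keeping all frames
    pdb <- suppressWarnings(bio3d::read.pdb(file, multi = TRUE,
                                            rm.alt = FALSE, verbose = FALSE))
    nmodels <- nrow(pdb$xyz)
    if (is.null(nmodels) || model > nmodels)
      stop("model ", model, " not present in '", file, "'")
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    atoms <- pdb$atom
    atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  }
  ca <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (!is.null(chains)) ca <- ca[ca$chain %in% chains, , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("no amino-acid C-alpha atoms found in '", file, "'")
  bad <- !is.finite(ca$x) | !is.finite(ca$y) | !is.finite(ca$z)
  if (any(bad)) {
    b <- ca[which(bad)[1L], ]
    stop(sprintf(
      "malformed C-alpha coordinates in '%s' at residue %s %s%d%s",
      file, b$resid, b$chain, b$resno,
      ifelse(is.na(b$insert), "", b$insert)))
  }
  chain  <- as.character(ca$chain)
  insert <- ifelse(is.na(ca$insert), "", as.character(ca$insert))
  alt    <- ifelse(is.na(ca$alt), "", as.character(ca$alt))
  occ    <- ifelse(is.na(ca$o), 1, ca$o)
  key    <- paste(chain, ca$resno, insert, sep = "|")

  # altloc resolution: per residue keep max occupancy, ties -> first altloc
  keep <- logical(nrow(ca))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) > 1L) {
      o <- occ[idx]
      idx <- idx[o == max(o)]
      if (length(idx) > 1L) idx <- idx[order(alt[idx])][1L]
    }
    keep[idx] <- TRUE
  }
  ca <- ca[keep, , drop = FALSE]
  ord <- order(match(rownames(ca), rownames(atoms)))  # preserve file order
  ca <- ca[ord, , drop = FALSE]

  resid <- as.character(ca$resid)
  resid[resid == "MSE"] <- "MET"
  out <- data.frame(
    chain  = as.character(ca$chain),
    resno  = as.integer(ca$resno),
    insert = ifelse(is.na(ca$insert), "", as.character(ca$insert)),
    resid  = resid,
    x = ca$x, y = ca$y, z = ca$z,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write residue records as a legacy PDB alpha-carbon trace
#'
#' Emits one fixed-width \code{ATOM} line per record (coordinates to three
#' decimals), terminated by \code{TER}/\code{END}, such that
#' \code{readCalpha()} round-trips the records to within 0.001 angstrom.
#'
#' @param records a residue-record \code{data.frame} as returned by
#'   [readCalpha()] (columns chain, resno, insert, resid, x, y, z).
#' @param file output path.
#' @return invisibly, the output path.
#' @export
writeCalpha <- function(records, file) {
  .checkRecords(records)
  xyz <- as.matrix(records[, c("x", "y", "z")])
  if (any(xyz > 9999.999 + 5e-4) || any(xyz < -999.999 - 5e-4))
    stop("coordinate exceeds the fixed-width 8.3 PDB field")
  n <- nrow(records)
  insert <- ifelse(is.na(records$insert) | records$insert == "",
                   " ", substr(records$insert, 1L, 1L))
  chain <- ifelse(is.na(records$chain) | records$chain == "",
                  "A", substr(records$chain, 1L, 1L))
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), substr(records$resid, 1L, 3L), chain,
    records$resno, insert, records$x, records$y, records$z, 1, 0)
  writeLines(c(lines, "TER", "END"), con = file)
  invisible(file)
}

.checkRecords <- function(records) {
  req <- c("chain", "resno", "insert", "resid", "x", "y", "z")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop("records must be a data.frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(records) == 0L)
    stop("records must contain at least one residue")
  if (!all(is.finite(records$x) & is.finite(records$y) &
           is.finite(records$z)))
    stop("residue coordinates must be finite")
  if (any(!nzchar(records$resid)))
    stop("residue labels must be non-empty")
  key <- paste(records$chain, records$resno, records$insert, sep = "|")
  if (anyDuplicated(key))
    stop("(chain, residue number, insertion code) must be unique")
  invisible(TRUE)
}
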