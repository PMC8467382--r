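#' Construct a ConformerEnsemble from coordinates
#'
#' @param atoms data.frame with columns \code{name}, \code{element}, or a
#'   character vector of atom names (elements then inferred from the leading
#'   letters of the name).
#' @param coords numeric array \code{n_atoms x 3 x n_frames} (Angstrom), or a
#'   list of \code{n_atoms x 3} matrices (one per frame).
#' @param frameIds optional integer frame ordinals; defaults to 1..n_frames.
#' @return a \linkS4class{ConformerEnsemble}
#' @examples
#' xyz <- array(rnorm(4 * 3 * 2), dim = c(4, 3, 2))
#' conformerEnsemble(c("C1", "C2", "H1", "H2"), xyz)
#' @export
conformerEnsemble <- function(atoms, coords, frameIds = NULL) {
  if (is.character(atoms))
    atoms <- data.frame(name = atoms, element = elementFromName(atoms),
                        stringsAsFactors = FALSE)
  if (is.list(coords) && !is.array(coords)) {
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 3L, length(coords)))
  }
  if (is.null(frameIds)) frameIds <- seq_len(dim(coords)[3])
  new("ConformerEnsemble", atoms = atoms, coords = coords,
      frameIds = as.integer(frameIds))
}

# heuristic used only when a format carries no explicit element column:
# leading alphabetic characters of the atom name, title-cased
elementFromName <- function(names) {
  el <- sub("^([A-Za-z]+).*$", "\\1", names)
  el <- sub("^([A-Za-z])([A-Za-z]?).*", "\\1\\2", el)
  # single-letter organic-set symbols dominate fragment work; treat a
  # two-letter prefix as one element only if it is a real symbol
  two <- c("Cl", "Br", "Si", "Se", "Na", "Mg", "Ca", "Fe", "Zn")
  first <- toupper(substr(el, 1, 1))
  second <- tolower(substr(el, 2, 2))
  cand <- paste0(first, second)
  ifelse(cand %in% two, cand, first)
}

#' Read a multi-model PDB file as a conformer ensemble
#'
#' One frame per \code{MODEL} record (a file with no MODEL records yields a
#' single-frame ensemble). Atom names are taken from the atom-name column.
#' All models must contain the same atoms in the same order.
#'
#' @param path PDB file path
#' @return a \linkS4class{ConformerEnsemble}
#' @export
readMultimodelPDB <- function(path) {
  if (!file.exists(path))
    vjStop("vicinalJ_format_error", "PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(isAtom))
    vjStop("vicinalJ_format_error",
           "no ATOM/HETATM records in %s (first line: '%s')",
           path, if (length(lines)) lines[1] else "<empty>")
  # pre-scan model structure so a dropped atom is reported cleanly
  modelStart <- grepl("^MODEL", lines)
  if (any(modelStart)) {
    modelIdx <- cumsum(modelStart)
    counts <- table(modelIdx[isAtom])
    if (length(unique(as.integer(counts))) != 1L)
      vjStop("vicinalJ_validation_error",
             "inconsistent atom counts across models in %s: %s",
             path, paste(sprintf("model %s: %s atoms", names(counts),
                                 as.integer(counts)), collapse = ", "))
    names1 <- trimws(substr(lines[isAtom & modelIdx == 1L], 13, 16))
    names2 <- split(trimws(substr(lines[isAtom], 13, 16)), modelIdx[isAtom])
    for (m in names(names2))
      if (!identical(names2[[m]], names1))
        vjStop("vicinalJ_validation_error",
               "atom table of model %s differs from model 1 in %s", m, path)
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    vjStop("vicinalJ_format_error",
                           "failed to parse PDB %s: %s", path,
                           conditionMessage(e)))
  natom <- nrow(pdb$atom)
  xyzMat <- pdb$xyz                       # n_models x 3*n_atoms
  if (is.null(dim(xyzMat))) xyzMat <- matrix(xyzMat, nrow = 1)
  nf <- nrow(xyzMat)
  coords <- array(NA_real_, dim = c(natom, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyzMat[f, ], ncol = 3, byrow = TRUE)
  el <- trimws(pdb$atom$elesy)
  el[!nzchar(el) | is.na(el)] <- NA
  elName <- elementFromName(pdb$atom$elety)
  el <- ifelse(is.na(el), elName,
               paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2))))
  atoms <- data.frame(name = trimws(pdb$atom$elety), element = el,
                      stringsAsFactors = FALSE)
  conformerEnsemble(atoms, coords)
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeMultimodelPDB <- function(ensemble, path) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  at <- ensemble@atoms
  nf <- nFrames(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  fmtName <- function(nm, el) {
    # PDB column 13-16: element right-justified in 13-14 for 1-letter symbols
    ifelse(nchar(nm) <= 3 & nchar(el) == 1, sprintf(" %-3s", nm),
           sprintf("%-4s", substr(nm, 1, 4)))
  }
  nm <- fmtName(at$name, at$element)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", ensemble@frameIds[f]), con)
    xyz <- ensemble@coords[, , f]
    writeLines(sprintf(
      "ATOM  %5d %s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)), nm, xyz[, 1], xyz[, 2], xyz[, 3],
      toupper(at$element)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read concatenated XYZ blocks as a conformer ensemble
#'
#' Standard chemistry XYZ format: each block is a count line, a comment
#' line, then one \code{element x y z} line per atom. Atom names are taken
#' from the symbol column plus a 1-based ordinal per element (C1, C2, H1,
#' ...) unless the symbol column already carries unique labels.
#'
#' @param path file of one or more concatenated XYZ blocks with identical
#'   atom ordering
#' @return a \linkS4class{ConformerEnsemble}
#' @export
readXYZFrames <- function(path) {
  if (!file.exists(path))
    vjStop("vicinalJ_format_error", "XYZ file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines))
    vjStop("vicinalJ_format_error", "empty XYZ file: %s", path)
  frames <- list()
  labels <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      vjStop("vicinalJ_format_error",
             "line %d of %s: expected an atom count, got '%s'", i, path, lines[i])
    if (i + 1L + n > length(lines))
      vjStop("vicinalJ_format_error",
             "line %d of %s: block declares %d atoms but file ends early",
             i, path, n)
    block <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(lengths(tok) < 4L)
    if (length(bad))
      vjStop("vicinalJ_format_error",
             "line %d of %s: malformed coordinate line '%s'",
             i + 1L + bad[1], path, block[bad[1]])
    sym <- vapply(tok, `[[`, character(1), 1L)
    xyz <- matrix(suppressWarnings(as.numeric(
      unlist(lapply(tok, function(t) t[2:4])))), ncol = 3, byrow = TRUE)
    if (any(!is.finite(xyz)))
      vjStop("vicinalJ_format_error",
             "non-numeric coordinates in block starting at line %d of %s",
             i, path)
    if (is.null(labels)) {
      labels <- sym
    } else if (length(sym) != length(labels) || !identical(sym, labels)) {
      vjStop("vicinalJ_validation_error",
             "block starting at line %d of %s has a different atom table",
             i, path)
    }
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (anyDuplicated(labels)) {
    el <- elementFromName(labels)
    ord <- stats::ave(seq_along(el), el, FUN = seq_along)
    names_ <- paste0(labels, ord)
  } else names_ <- labels
  atoms <- data.frame(name = names_, element = elementFromName(labels),
                      stringsAsFactors = FALSE)
  conformerEnsemble(atoms, frames)
}

#' Write a conformer ensemble as concatenated XYZ blocks
#'
#' Coordinates are written with three decimals (the conventional XYZ
#' precision), so a write-read roundtrip preserves coordinates to 1e-3
#' Angstrom.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}
#' @param path output path
#' @param comment comment-line text (frame id is appended)
#' @return \code{path}, invisibly
#' @export
writeXYZFrames <- function(ensemble, path, comment = "frame") {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(ensemble))) {
    xyz <- ensemble@coords[, , f]
    writeLines(as.character(nAtoms(ensemble)), con)
    writeLines(sprintf("%s %d", comment, ensemble@frameIds[f]), con)
    writeLines(sprintf("%-4s %12.3f %12.3f %12.3f", ensemble@atoms$name,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}
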