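# Signed torsion angles and substituent orientation factors.

# vectorized core: p1..p4 are n x 3 matrices (one row per frame);
# returns signed dihedrals in degrees, (-180, 180], IUPAC right-handed
# convention (positive = far bond clockwise from near bond viewed p2 -> p3)
dihedralCore <- function(p1, p2, p3, p4, context = "") {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(a, b) cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  norm2 <- function(m) sqrt(rowSums(m * m))
  # collinearity guard on normalized bond vectors
  c1 <- norm2(n1) / (norm2(b1) * norm2(b2))
  c2 <- norm2(n2) / (norm2(b2) * norm2(b3))
  bad <- which(c1 < 1e-6 | c2 < 1e-6)
  if (length(bad))
    vjStop("vicinalJ_geometry_error",
           "collinear atoms (cross-norm < 1e-6)%s at frame %d",
           context, bad[1])
  b2n <- b2 / norm2(b2)
  m1 <- cross(n1, n2)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * b2n)
  phi <- atan2(y, x) / DEG
  wrapAngle(phi)
}

#' Signed dihedral angle of four points
#'
#' Right-handed (IUPAC) convention: the torsion is positive when, looking
#' from \code{p2} toward \code{p3}, the bond to \code{p4} is rotated
#' clockwise from the bond to \code{p1}. Result in degrees, in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric xyz triples (Angstrom)
#' @return signed torsion angle in degrees
#' @examples
#' signedDihedral(c(-0.5, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(2, 0, 1)) # +90
#' @export
signedDihedral <- function(p1, p2, p3, p4) {
  dihedralCore(matrix(p1, 1), matrix(p2, 1), matrix(p3, 1), matrix(p4, 1))
}

# internal: per-frame dihedral for four named atoms of an ensemble
ensembleDihedral <- function(ensemble, a1, a2, a3, a4) {
  idx <- match(c(a1, a2, a3, a4), atomNames(ensemble))
  if (anyNA(idx))
    vjStop("vicinalJ_lookup_error", "atom(s) not found: %s",
           paste(c(a1, a2, a3, a4)[is.na(idx)], collapse = ", "))
  co <- ensemble@coords
  g <- function(i) {          # n_frames x 3 slice for atom i
    m <- co[i, , , drop = FALSE]
    matrix(aperm(m, c(3, 2, 1)), ncol = 3)
  }
  dihedralCore(g(idx[1]), g(idx[2]), g(idx[3]), g(idx[4]),
               context = sprintf(" in %s-%s-%s-%s", a1, a2, a3, a4))
}

#' Per-frame H-C-C-H torsion series for a coupling
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}
#' @param coupling a \linkS4class{CouplingDefinition}
#' @return list with \code{couplingLabel} and \code{phiDeg} (signed torsion
#'   per frame, degrees)
#' @export
torsionSeries <- function(ensemble, coupling) {
  stopifnot(is(ensemble, "ConformerEnsemble"), is(coupling, "CouplingDefinition"))
  phi <- ensembleDihedral(ensemble, coupling@protonA, coupling@carbonA,
                          coupling@carbonB, coupling@protonB)
  list(couplingLabel = coupling@label, phiDeg = phi)
}

#' Write a per-frame torsion series as TSV
#'
#' Diagnostic export: columns \code{frame} (1-based) and \code{phi_deg}.
#'
#' @param series result of [torsionSeries()]
#' @param path output TSV path
#' @return \code{path}, invisibly
#' @export
writeTorsionTSV <- function(series, path) {
  df <- data.frame(frame = seq_along(series$phiDeg), phi_deg = series$phiDeg)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign substituent orientation factors for a coupling
#'
#' For a substituent S geminal to \eqn{H_A} (on \eqn{C_A}) the orientation
#' dihedral is \eqn{\theta} = S-C_A-C_B-H_B; for S on \eqn{C_B} it is
#' \eqn{\theta} = H_A-C_A-C_B-S. With \eqn{\phi} the coupling torsion
#' H_A-C_A-C_B-H_B, \eqn{\xi = +1} if wrap(\eqn{\theta - \phi}) lies in
#' (0, 180) degrees and \eqn{-1} otherwise. At an sp3 carbon the geminal
#' offset is near +/-120 degrees, so wrap(\eqn{\theta - \phi}) within 15
#' degrees of 0 or 180 signals a chemically impossible near-planar
#' substituent and raises a validation error.
#'
#' Because mirror reflection negates every dihedral, it flips every
#' \eqn{\xi}; the HLA equation is invariant under the joint flip
#' \eqn{(\phi, \xi) \to (-\phi, -\xi)}, so enantiomeric ensembles predict
#' identical couplings, as they must.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}
#' @param coupling a \linkS4class{CouplingDefinition}
#' @param frame frame index used for the assignment (default 1)
#' @return named numeric vector of +1/-1, one per substituent (empty if the
#'   coupling lists none)
#' @export
assignXi <- function(ensemble, coupling, frame = 1L) {
  stopifnot(is(ensemble, "ConformerEnsemble"), is(coupling, "CouplingDefinition"))
  s <- coupling@substituents
  if (!nrow(s)) return(stats::setNames(numeric(0), character(0)))
  sub <- subEnsembleFrame(ensemble, frame)
  phi <- ensembleDihedral(sub, coupling@protonA, coupling@carbonA,
                          coupling@carbonB, coupling@protonB)
  xi <- vapply(seq_len(nrow(s)), function(k) {
    theta <- if (s$side[k] == "carbon_a") {
      ensembleDihedral(sub, s$atom[k], coupling@carbonA, coupling@carbonB,
                       coupling@protonB)
    } else {
      ensembleDihedral(sub, coupling@protonA, coupling@carbonA,
                       coupling@carbonB, s$atom[k])
    }
    off <- wrapAngle(theta - phi)
    if (min(abs(off), abs(abs(off) - 180)) < 15)
      vjStop("vicinalJ_validation_error",
             "substituent %s of coupling '%s' is near-planar (offset %.1f deg from the coupled proton) - impossible at an sp3 carbon",
             s$atom[k], coupling@label, off)
    if (off > 0 && off < 180) 1 else -1
  }, numeric(1))
  stats::setNames(xi, s$atom)
}

# internal: single-frame view of an ensemble
subEnsembleFrame <- function(ensemble, frame) {
  stopifnot(frame >= 1L, frame <= nFrames(ensemble))
  conformerEnsemble(ensemble@atoms,
                    ensemble@coords[, , frame, drop = FALSE],
                    frameIds = ensemble@frameIds[frame])
}
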