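# Fixtures are built in code at test time.

# hand-rolled PDB text (independent of the package's writer): a 14-atom
# fragment over `models` MODEL blocks, coordinates jittered per model
writePDBFixture <- function(path, models = 3L, natoms = 14L,
                            dropAtomInModel = NULL) {
  set.seed(4242)
  base <- matrix(rnorm(natoms * 3, sd = 2), natoms, 3)
  names_ <- c(sprintf("C%d", seq_len(natoms %/% 2)),
              sprintf("H%d", seq_len(natoms - natoms %/% 2)))
  elements <- substr(names_, 1, 1)
  lines <- character(0)
  for (m in seq_len(models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    xyz <- base + 0.05 * m
    keep <- seq_len(natoms)
    if (!is.null(dropAtomInModel) && m == dropAtomInModel)
      keep <- keep[-natoms]
    lines <- c(lines, sprintf(
      "ATOM  %5d  %-3s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00           %s",
      seq_along(keep), names_[keep], xyz[keep, 1], xyz[keep, 2], xyz[keep, 3],
      elements[keep]))
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  list(names = names_, base = base)
}

# minimal single-block / multi-block XYZ text
writeXYZFixture <- function(path, frames = 2L) {
  set.seed(7)
  sym <- c("C", "C", "O", "H", "H")
  lines <- character(0)
  for (f in seq_len(frames)) {
    xyz <- matrix(rnorm(15), 5, 3) + f
    lines <- c(lines, "5", sprintf("frame %d", f),
               sprintf("%s %10.4f %10.4f %10.4f", sym, xyz[, 1], xyz[, 2],
                       xyz[, 3]))
  }
  writeLines(lines, path)
}

# an idealized staggered H-C-C-H fragment with one substituent S on each
# carbon, used for xi-rule unit tests. offsetA/offsetB are the orientation
# offsets wrap(theta - phi) of SA (on CA, theta = SA-CA-CB-HB) and SB (on
# CB, theta = HA-CA-CB-SB) relative to the coupling torsion phi.
# Returns a 1-frame ensemble with atoms HA, CA, CB, HB, SA, SB.
staggeredFragment <- function(phi = 180, offsetA = 120, offsetB = 120) {
  r <- 1.53; rh <- 1.10
  deg <- pi / 180
  ca <- c(0, 0, 0); cb <- c(r, 0, 0)
  place <- function(center, axisFrom, tau, bond) {
    # position about the CA-CB axis at torsion tau relative to +z reference
    u <- (center - axisFrom) / sqrt(sum((center - axisFrom)^2))
    theta <- 109.5 * deg
    ez <- c(0, 0, 1)
    m <- ez - sum(ez * u) * u; m <- m / sqrt(sum(m * m))
    nv <- c(u[2] * m[3] - u[3] * m[2], u[3] * m[1] - u[1] * m[3],
            u[1] * m[2] - u[2] * m[1])
    center + bond * (cos(theta) * u +
                       sin(theta) * (cos(tau * deg) * m + sin(tau * deg) * nv))
  }
  # HA sits at angular reference 0 on CA. Probe placements establish the
  # (possibly negative) slope between the placement angle tau and the
  # measured signed torsion on each side, so requested offsets are exact.
  ha <- place(ca, cb, 0, rh)
  p0 <- signedDihedral(ha, ca, cb, place(cb, ca, 0, rh))
  p10 <- signedDihedral(ha, ca, cb, place(cb, ca, 10, rh))
  slopeB <- sign(wrapAngle(p10 - p0))
  hb <- place(cb, ca, slopeB * (phi - p0), rh)
  stopifnot(abs(wrapAngle(signedDihedral(ha, ca, cb, hb) - phi)) < 1e-6)
  sb <- place(cb, ca, slopeB * (phi + offsetB - p0), r)
  a0 <- signedDihedral(place(ca, cb, 0, r), ca, cb, hb)
  a10 <- signedDihedral(place(ca, cb, 10, r), ca, cb, hb)
  slopeA <- sign(wrapAngle(a10 - a0))
  # theta_SA = phi + offsetA; HA is at tau = 0 where theta = phi
  sa <- place(ca, cb, slopeA * offsetA, r)
  atoms <- data.frame(name = c("HA", "CA", "CB", "HB", "SA", "SB"),
                      element = c("H", "C", "C", "H", "C", "C"),
                      stringsAsFactors = FALSE)
  coords <- array(NA_real_, dim = c(6, 3, 1))
  coords[, , 1] <- rbind(ha, ca, cb, hb, sa, sb)
  conformerEnsemble(atoms, coords)
}

simpleCoupling <- function(withSubs = TRUE) {
  subs <- if (withSubs)
    data.frame(atom = c("SA", "SB"), side = c("carbon_a", "carbon_b"),
               group = c("OH", "CH2CH2R"), deltaChi = c(1.33, 0.76),
               stringsAsFactors = FALSE)
  else NULL
  couplingDefinition("HA/HB", "HA", "CA", "CB", "HB", subs)
}
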