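# Synthetic rotamer ensembles with known stereochemical ground truth.
#
# The generator samples torsion space directly: conformers are built from an
# internal-coordinate template by drawing each flexible backbone torsion from
# a von Mises rotamer mixture, independently per frame. The HLA machinery
# consumes only torsion statistics, so this reproduces exactly the feature of
# a solution-state trajectory that the coupling analysis depends on, with
# none of the energetics.

#' Define a von Mises rotamer mixture for one torsion
#'
#' @param torsionName sampled torsion name (e.g. \code{"chi1"})
#' @param centers rotamer centers in degrees
#' @param weights rotamer populations (summing to 1)
#' @param kappa von Mises concentration, scalar (recycled) or per center.
#'   kappa = 20 gives roughly +/- 13 degrees of thermal spread.
#' @return a \linkS4class{RotamerSpec}
#' @examples
#' rotamerSpec("chi1", c(60, 180, -60), c(0.65, 0.25, 0.10))
#' @export
rotamerSpec <- function(torsionName, centers, weights, kappa = 20) {
  if (length(kappa) == 1L) kappa <- rep(kappa, length(centers))
  new("RotamerSpec", torsionName = torsionName,
      centers = wrapAngle(as.numeric(centers)),
      weights = as.numeric(weights), kappa = as.numeric(kappa))
}

# the default chiral fragment: a five-carbon chain C39-C40-C41-C42-C43 with
# a hydroxyl on C41 (the stereocenter) and explicit hydrogens. Torsions:
#   chi1 = C42-C41-C40-C39 (backbone, C40-C41 bond)
#   chi2 = C43-C42-C41-C40 (backbone, C41-C42 bond; stereocenter-adjacent)
# The S template carries every constant torsion offset negated, so the S
# fragment at mirrored torsion values is the exact mirror image of R.
defaultZmatrix <- function(chirality = "R") {
  z <- data.frame(
    name = c("C39", "C40", "C41", "C42", "C43", "O41", "H41",
             "H40a", "H40b", "H42a", "H42b", "HO41",
             "H39a", "H39b", "H39c", "H43a", "H43b", "H43c"),
    element = c(rep("C", 5), "O", rep("H", 12)),
    ref1 = c(NA, "C39", "C40", "C41", "C42", "C41", "C41",
             "C40", "C40", "C42", "C42", "O41",
             "C39", "C39", "C39", "C43", "C43", "C43"),
    ref2 = c(NA, NA, "C39", "C40", "C41", "C40", "C40",
             "C41", "C41", "C41", "C41", "C41",
             "C40", "C40", "C40", "C42", "C42", "C42"),
    ref3 = c(NA, NA, NA, "C39", "C40", "C39", "C39",
             "C42", "C42", "C40", "C40", "C40",
             "C41", "C41", "C41", "C41", "C41", "C41"),
    bond = c(NA, 1.53, 1.53, 1.53, 1.53, 1.43, 1.10,
             1.10, 1.10, 1.10, 1.10, 1.00,
             1.10, 1.10, 1.10, 1.10, 1.10, 1.10),
    angle = c(NA, NA, 111, 111, 111, 109.5, 109,
              109, 109, 109, 109, 108.5,
              109, 109, 109, 109, 109, 109),
    torsionName = c(NA, NA, NA, "chi1", "chi2", "chi1", "chi1",
                    "chi1", "chi1", "chi2", "chi2", NA,
                    NA, NA, NA, NA, NA, NA),
    torsionOffset = c(NA, NA, NA, 0, 0, 120, -120,
                      120, -120, 120, -120, 180,
                      60, 180, -60, 60, 180, -60),
    stringsAsFactors = FALSE
  )
  if (chirality == "S") z$torsionOffset <- -z$torsionOffset
  z
}

#' Construct a chiral fragment blueprint
#'
#' Builds the internal-coordinate template of a six-heavy-atom chain
#' (C39-C40-C41(OH)-C42-C43) with one hydroxyl-bearing stereocenter at C41
#' and explicit hydrogens. Two backbone torsions are sampled: \code{chi1}
#' (C42-C41-C40-C39) and \code{chi2} (C43-C42-C41-C40). Default rotamer
#' mixtures put staggered centers at 60/180/-60 degrees with kappa = 20 and
#' unequal populations favouring the gauche+ basin, emulating the skewed
#' rotamer occupancies of a chain section organized by an intramolecular
#' contact.
#'
#' With \code{hbondBias = TRUE} (the default) the stereocenter-adjacent
#' torsion \code{chi2} is replaced by a narrowed single-center distribution
#' (center 180 degrees, kappa = 60): the minimal model of a hydroxyl/carbonyl
#' hydrogen bond that locks the stereocenter-to-carbonyl stretch of the
#' chain and sharply reduces its conformational freedom.
#'
#' @param chirality \code{"R"} or \code{"S"} at C41. The two templates are
#'   exact mirror images when all sampled torsions are mirrored too.
#' @param hbondBias logical, or a \linkS4class{RotamerSpec} named
#'   \code{"chi2"} to override the stereocenter-adjacent torsion explicitly
#' @param sampledTorsions optional list of \linkS4class{RotamerSpec} to
#'   replace both defaults outright
#' @return a \linkS4class{FragmentBlueprint}
#' @examples
#' fragmentBlueprint("R")
#' @export
fragmentBlueprint <- function(chirality = c("R", "S"), hbondBias = TRUE,
                              sampledTorsions = NULL) {
  chirality <- match.arg(chirality)
  if (is.null(sampledTorsions))
    sampledTorsions <- list(
      rotamerSpec("chi1", c(60, 180, -60), c(0.65, 0.25, 0.10), kappa = 20),
      rotamerSpec("chi2", c(180, 60, -60), c(0.50, 0.30, 0.20), kappa = 20))
  bias <- NULL
  if (isTRUE(hbondBias)) {
    # anti basin: brings the C41 hydroxyl oxygen ~2.9 A from C43, the
    # geometry of the intramolecular hydroxyl/carbonyl contact
    bias <- rotamerSpec("chi2", 180, 1, kappa = 60)
  } else if (is(hbondBias, "RotamerSpec")) {
    bias <- hbondBias
  }
  new("FragmentBlueprint", zmatrix = defaultZmatrix(chirality),
      chirality = chirality, sampledTorsions = sampledTorsions,
      hbondBias = bias)
}

# effective torsion specs after applying the hydrogen-bond bias override
effectiveSpecs <- function(blueprint) {
  specs <- blueprint@sampledTorsions
  names(specs) <- vapply(specs, function(s) s@torsionName, character(1))
  if (!is.null(blueprint@hbondBias))
    specs[[blueprint@hbondBias@torsionName]] <- blueprint@hbondBias
  specs
}

# vectorized natural-extension (NeRF) build: torsions is an n x k matrix
# with one column per sampled torsion name; returns n_atoms x 3 x n array
buildEnsembleCoords <- function(blueprint, torsions) {
  z <- blueprint@zmatrix
  n <- nrow(torsions)
  pos <- vector("list", nrow(z))
  names(pos) <- z$name
  unit <- function(m) m / sqrt(rowSums(m * m))
  cross <- function(a, b) cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1])
  rep3 <- function(v) matrix(v, nrow = n, ncol = 3, byrow = TRUE)
  for (i in seq_len(nrow(z))) {
    if (i == 1L) {
      pos[[i]] <- matrix(0, n, 3)
    } else if (i == 2L) {
      pos[[i]] <- rep3(c(z$bond[i], 0, 0))
    } else if (i == 3L) {
      p1 <- pos[[z$ref1[i]]]; p2 <- pos[[z$ref2[i]]]
      u <- unit(p2 - p1)
      perp <- cross(u, rep3(c(0, 0, 1)))
      bad <- rowSums(perp * perp) < 1e-12
      if (any(bad)) perp[bad, ] <- cross(u[bad, , drop = FALSE],
                                         rep3(c(0, 1, 0))[bad, , drop = FALSE])
      perp <- unit(perp)
      th <- z$angle[i] * DEG
      pos[[i]] <- p1 + z$bond[i] * (cos(th) * u + sin(th) * perp)
    } else {
      C <- pos[[z$ref1[i]]]; B <- pos[[z$ref2[i]]]; A <- pos[[z$ref3[i]]]
      tau <- rep(z$torsionOffset[i], n)
      if (!is.na(z$torsionName[i]))
        tau <- tau + torsions[, z$torsionName[i]]
      tau <- tau * DEG
      th <- z$angle[i] * DEG
      u <- unit(C - B)
      nhat <- unit(cross(B - A, u))
      mhat <- cross(nhat, u)
      d <- (-cos(th)) * u + sin(th) * (cos(tau) * mhat + sin(tau) * nhat)
      pos[[i]] <- C + z$bond[i] * d
    }
    if (any(!is.finite(pos[[i]])))
      vjStop("vicinalJ_construction_error",
             "internal-coordinate inconsistency while placing atom %s",
             z$name[i])
  }
  coords <- array(NA_real_, dim = c(nrow(z), 3L, n))
  for (i in seq_len(nrow(z))) coords[i, , ] <- t(pos[[i]])
  coords
}

#' Build a single conformer from a blueprint
#'
#' Deterministic: the same torsion values always give bit-identical frames.
#' Torsions measured on the built frame (via [signedDihedral()]) equal the
#' requested values to well under 1e-6 degrees.
#'
#' @param blueprint a \linkS4class{FragmentBlueprint}
#' @param torsionValues named numeric vector, one value (degrees) per
#'   sampled torsion (e.g. \code{c(chi1 = 60, chi2 = 180)})
#' @return a one-frame \linkS4class{ConformerEnsemble}
#' @export
buildConformer <- function(blueprint, torsionValues) {
  specs <- effectiveSpecs(blueprint)
  need <- names(specs)
  if (!all(need %in% names(torsionValues)))
    vjStop("vicinalJ_construction_error",
           "torsion value(s) missing for: %s",
           paste(setdiff(need, names(torsionValues)), collapse = ", "))
  tm <- matrix(torsionValues[need], nrow = 1,
               dimnames = list(NULL, need))
  coords <- buildEnsembleCoords(blueprint, tm)
  conformerEnsemble(blueprint@zmatrix[, c("name", "element")], coords)
}

# von Mises sampler, Best & Fisher (1979) rejection; mu and result in
# radians. Vectorized batch rejection.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.3))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    zc <- cos(pi * u1)
    f <- (1 + r * zc) / (r + zc)
    cq <- kappa * (r - f)
    ok <- (cq * (2 - cq) - u2 > 0) | (log(cq / u2) + 1 - cq >= 0)
    theta <- sign(u3 - 0.5) * acos(pmax(-1, pmin(1, f)))
    out <- c(out, theta[ok])
  }
  mu + out[seq_len(n)]
}

# density of a von Mises mixture at angles x (degrees); used by tests and
# diagnostics. Normalized over degrees (integrates to 1 on (-180, 180]).
vonMisesMixtureDensity <- function(x, spec) {
  xr <- x * DEG
  dens <- rep(0, length(x))
  for (k in seq_along(spec@centers)) {
    mu <- spec@centers[k] * DEG
    kap <- spec@kappa[k]
    dens <- dens + spec@weights[k] *
      exp(kap * cos(xr - mu)) / (2 * pi * besselI(kap, 0, expon.scaled = TRUE) *
                                   exp(kap))
  }
  dens * DEG
}

# draw n angles (degrees) from a rotamer mixture
sampleRotamerMixture <- function(n, spec) {
  comp <- sample.int(length(spec@centers), n, replace = TRUE,
                     prob = spec@weights)
  out <- numeric(n)
  for (k in seq_along(spec@centers)) {
    idx <- which(comp == k)
    if (length(idx))
      out[idx] <- rvonmises(length(idx), spec@centers[k] * DEG,
                            spec@kappa[k]) / DEG
  }
  wrapAngle(out)
}

#' Generate a seeded rotamer ensemble with ground truth
#'
#' Each frame's sampled torsions are drawn independently from their von
#' Mises rotamer mixtures (after applying the hydrogen-bond bias override,
#' if present) and the conformer is built from the blueprint. The same seed
#' always reproduces the identical ensemble.
#'
#' @param blueprint a \linkS4class{FragmentBlueprint}
#' @param nFrames number of frames (the conventional statistical probe from
#'   a long trajectory is 2000)
#' @param seed integer RNG seed (required: the truth record stores it)
#' @return list with \code{ensemble} (a \linkS4class{ConformerEnsemble}),
#'   \code{torsions} (n x k matrix of the sampled values, degrees) and
#'   \code{truth} (chirality, seed, frame count, torsion specs)
#' @export
generateRotamerEnsemble <- function(blueprint, nFrames = 2000L, seed) {
  stopifnot(is(blueprint, "FragmentBlueprint"), nFrames >= 1L)
  if (missing(seed))
    vjStop("vicinalJ_config_error", "a seed is required for generation")
  specs <- effectiveSpecs(blueprint)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  torsions <- vapply(specs, function(s) sampleRotamerMixture(nFrames, s),
                     numeric(nFrames))
  if (nFrames == 1L) torsions <- matrix(torsions, nrow = 1,
                                        dimnames = list(NULL, names(specs)))
  coords <- buildEnsembleCoords(blueprint, torsions)
  ens <- conformerEnsemble(blueprint@zmatrix[, c("name", "element")], coords)
  truth <- list(
    chirality = blueprint@chirality,
    seed = seed,
    n_frames = as.integer(nFrames),
    hbond_bias = !is.null(blueprint@hbondBias),
    torsions = lapply(specs, function(s) list(
      name = s@torsionName, centers = s@centers, weights = s@weights,
      kappa = s@kappa)))
  list(ensemble = ens, torsions = torsions, truth = truth)
}

#' Mirror an ensemble through the yz-plane
#'
#' Reflection negates every torsion and flips every substituent orientation
#' factor, so a mirrored ensemble predicts identical couplings once the
#' orientation factors are re-assigned — enantiomers are indistinguishable
#' by scalar couplings, as required. Applying the mirror twice returns the
#' original coordinates exactly.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}
#' @return the mirrored \linkS4class{ConformerEnsemble}
#' @export
mirrorEnsemble <- function(ensemble) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  coords <- ensemble@coords
  coords[, 1, ] <- -coords[, 1, ]
  conformerEnsemble(ensemble@atoms, coords, ensemble@frameIds)
}

#' Write a generated ensemble plus its truth sidecar
#'
#' Writes a multi-model PDB and a JSON sidecar holding chirality, seed and
#' torsion specs, so downstream comparisons can be checked against the
#' generator's ground truth.
#'
#' @param generated result of [generateRotamerEnsemble()]
#' @param pdbPath output PDB path
#' @param truthPath output JSON sidecar path
#' @return invisibly, list of the two paths
#' @export
writeEnsembleWithTruth <- function(generated, pdbPath, truthPath) {
  writeMultimodelPDB(generated$ensemble, pdbPath)
  jsonlite::write_json(generated$truth, truthPath, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(pdb = pdbPath, truth = truthPath))
}
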