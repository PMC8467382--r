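#' @import methods
NULL

#' ConformerEnsemble: an ordered set of conformer frames over a fixed atom table
#'
#' Holds Cartesian coordinates (in Angstrom) for one molecular fragment across
#' an ordered series of conformers ("frames"), e.g. snapshots extracted from a
#' molecular-dynamics trajectory or frames drawn by the rotamer generator.
#' Every frame shares the same atom table; atoms are identified by their name
#' strings (e.g. \code{"H41"}), matching the proton/carbon numbering used in
#' NMR assignment work.
#'
#' @slot atoms data.frame with columns \code{name} (unique atom labels) and
#'   \code{element} (element symbols).
#' @slot coords numeric array of dimension \code{n_atoms x 3 x n_frames},
#'   coordinates in Angstrom.
#' @slot frameIds integer vector of frame ordinals (1-based, matching PDB
#'   MODEL numbering in reports; the accessor API is 1-based as usual in R).
#'
#' @seealso [readMultimodelPDB()], [readXYZFrames()],
#'   [generateRotamerEnsemble()]
#' @export
setClass("ConformerEnsemble",
  slots = c(
    atoms = "data.frame",
    coords = "array",
    frameIds = "integer"
  )
)

setValidity("ConformerEnsemble", function(object) {
  msgs <- character()
  at <- object@atoms
  if (!all(c("name", "element") %in% names(at)))
    msgs <- c(msgs, "atoms must have columns 'name' and 'element'")
  else {
    if (anyDuplicated(at$name))
      msgs <- c(msgs, "atom names must be unique")
    bad <- !grepl("^[A-Z][a-z]?$", at$element)
    if (any(bad))
      msgs <- c(msgs, sprintf("invalid element symbol(s): %s",
                              paste(unique(at$element[bad]), collapse = ", ")))
  }
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msgs <- c(msgs, "coords must be an n_atoms x 3 x n_frames array")
  else {
    if (d[1] != nrow(at))
      msgs <- c(msgs, "coords first dimension must equal number of atoms")
    if (d[3] < 1L)
      msgs <- c(msgs, "ensemble must contain at least one frame")
    if (length(object@frameIds) != d[3])
      msgs <- c(msgs, "frameIds length must equal number of frames")
    if (!all(is.finite(object@coords)))
      msgs <- c(msgs, "coordinates must all be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' CouplingDefinition: one H-C-C-H vicinal coupling path with its substituents
#'
#' Describes a single three-bond proton-proton coupling \eqn{H_A-C_A-C_B-H_B}
#' together with the non-hydrogen substituents attached to the two carbons.
#' Each substituent carries an electronegativity-difference group label whose
#' \eqn{\Delta\chi} value feeds the HLA correction term; its orientation
#' factor \eqn{\xi = \pm 1} is determined from geometry by [assignXi()].
#'
#' @slot label coupling name, e.g. \code{"H40a/H41"}.
#' @slot protonA,carbonA,carbonB,protonB atom names of the coupling path.
#' @slot substituents data.frame with columns \code{atom} (atom name),
#'   \code{side} (\code{"carbon_a"} or \code{"carbon_b"}), \code{group}
#'   (substituent group label) and \code{deltaChi} (numeric).
#'
#' @seealso [couplingDefinition()], [deltaChiTable()]
#' @export
setClass("CouplingDefinition",
  slots = c(
    label = "character",
    protonA = "character",
    carbonA = "character",
    carbonB = "character",
    protonB = "character",
    substituents = "data.frame"
  )
)

setValidity("CouplingDefinition", function(object) {
  msgs <- character()
  path <- c(object@protonA, object@carbonA, object@carbonB, object@protonB)
  if (length(object@label) != 1L || !nzchar(object@label))
    msgs <- c(msgs, "label must be a single non-empty string")
  if (anyDuplicated(path))
    msgs <- c(msgs, "the four path atoms must be distinct")
  s <- object@substituents
  req <- c("atom", "side", "deltaChi")
  if (!all(req %in% names(s))) {
    msgs <- c(msgs, "substituents must have columns atom, side, deltaChi")
  } else if (nrow(s)) {
    if (!all(s$side %in% c("carbon_a", "carbon_b")))
      msgs <- c(msgs, "substituent side must be 'carbon_a' or 'carbon_b'")
    if (any(table(s$side) > 3L))
      msgs <- c(msgs, "each carbon carries at most 3 substituents")
    if (any(s$atom %in% path))
      msgs <- c(msgs, "substituent atoms must be distinct from path atoms")
    if (anyDuplicated(s$atom))
      msgs <- c(msgs, "substituent atoms must be distinct")
    if (any(!is.finite(s$deltaChi)))
      msgs <- c(msgs, "deltaChi values must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' KarplusParameterSet: the six coefficients of the generalized HLA equation
#'
#' \eqn{P_1 \ldots P_5} set the amplitude of the cosine terms (their
#' contribution is in Hz); \eqn{P_6} is a phase in degrees. The default set
#' is the MestReJ parameterization for vicinal proton couplings:
#' (14.64, -0.78, 0.58, 0.34, -2.31, 18.40).
#'
#' @slot p numeric vector of length 6, named p1..p6.
#' @seealso [karplusParameters()], [predict3J()]
#' @export
setClass("KarplusParameterSet", slots = c(p = "numeric"))

setValidity("KarplusParameterSet", function(object) {
  if (length(object@p) != 6L) return("parameter vector must have length 6")
  if (!all(is.finite(object@p))) return("parameters must be finite")
  TRUE
})

#' JPredictionReport: per-frame couplings and ensemble statistics
#'
#' The result of evaluating the HLA equation on every frame of a conformer
#' ensemble for one coupling: the per-frame \eqn{^3J} series, its ensemble
#' mean \eqn{^3\hat{J}}, dispersion and standard-error estimates, and a
#' cumulative-mean convergence trace.
#'
#' @slot couplingLabel coupling name.
#' @slot jPerFrame per-frame couplings (Hz).
#' @slot jMean ensemble-average coupling (Hz).
#' @slot jSD standard deviation of the per-frame series (Hz).
#' @slot jSE named numeric: \code{naive} (SD/sqrt(n)) and \code{block}
#'   (block-averaging estimate; frames from dynamics are autocorrelated, so
#'   the naive value is usually optimistic).
#' @slot nFrames number of frames averaged.
#' @slot convergence cumulative-mean trace (Hz), one value per frame.
#' @slot xi named numeric vector of substituent orientation factors (+1/-1)
#'   used for every frame.
#' @export
setClass("JPredictionReport",
  slots = c(
    couplingLabel = "character",
    jPerFrame = "numeric",
    jMean = "numeric",
    jSD = "numeric",
    jSE = "numeric",
    nFrames = "integer",
    convergence = "numeric",
    xi = "numeric"
  )
)

setValidity("JPredictionReport", function(object) {
  msgs <- character()
  n <- object@nFrames
  if (length(object@jPerFrame) != n)
    msgs <- c(msgs, "jPerFrame length must equal nFrames")
  if (n < 1L) msgs <- c(msgs, "report requires at least one frame")
  if (abs(object@jMean - mean(object@jPerFrame)) > 1e-9)
    msgs <- c(msgs, "jMean must equal the arithmetic mean of jPerFrame")
  if (object@jMean < min(object@jPerFrame) - 1e-12 ||
      object@jMean > max(object@jPerFrame) + 1e-12)
    msgs <- c(msgs, "jMean must lie within the range of jPerFrame")
  if (length(msgs)) msgs else TRUE
})

#' EpimerComparison: measured vs predicted couplings for one candidate
#'
#' Per-coupling absolute disagreement between a measured \eqn{^3J} set and
#' the ensemble-averaged predictions of one stereochemical candidate, plus
#' the mean and maximum absolute disagreement used to rank candidates.
#'
#' @slot candidateLabel candidate name, e.g. \code{"41R"}.
#' @slot pairs data.frame with columns \code{coupling}, \code{measured},
#'   \code{predicted}, \code{absDiff} (all J values in Hz, full precision).
#' @slot meanAbsDiff mean of the absolute differences (Hz).
#' @slot maxAbsDiff maximum absolute difference (Hz).
#' @seealso [compareJSets()], [decideEpimer()]
#' @export
setClass("EpimerComparison",
  slots = c(
    candidateLabel = "character",
    pairs = "data.frame",
    meanAbsDiff = "numeric",
    maxAbsDiff = "numeric"
  )
)

setValidity("EpimerComparison", function(object) {
  msgs <- character()
  p <- object@pairs
  req <- c("coupling", "measured", "predicted", "absDiff")
  if (!all(req %in% names(p)))
    msgs <- c(msgs, "pairs must have columns coupling, measured, predicted, absDiff")
  else {
    if (nrow(p) < 1L) msgs <- c(msgs, "at least one coupling pair required")
    if (any(p$absDiff < 0)) msgs <- c(msgs, "absDiff must be non-negative")
    if (nrow(p)) {
      if (abs(object@meanAbsDiff - mean(p$absDiff)) > 1e-9)
        msgs <- c(msgs, "meanAbsDiff must equal mean of absDiff")
      if (abs(object@maxAbsDiff - max(p$absDiff)) > 1e-9)
        msgs <- c(msgs, "maxAbsDiff must equal max of absDiff")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' RotamerSpec: a von Mises mixture describing one sampled torsion
#'
#' Torsional fluctuation about rotamer states is modeled as a mixture of
#' von Mises distributions (the circular analogue of the Gaussian): one
#' component per rotamer center, with mixture weights giving the rotamer
#' populations and concentration kappa setting the width of thermal
#' fluctuation about each center (kappa = 20 corresponds to roughly
#' +/- 13 degrees of spread).
#'
#' @slot torsionName name of the torsion this spec samples.
#' @slot centers rotamer centers in degrees, each in (-180, 180].
#' @slot weights mixture weights, summing to 1.
#' @slot kappa von Mises concentration per center (recycled if scalar).
#' @seealso [rotamerSpec()], [generateRotamerEnsemble()]
#' @export
setClass("RotamerSpec",
  slots = c(
    torsionName = "character",
    centers = "numeric",
    weights = "numeric",
    kappa = "numeric"
  )
)

setValidity("RotamerSpec", function(object) {
  msgs <- character()
  k <- length(object@centers)
  if (k < 1L) msgs <- c(msgs, "at least one rotamer center required")
  if (length(object@weights) != k)
    msgs <- c(msgs, "weights must match centers in length")
  else if (abs(sum(object@weights) - 1) > 1e-9)
    msgs <- c(msgs, "weights must sum to 1")
  if (any(object@weights < 0)) msgs <- c(msgs, "weights must be non-negative")
  if (any(object@centers <= -180 | object@centers > 180))
    msgs <- c(msgs, "centers must lie in (-180, 180]")
  if (length(object@kappa) != k)
    msgs <- c(msgs, "kappa must match centers in length")
  else if (any(object@kappa <= 0)) msgs <- c(msgs, "kappa must be positive")
  if (length(msgs)) msgs else TRUE
})

#' FragmentBlueprint: internal-coordinate template for a chiral chain fragment
#'
#' A z-matrix-style template of a six-heavy-atom chain carrying one
#' hydroxyl-bearing stereocenter with explicit hydrogens (a C39-C43-like
#' fragment). Conformers are built from it by supplying values for the
#' sampled backbone torsions; the \code{chirality} flag swaps the hydroxyl
#' and stereocenter proton positions, so the R and S blueprints are exact
#' mirror images when all sampled torsions are mirrored too.
#'
#' An optional hydrogen-bond bias replaces the rotamer distribution of the
#' stereocenter-adjacent torsion with a narrowed, single-center one. This is
#' the minimal encoding of an intramolecular hydroxyl/carbonyl hydrogen bond
#' that locks part of the chain: it reduces conformational freedom without
#' introducing explicit energetics.
#'
#' @slot zmatrix data.frame template (atom, element, refs and internal
#'   coordinates; torsion entries may name a sampled torsion plus an offset).
#' @slot chirality \code{"R"} or \code{"S"} at the stereocenter.
#' @slot sampledTorsions list of [RotamerSpec-class] objects, one per sampled
#'   backbone torsion.
#' @slot hbondBias a [RotamerSpec-class] overriding the stereocenter-adjacent
#'   torsion, or NULL.
#' @seealso [fragmentBlueprint()], [buildConformer()]
#' @export
setClass("FragmentBlueprint",
  slots = c(
    zmatrix = "data.frame",
    chirality = "character",
    sampledTorsions = "list",
    hbondBias = "ANY"
  )
)

setValidity("FragmentBlueprint", function(object) {
  msgs <- character()
  if (!object@chirality %in% c("R", "S"))
    msgs <- c(msgs, "chirality must be 'R' or 'S'")
  z <- object@zmatrix
  req <- c("name", "element", "ref1", "ref2", "ref3", "bond", "angle",
           "torsionName", "torsionOffset")
  if (!all(req %in% names(z)))
    msgs <- c(msgs, "zmatrix missing required columns")
  else {
    placed <- z$name[-(1:3)]
    b <- z$bond[-1]
    if (any(b < 1.0 | b > 1.6))
      msgs <- c(msgs, "bond lengths must lie in 1.0-1.6 Angstrom")
    a <- z$angle[-(1:2)]
    if (any(a < 105 | a > 115))
      msgs <- c(msgs, "bond angles must lie in the sp3 range 105-115 degrees")
  }
  if (!all(vapply(object@sampledTorsions, inherits, logical(1), "RotamerSpec")))
    msgs <- c(msgs, "sampledTorsions must be RotamerSpec objects")
  if (!is.null(object@hbondBias) && !inherits(object@hbondBias, "RotamerSpec"))
    msgs <- c(msgs, "hbondBias must be NULL or a RotamerSpec")
  if (length(msgs)) msgs else TRUE
})
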