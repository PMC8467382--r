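#' @rdname ConformerEnsemble-class
#' @param x,object a \linkS4class{ConformerEnsemble} (or other object for
#'   which a method is defined)
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname ConformerEnsemble-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname ConformerEnsemble-class
#' @export
setGeneric("atomNames", function(x) standardGeneric("atomNames"))

#' @rdname ConformerEnsemble-class
#' @param i frame index (1-based)
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname JPredictionReport-class
#' @export
setGeneric("jMean", function(x) standardGeneric("jMean"))

#' @rdname JPredictionReport-class
#' @export
setGeneric("jPerFrame", function(x) standardGeneric("jPerFrame"))

#' @rdname EpimerComparison-class
#' @export
setGeneric("meanAbsDiff", function(x) standardGeneric("meanAbsDiff"))

#' @rdname EpimerComparison-class
#' @export
setGeneric("maxAbsDiff", function(x) standardGeneric("maxAbsDiff"))

#' @rdname ConformerEnsemble-class
setMethod("nFrames", "ConformerEnsemble", function(x) dim(x@coords)[3])

#' @rdname ConformerEnsemble-class
setMethod("nAtoms", "ConformerEnsemble", function(x) dim(x@coords)[1])

#' @rdname ConformerEnsemble-class
setMethod("atomNames", "ConformerEnsemble", function(x) x@atoms$name)

#' @rdname ConformerEnsemble-class
setMethod("frameCoords", "ConformerEnsemble", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nFrames(x))
  m <- x@coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  rownames(m) <- x@atoms$name
  colnames(m) <- c("x", "y", "z")
  m
})

#' @rdname JPredictionReport-class
setMethod("jMean", "JPredictionReport", function(x) x@jMean)

#' @rdname JPredictionReport-class
setMethod("jPerFrame", "JPredictionReport", function(x) x@jPerFrame)

#' @rdname EpimerComparison-class
setMethod("meanAbsDiff", "EpimerComparison", function(x) x@meanAbsDiff)

#' @rdname EpimerComparison-class
setMethod("maxAbsDiff", "EpimerComparison", function(x) x@maxAbsDiff)

#' @rdname ConformerEnsemble-class
setMethod("show", "ConformerEnsemble", function(object) {
  cat(sprintf("ConformerEnsemble: %d atoms x %d frame(s)\n",
              nAtoms(object), nFrames(object)))
  cat("  atoms:", paste(utils::head(atomNames(object), 12), collapse = " "),
      if (nAtoms(object) > 12) "..." else "", "\n")
})

#' @rdname CouplingDefinition-class
#' @param object a \linkS4class{CouplingDefinition}
setMethod("show", "CouplingDefinition", function(object) {
  cat(sprintf("CouplingDefinition '%s': %s-%s-%s-%s\n", object@label,
              object@protonA, object@carbonA, object@carbonB, object@protonB))
  s <- object@substituents
  if (nrow(s))
    cat(sprintf("  substituents: %s\n",
                paste(sprintf("%s(%s, dChi=%.2f)", s$atom,
                              ifelse(s$side == "carbon_a", object@carbonA,
                                     object@carbonB), s$deltaChi),
                      collapse = ", ")))
})

#' @rdname KarplusParameterSet-class
#' @param object a \linkS4class{KarplusParameterSet}
setMethod("show", "KarplusParameterSet", function(object) {
  cat("KarplusParameterSet (HLA):",
      paste(sprintf("P%d=%.2f", 1:6, object@p), collapse = " "), "\n")
})

#' @rdname JPredictionReport-class
#' @param object a \linkS4class{JPredictionReport}
setMethod("show", "JPredictionReport", function(object) {
  cat(sprintf("JPredictionReport '%s': <J> = %.1f Hz (SD %.1f, n = %d)\n",
              object@couplingLabel, object@jMean, object@jSD, object@nFrames))
  cat(sprintf("  SE: naive %.3f Hz, block %.3f Hz\n",
              object@jSE[["naive"]], object@jSE[["block"]]))
})

#' @rdname EpimerComparison-class
#' @param object an \linkS4class{EpimerComparison}
setMethod("show", "EpimerComparison", function(object) {
  cat(sprintf("EpimerComparison '%s': mean |dJ| = %.1f Hz, max |dJ| = %.1f Hz\n",
              object@candidateLabel,
              roundHalfUp(object@meanAbsDiff, 1),
              roundHalfUp(object@maxAbsDiff, 1)))
  p <- object@pairs
  for (k in seq_len(nrow(p)))
    cat(sprintf("  %-12s measured %5.1f  predicted %5.1f  |d| %4.1f\n",
                p$coupling[k], p$measured[k], roundHalfUp(p$predicted[k], 1),
                roundHalfUp(p$absDiff[k], 1)))
})

#' @rdname RotamerSpec-class
#' @param object a \linkS4class{RotamerSpec}
setMethod("show", "RotamerSpec", function(object) {
  cat(sprintf("RotamerSpec '%s': centers (%s) deg, weights (%s), kappa (%s)\n",
              object@torsionName,
              paste(object@centers, collapse = ", "),
              paste(signif(object@weights, 3), collapse = ", "),
              paste(object@kappa, collapse = ", ")))
})

#' @rdname FragmentBlueprint-class
#' @param object a \linkS4class{FragmentBlueprint}
setMethod("show", "FragmentBlueprint", function(object) {
  cat(sprintf("FragmentBlueprint: %d atoms, chirality %s, %d sampled torsion(s)%s\n",
              nrow(object@zmatrix), object@chirality,
              length(object@sampledTorsions),
              if (is.null(object@hbondBias)) "" else ", H-bond bias active"))
})
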