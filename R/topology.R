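#' Built-in substituent electronegativity-difference groups
#'
#' The electronegativity-difference parameters \eqn{\Delta\chi_i} used by the
#' HLA correction term, per substituent group relative to hydrogen
#' (MestReJ values): H 0, CHMeOH 0.62, CH2C(O)R 0.72, CH2CH2R 0.76, OH 1.33.
#'
#' @return data.frame with columns \code{label} and \code{deltaChi}
#' @examples
#' deltaChiTable()
#' @export
deltaChiTable <- function() {
  data.frame(
    label = c("H", "CHMeOH", "CH2C(O)R", "CH2CH2R", "OH"),
    deltaChi = c(0, 0.62, 0.72, 0.76, 1.33),
    stringsAsFactors = FALSE
  )
}

#' Look up a substituent group
#'
#' @param label group label from [deltaChiTable()], or a custom label when
#'   \code{deltaChi} is supplied explicitly
#' @param deltaChi optional explicit electronegativity-difference value
#'   (overrides the table; must be non-negative for table groups but custom
#'   negative values, legal in the general HLA framework, are accepted)
#' @return list with \code{label} and \code{deltaChi}
#' @export
substituentGroup <- function(label, deltaChi = NULL) {
  if (is.null(deltaChi)) {
    tab <- deltaChiTable()
    hit <- match(label, tab$label)
    if (is.na(hit))
      vjStop("vicinalJ_validation_error",
             "unknown substituent group '%s'; known: %s", label,
             paste(tab$label, collapse = ", "))
    deltaChi <- tab$deltaChi[hit]
  }
  if (!is.finite(deltaChi))
    vjStop("vicinalJ_validation_error", "deltaChi must be finite")
  list(label = label, deltaChi = deltaChi)
}

#' Define a vicinal H-C-C-H coupling with its substituents
#'
#' @param label coupling name, e.g. \code{"H40a/H41"}
#' @param protonA,carbonA,carbonB,protonB atom names of the
#'   \eqn{H_A-C_A-C_B-H_B} path
#' @param substituents data.frame (or list of lists) with columns/fields
#'   \code{atom}, \code{side} (\code{"carbon_a"}/\code{"carbon_b"}) and
#'   either \code{group} (a [deltaChiTable()] label) or \code{deltaChi}.
#'   Geminal hydrogens may be listed (with group \code{"H"}) or omitted;
#'   the two are numerically identical.
#' @return a \linkS4class{CouplingDefinition}
#' @examples
#' couplingDefinition("Ha/Hb", "Ha", "C1", "C2", "Hb",
#'   data.frame(atom = "O1", side = "carbon_a", group = "OH"))
#' @export
couplingDefinition <- function(label, protonA, carbonA, carbonB, protonB,
                               substituents = NULL) {
  if (is.null(substituents)) {
    substituents <- data.frame(atom = character(), side = character(),
                               group = character(), deltaChi = numeric(),
                               stringsAsFactors = FALSE)
  } else if (!is.data.frame(substituents)) {
    substituents <- do.call(rbind, lapply(substituents, function(s)
      data.frame(atom = s$atom, side = s$side,
                 group = if (is.null(s$group)) NA_character_ else s$group,
                 deltaChi = if (is.null(s$deltaChi)) NA_real_ else s$deltaChi,
                 stringsAsFactors = FALSE)))
  }
  if (nrow(substituents)) {
    if (is.null(substituents$deltaChi)) substituents$deltaChi <- NA_real_
    if (is.null(substituents$group)) substituents$group <- NA_character_
    need <- is.na(substituents$deltaChi)
    substituents$deltaChi[need] <- vapply(
      substituents$group[need],
      function(g) substituentGroup(g)$deltaChi, numeric(1))
    substituents$group[is.na(substituents$group)] <- "custom"
  }
  new("CouplingDefinition", label = label, protonA = protonA,
      carbonA = carbonA, carbonB = carbonB, protonB = protonB,
      substituents = substituents)
}

#' Read topology and measured couplings from a YAML config
#'
#' The config has sections \code{atoms} (optional list of expected atom
#' names), \code{couplings} (list of coupling definitions: \code{label},
#' \code{proton_a}, \code{carbon_a}, \code{carbon_b}, \code{proton_b},
#' \code{substituents} as \code{{atom, on, group}} entries) and
#' \code{measured} (list of \code{{label, j_hz}}).
#'
#' @param path YAML config file
#' @return list with \code{atoms} (character or NULL), \code{couplings}
#'   (list of \linkS4class{CouplingDefinition}) and \code{measured}
#'   (data.frame label/jHz, possibly empty)
#' @export
readTopologyConfig <- function(path) {
  if (!file.exists(path))
    vjStop("vicinalJ_config_error", "topology config not found: %s", path)
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    vjStop("vicinalJ_format_error", "failed to parse YAML %s: %s",
           path, conditionMessage(e)))
  if (is.null(cfg$couplings) || !length(cfg$couplings))
    vjStop("vicinalJ_config_error", "config %s has no 'couplings' section", path)
  couplings <- lapply(cfg$couplings, function(cp) {
    subs <- if (is.null(cp$substituents)) NULL else
      lapply(cp$substituents, function(s)
        list(atom = s$atom, side = s$site, group = s$group,
             deltaChi = s$delta_chi))
    couplingDefinition(cp$label, cp$proton_a, cp$carbon_a, cp$carbon_b,
                       cp$proton_b, subs)
  })
  measured <- if (is.null(cfg$measured)) {
    data.frame(label = character(), jHz = numeric(), stringsAsFactors = FALSE)
  } else {
    data.frame(
      label = vapply(cfg$measured, function(m) as.character(m$label),
                     character(1)),
      jHz = vapply(cfg$measured, function(m) as.numeric(m$j_hz), numeric(1)),
      stringsAsFactors = FALSE)
  }
  if (any(measured$jHz < 0))
    vjStop("vicinalJ_validation_error",
           "measured couplings must be non-negative (file %s)", path)
  list(atoms = if (is.null(cfg$atoms)) NULL else unlist(cfg$atoms),
       couplings = couplings, measured = measured)
}

#' Validate a coupling topology against an ensemble's geometry
#'
#' Checks that all named atoms exist and that, in the first frame, the
#' \eqn{C_A-C_B} bond, the two \eqn{H-C} bonds and every substituent-carbon
#' contact fall within a plausible covalent distance range.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}
#' @param coupling a \linkS4class{CouplingDefinition}
#' @param bondRange length-2 numeric, allowed covalent distance range in
#'   Angstrom (default 0.7-1.9)
#' @return the validated \linkS4class{CouplingDefinition}, invisibly
#' @export
validateTopology <- function(ensemble, coupling, bondRange = c(0.7, 1.9)) {
  stopifnot(is(ensemble, "ConformerEnsemble"), is(coupling, "CouplingDefinition"))
  need <- c(coupling@protonA, coupling@carbonA, coupling@carbonB,
            coupling@protonB, coupling@substituents$atom)
  missing <- setdiff(need, atomNames(ensemble))
  if (length(missing))
    vjStop("vicinalJ_lookup_error",
           "coupling '%s' references atom(s) not in the ensemble: %s",
           coupling@label, paste(missing, collapse = ", "))
  xyz <- frameCoords(ensemble, 1L)
  dist <- function(a, b) sqrt(sum((xyz[a, ] - xyz[b, ])^2))
  checkBond <- function(a, b) {
    d <- dist(a, b)
    if (d < bondRange[1] || d > bondRange[2])
      vjStop("vicinalJ_validation_error",
             "coupling '%s': %s-%s distance %.2f A outside covalent range %.2f-%.2f A",
             coupling@label, a, b, d, bondRange[1], bondRange[2])
  }
  checkBond(coupling@carbonA, coupling@carbonB)
  checkBond(coupling@protonA, coupling@carbonA)
  checkBond(coupling@protonB, coupling@carbonB)
  s <- coupling@substituents
  for (k in seq_len(nrow(s))) {
    carbon <- if (s$side[k] == "carbon_a") coupling@carbonA else coupling@carbonB
    checkBond(s$atom[k], carbon)
  }
  invisible(coupling)
}
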