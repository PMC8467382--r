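# Generalized Haasnoot-de Leeuw-Altona (HLA) Karplus equation.
#
#   3J(phi) = P1 cos^2(phi) + P2 cos(phi) + P3
#             + sum_i dchi_i * [ P4 + P5 cos^2( xi_i * phi + P6 * |dchi_i| ) ]
#
# phi is the H-C-C-H torsion in degrees; each substituent contributes an
# electronegativity correction scaled by dchi_i with orientation xi_i = +/-1.
# P6 is a phase in degrees, which is why the whole J machinery works in
# degrees and converts only inside the trig calls.

#' HLA Karplus parameter set
#'
#' @param p numeric length-6 vector (P1..P6). Defaults to the MestReJ
#'   parameterization (14.64, -0.78, 0.58, 0.34, -2.31, 18.40): P1-P5 set
#'   Hz-scale amplitudes, P6 is a phase in degrees.
#' @return a \linkS4class{KarplusParameterSet}
#' @examples
#' karplusParameters()
#' @export
karplusParameters <- function(p = c(14.64, -0.78, 0.58, 0.34, -2.31, 18.40)) {
  p <- as.numeric(p)
  names(p) <- paste0("p", 1:6)
  new("KarplusParameterSet", p = p)
}

#' Load a Karplus parameter set from a YAML config
#'
#' Supports alternative vicinal-coupling parameterizations; the file holds a
#' key \code{params} with six numbers (or keys \code{p1}..\code{p6}).
#'
#' @param path YAML file
#' @return a \linkS4class{KarplusParameterSet}
#' @export
readKarplusParameters <- function(path) {
  if (!file.exists(path))
    vjStop("vicinalJ_config_error", "parameter file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  p <- if (!is.null(cfg$params)) unlist(cfg$params)
       else unlist(cfg[paste0("p", 1:6)])
  if (length(p) != 6L)
    vjStop("vicinalJ_config_error",
           "parameter file %s must supply exactly 6 coefficients", path)
  karplusParameters(p)
}

#' Predict a single-conformer vicinal coupling from the HLA equation
#'
#' @param phi H-C-C-H torsion angle in degrees (scalar or vector; vector
#'   input returns one J per angle)
#' @param substituents data.frame (or NULL) with columns \code{deltaChi} and
#'   \code{xi} (+1/-1), one row per substituent. Substituents with
#'   \code{deltaChi = 0} (hydrogens) may be listed or omitted; the result is
#'   identical.
#' @param params a \linkS4class{KarplusParameterSet}
#' @return predicted \eqn{^3J} in Hz
#' @examples
#' predict3J(180, NULL)  # unsubstituted anti coupling: 16.00 Hz
#' @export
predict3J <- function(phi, substituents = NULL, params = karplusParameters()) {
  stopifnot(all(is.finite(phi)))
  p <- params@p
  cphi <- cos(phi * DEG)
  j <- p[1] * cphi^2 + p[2] * cphi + p[3]
  if (!is.null(substituents) && nrow(substituents)) {
    dchi <- substituents$deltaChi
    xi <- substituents$xi
    if (!all(xi %in% c(-1, 1)))
      vjStop("vicinalJ_validation_error", "every xi must be +1 or -1")
    for (k in seq_along(dchi)) {
      arg <- (xi[k] * phi + p[6] * abs(dchi[k])) * DEG
      j <- j + dchi[k] * (p[4] + p[5] * cos(arg)^2)
    }
  }
  unname(j)
}

#' Sample the substituted Karplus curve over a torsion grid
#'
#' Diagnostic: J evaluated on a regular grid covering (-180, 180].
#'
#' @param substituents as in [predict3J()]
#' @param params a \linkS4class{KarplusParameterSet}
#' @param step grid step in degrees; must divide 360
#' @return data.frame with columns \code{phi} (degrees) and \code{j} (Hz)
#' @export
karplusCurve <- function(substituents = NULL, params = karplusParameters(),
                         step = 1) {
  if (abs(360 / step - round(360 / step)) > 1e-9)
    vjStop("vicinalJ_validation_error", "step must divide 360")
  phi <- seq(-180 + step, 180, by = step)
  data.frame(phi = phi, j = predict3J(phi, substituents, params))
}
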