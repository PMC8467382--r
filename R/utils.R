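# Shared numeric helpers.

DEG <- pi / 180

#' Wrap angles into (-180, 180]
#'
#' @param x angles in degrees
#' @return wrapped angles, each in the half-open interval (-180, 180]
#' @export
wrapAngle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  # floor maps +180 to -180; the convention here keeps +180
  w[w <= -180] <- w[w <= -180] + 360
  w
}

#' Round half away from zero
#'
#' Table-style reports round half away from zero (so 0.25 Hz displays as
#' 0.3 Hz), unlike base R's round-half-even.
#'
#' @param x numeric
#' @param digits decimal digits
#' @return rounded numeric
#' @export
roundHalfUp <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# internal: stop with a classed condition so callers can distinguish
# format/validation/lookup/geometry failures
vjStop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "vicinalJ_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
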