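# Independent brute-force evaluation of the generalized HLA equation,
# deliberately written in a different style from the production code
# (radians throughout, explicit term accumulation) so the two can serve as
# mutual checks.
oracleHLA <- function(phiDeg, deltaChi = numeric(0), xi = numeric(0),
                      p = c(14.64, -0.78, 0.58, 0.34, -2.31, 18.40)) {
  stopifnot(length(deltaChi) == length(xi))
  phi <- phiDeg * pi / 180
  total <- p[1] * cos(phi)^2 + p[2] * cos(phi) + p[3]
  i <- 0
  while (i < length(deltaChi)) {
    i <- i + 1
    phase <- (xi[i] * phiDeg + p[6] * abs(deltaChi[i])) * pi / 180
    total <- total + deltaChi[i] * (p[4] + p[5] * cos(phase) * cos(phase))
  }
  total
}

# independent disagreement statistics for compareJSets checks
oracleDiffStats <- function(measured, predicted) {
  d <- numeric(length(measured))
  for (i in seq_along(measured)) d[i] <- abs(measured[i] - predicted[i])
  list(diffs = d, mean = sum(d) / length(d), max = max(d))
}

# random rigid rotation matrix (QR of a Gaussian matrix, det +1)
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid rotation + translation to every frame
transformEnsemble <- function(ens, rot = diag(3), shift = c(0, 0, 0)) {
  co <- ens@coords
  for (f in seq_len(dim(co)[3]))
    co[, , f] <- co[, , f] %*% t(rot) + matrix(shift, dim(co)[1], 3,
                                               byrow = TRUE)
  conformerEnsemble(ens@atoms, co, ens@frameIds)
}

# reflection through the xy-plane (z -> -z); like any mirror it negates
# torsions, and it maps the builder's canonical frame (first three atoms in
# the z = 0 plane) onto itself, allowing per-atom coordinate comparisons
reflectZ <- function(ens) {
  co <- ens@coords
  co[, 3, ] <- -co[, 3, ]
  conformerEnsemble(ens@atoms, co, ens@frameIds)
}

table1Measured <- function() {
  data.frame(label = c("H40a/H41", "H40b/H41", "H41/H42a", "H41/H42b"),
             jHz = c(4.5, 8.5, 3.2, 9.3), stringsAsFactors = FALSE)
}

table1Calc <- function(candidate = c("41R", "41S")) {
  candidate <- match.arg(candidate)
  jHz <- if (candidate == "41R") c(3.8, 8.7, 3.1, 9.2)
         else c(2.3, 9.7, 4.5, 6.0)
  data.frame(label = table1Measured()$label, jHz = jHz,
             stringsAsFactors = FALSE)
}

exampleTopologyPath <- function() {
  system.file("extdata", "mepartricin_c41_topology.yaml",
              package = "vicinalJ", mustWork = TRUE)
}
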