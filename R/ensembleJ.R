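# Ensemble-averaged couplings.
#
# The coupling is averaged over conformers as <J(phi)>, never as J(<phi>):
# the Karplus curve is strongly nonlinear, so averaging the torsion first
# gives badly wrong results for multimodal rotamer populations (a test pins
# a bimodal case where the two orders differ by several Hz).

#' Ensemble-average a vicinal coupling over a conformer ensemble
#'
#' For each frame the H-C-C-H torsion is measured and the HLA equation
#' evaluated; the per-frame couplings are then averaged arithmetically.
#' Substituent orientation factors are assigned on the first frame
#' ([assignXi()]) and verified constant on a random 1\% sample of frames
#' (at least 5), since a sign flip mid-trajectory would mean the ensemble
#' inverted configuration and the average would be meaningless.
#'
#' If the ensemble holds more than \code{maxFrames} frames it is subsampled
#' with a uniform stride before averaging (default budget 2000 frames, the
#' conventional size of a statistical probe from a long MD run).
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}
#' @param coupling a \linkS4class{CouplingDefinition}
#' @param params a \linkS4class{KarplusParameterSet}
#' @param maxFrames frame budget; longer ensembles are stride-subsampled
#' @param checkFraction fraction of frames on which the orientation factors
#'   are re-checked (minimum 5 frames)
#' @return a \linkS4class{JPredictionReport}
#' @export
ensembleAverageJ <- function(ensemble, coupling, params = karplusParameters(),
                             maxFrames = 2000L, checkFraction = 0.01) {
  validateTopology(ensemble, coupling)
  nf <- nFrames(ensemble)
  if (nf > maxFrames) {
    stride <- seq(1L, nf, length.out = maxFrames)
    ensemble <- conformerEnsemble(
      ensemble@atoms, ensemble@coords[, , unique(round(stride)), drop = FALSE])
    nf <- nFrames(ensemble)
  }
  xi <- assignXi(ensemble, coupling, frame = 1L)
  if (length(xi) && nf > 1L) {
    nCheck <- max(5L, ceiling(checkFraction * nf))
    check <- unique(c(nf, sample.int(nf, min(nCheck, nf))))
    for (f in check) {
      xif <- assignXi(ensemble, coupling, frame = f)
      if (!identical(unname(xif), unname(xi)))
        vjStop("vicinalJ_validation_error",
               "orientation factor changed sign at frame %d of coupling '%s': the ensemble appears to invert configuration",
               f, coupling@label)
    }
  }
  phi <- torsionSeries(ensemble, coupling)$phiDeg
  s <- coupling@substituents
  subs <- if (nrow(s)) data.frame(deltaChi = s$deltaChi, xi = unname(xi[s$atom]))
          else NULL
  j <- predict3J(phi, subs, params)
  se <- c(naive = stats::sd(j) / sqrt(nf), block = blockSE(j))
  new("JPredictionReport",
      couplingLabel = coupling@label,
      jPerFrame = j,
      jMean = mean(j),
      jSD = if (nf > 1L) stats::sd(j) else 0,
      jSE = se,
      nFrames = as.integer(nf),
      convergence = cumsum(j) / seq_len(nf),
      xi = xi)
}

# block-averaging standard error: MD frames are autocorrelated, so the SE of
# the mean is estimated from means of contiguous blocks (default 50 frames)
blockSE <- function(j, block = 50L) {
  n <- length(j)
  nb <- n %/% block
  if (nb < 2L) return(NA_real_)
  bm <- colMeans(matrix(j[seq_len(nb * block)], nrow = block))
  stats::sd(bm) / sqrt(nb)
}

#' Check convergence of the running ensemble average
#'
#' Passes when the cumulative mean moves by no more than \code{tol} over the
#' final \code{window} frames — a guard that the frame budget was large
#' enough for the rotamer populations to equilibrate in the average.
#'
#' @param report a \linkS4class{JPredictionReport}
#' @param window number of trailing frames inspected
#' @param tol maximum allowed drift of the cumulative mean (Hz)
#' @return list with \code{pass} (logical), \code{drift} (Hz, max - min of
#'   the trace over the window) and \code{trace} (the full cumulative mean)
#' @export
convergenceCheck <- function(report, window = 200L, tol = 0.2) {
  stopifnot(is(report, "JPredictionReport"))
  n <- report@nFrames
  if (window >= n)
    vjStop("vicinalJ_validation_error",
           "window (%d) must be smaller than the frame count (%d)", window, n)
  tail_ <- report@convergence[(n - window + 1L):n]
  drift <- max(tail_) - min(tail_)
  list(pass = drift <= tol, drift = drift, trace = report@convergence)
}

#' Write prediction reports as a TSV summary
#'
#' Columns: coupling, n_frames, j_mean, j_sd, j_se_naive, j_se_block. Mean
#' values are written at full precision; round for display with
#' [roundHalfUp()].
#'
#' @param reports list of \linkS4class{JPredictionReport}
#' @param path output TSV path
#' @param perFrame optional path; if given, the per-frame J series are also
#'   dumped (long format: coupling, frame, j_hz)
#' @return \code{path}, invisibly
#' @export
writePredictionTSV <- function(reports, path, perFrame = NULL) {
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(coupling = r@couplingLabel, n_frames = r@nFrames,
               j_mean = r@jMean, j_sd = r@jSD,
               j_se_naive = r@jSE[["naive"]], j_se_block = r@jSE[["block"]])))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(perFrame)) {
    long <- do.call(rbind, lapply(reports, function(r)
      data.frame(coupling = r@couplingLabel, frame = seq_len(r@nFrames),
                 j_hz = r@jPerFrame)))
    utils::write.table(long, perFrame, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
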