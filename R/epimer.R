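# Epimer discrimination against measured couplings, plus the quantitative
# J-threshold geometry rules (olefinic E/Z, sp3 diaxial-range).

#' Compare a measured coupling set against one candidate's predictions
#'
#' Computes per-coupling absolute differences |measured - predicted| and
#' their mean and maximum, at full precision; rounding to 0.1 Hz is applied
#' only in display/report output.
#'
#' @param measured data.frame with columns \code{label} and \code{jHz}
#'   (measured couplings, Hz)
#' @param predicted either a list of \linkS4class{JPredictionReport} objects
#'   or a data.frame with columns \code{label} and \code{jHz} (pre-computed
#'   predictions, e.g. published calculated values)
#' @param candidateLabel candidate name, e.g. \code{"41R"}
#' @return an \linkS4class{EpimerComparison}
#' @examples
#' meas <- data.frame(label = c("a", "b"), jHz = c(4.5, 8.5))
#' pred <- data.frame(label = c("a", "b"), jHz = c(3.8, 8.7))
#' compareJSets(meas, pred, "R")
#' @export
compareJSets <- function(measured, predicted, candidateLabel) {
  if (is.list(predicted) && !is.data.frame(predicted) &&
      all(vapply(predicted, is, logical(1), "JPredictionReport"))) {
    predicted <- data.frame(
      label = vapply(predicted, function(r) r@couplingLabel, character(1)),
      jHz = vapply(predicted, function(r) r@jMean, numeric(1)),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(measured), is.data.frame(predicted))
  if (!setequal(measured$label, predicted$label) ||
      anyDuplicated(measured$label) || anyDuplicated(predicted$label)) {
    onlyM <- setdiff(measured$label, predicted$label)
    onlyP <- setdiff(predicted$label, measured$label)
    vjStop("vicinalJ_validation_error",
           "measured and predicted coupling sets do not match%s%s",
           if (length(onlyM)) paste0("; only measured: ",
                                     paste(onlyM, collapse = ", ")) else "",
           if (length(onlyP)) paste0("; only predicted: ",
                                     paste(onlyP, collapse = ", ")) else "")
  }
  if (nrow(measured) < 1L)
    vjStop("vicinalJ_validation_error", "at least one coupling pair required")
  ord <- match(measured$label, predicted$label)
  pairs <- data.frame(
    coupling = measured$label,
    measured = measured$jHz,
    predicted = predicted$jHz[ord],
    stringsAsFactors = FALSE)
  pairs$absDiff <- abs(pairs$measured - pairs$predicted)
  new("EpimerComparison", candidateLabel = candidateLabel, pairs = pairs,
      meanAbsDiff = mean(pairs$absDiff), maxAbsDiff = max(pairs$absDiff))
}

#' Decide the supported epimer from candidate comparisons
#'
#' The winner is the candidate with the smallest mean absolute disagreement;
#' if the two best means differ by less than \code{margin} the call is
#' \code{"ambiguous"}. The margin guard is a conservative tie-break for
#' closely matched candidates — a well-separated case (means differing by
#' more than an Hz) is unaffected by it.
#'
#' @param comparisons list of \linkS4class{EpimerComparison} objects over the
#'   same coupling set (at least two candidates)
#' @param margin minimum lead of the best mean over the runner-up (Hz)
#' @return list with \code{decision} (winner label or \code{"ambiguous"}),
#'   \code{marginAchieved} (Hz gap between the two best means) and
#'   \code{ranking} (data.frame candidate/meanAbsDiff/maxAbsDiff sorted best
#'   first)
#' @export
decideEpimer <- function(comparisons, margin = 0.5) {
  if (length(comparisons) < 2L)
    vjStop("vicinalJ_validation_error",
           "epimer discrimination requires at least two candidates")
  stopifnot(all(vapply(comparisons, is, logical(1), "EpimerComparison")))
  sets <- lapply(comparisons, function(cp) sort(cp@pairs$coupling))
  for (k in seq_along(sets)[-1])
    if (!identical(sets[[k]], sets[[1]]))
      vjStop("vicinalJ_validation_error",
             "candidates were scored on different coupling sets")
  ranking <- data.frame(
    candidate = vapply(comparisons, function(cp) cp@candidateLabel, character(1)),
    meanAbsDiff = vapply(comparisons, meanAbsDiff, numeric(1)),
    maxAbsDiff = vapply(comparisons, maxAbsDiff, numeric(1)),
    stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$meanAbsDiff, ranking$candidate), ]
  rownames(ranking) <- NULL
  gap <- ranking$meanAbsDiff[2] - ranking$meanAbsDiff[1]
  decision <- if (gap < margin) "ambiguous" else ranking$candidate[1]
  list(decision = decision, marginAchieved = gap, ranking = ranking)
}

#' Classify an olefinic coupling as E, Z or ambiguous
#'
#' Trans (E) olefinic protons couple near 15-16 Hz, cis (Z) near 11-12 Hz.
#' The default thresholds sit between the observed ranges: E for
#' J >= \code{eMin}, Z for J <= \code{zMax}, ambiguous between.
#'
#' @param jHz measured coupling(s), Hz (non-negative; vectorized)
#' @param eMin minimum J called E (default 14.0 Hz)
#' @param zMax maximum J called Z (default 12.5 Hz)
#' @param bondLabel optional label(s) carried into the result
#' @return data.frame with columns \code{bond}, \code{jHz}, \code{call}
#' @examples
#' classifyOlefinic(c(15.3, 11.5, 13.0))$call # "E" "Z" "ambiguous"
#' @export
classifyOlefinic <- function(jHz, eMin = 14.0, zMax = 12.5, bondLabel = NULL) {
  stopifnot(all(jHz >= 0), zMax < eMin)
  call <- ifelse(jHz >= eMin, "E", ifelse(jHz <= zMax, "Z", "ambiguous"))
  data.frame(bond = if (is.null(bondLabel)) as.character(seq_along(jHz))
                    else bondLabel,
             jHz = jHz, call = call, stringsAsFactors = FALSE)
}

#' Classify an sp3-sp3 coupling by the diaxial-range rule
#'
#' Large vicinal couplings (roughly 9-12 Hz) between ring protons are
#' characteristic of a diaxial (anti) arrangement; small couplings
#' (< ~6 Hz) of gauche arrangements. Defaults: diaxial-range for
#' J >= \code{diaxialMin}, small for J <= \code{smallMax}, intermediate
#' between.
#'
#' @param jHz measured coupling(s), Hz (non-negative; vectorized)
#' @param diaxialMin minimum J called diaxial-range (default 9.0 Hz)
#' @param smallMax maximum J called small (default 6.0 Hz)
#' @param bondLabel optional label(s) carried into the result
#' @return data.frame with columns \code{bond}, \code{jHz}, \code{call}
#' @examples
#' classifySp3(c(10.5, 5.6, 7.5))$call # "diaxial-range" "small" "intermediate"
#' @export
classifySp3 <- function(jHz, diaxialMin = 9.0, smallMax = 6.0,
                        bondLabel = NULL) {
  stopifnot(all(jHz >= 0), smallMax < diaxialMin)
  call <- ifelse(jHz >= diaxialMin, "diaxial-range",
                 ifelse(jHz <= smallMax, "small", "intermediate"))
  data.frame(bond = if (is.null(bondLabel)) as.character(seq_along(jHz))
                    else bondLabel,
             jHz = jHz, call = call, stringsAsFactors = FALSE)
}

#' Write a comparison table and decision record
#'
#' Emits a table-shaped TSV (one row per coupling: measured value, then per
#' candidate the predicted value and |difference|, rounded half-away-from-
#' zero to 0.1 Hz) and a JSON decision record with full-precision
#' statistics.
#'
#' @param comparisons list of \linkS4class{EpimerComparison}
#' @param decision result of [decideEpimer()]
#' @param tsvPath output TSV path
#' @param jsonPath output JSON path
#' @return invisibly, list of the two paths
#' @export
writeComparisonReport <- function(comparisons, decision, tsvPath, jsonPath) {
  base <- comparisons[[1]]@pairs[, c("coupling", "measured")]
  tab <- base
  for (cp in comparisons) {
    ord <- match(base$coupling, cp@pairs$coupling)
    tab[[paste0("calc_", cp@candidateLabel)]] <-
      roundHalfUp(cp@pairs$predicted[ord], 1)
    tab[[paste0("absdiff_", cp@candidateLabel)]] <-
      roundHalfUp(cp@pairs$absDiff[ord], 1)
  }
  utils::write.table(tab, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rec <- list(
    decision = decision$decision,
    margin_achieved_hz = decision$marginAchieved,
    ranking = decision$ranking,
    candidates = lapply(comparisons, function(cp) list(
      candidate = cp@candidateLabel,
      mean_abs_diff_hz = cp@meanAbsDiff,
      max_abs_diff_hz = cp@maxAbsDiff)))
  jsonlite::write_json(rec, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(tsv = tsvPath, json = jsonPath))
}
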