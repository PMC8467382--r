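# Workflow orchestration: predict / compare / simulate runs driven by a
# YAML run config. Flags from the CLI wrapper arrive as an `overrides` list
# and take precedence over file values. Every run writes a provenance JSON
# (config echo, seed, package version) sufficient to reproduce it.

readRunConfig <- function(configPath, overrides = list()) {
  if (!file.exists(configPath))
    vjStop("vicinalJ_config_error", "run config not found: %s", configPath)
  cfg <- yaml::read_yaml(configPath)
  for (k in names(overrides))
    if (!is.null(overrides[[k]])) cfg[[k]] <- overrides[[k]]
  cfg
}

vjLog <- function(fmt, ...) message(sprintf(paste0("[vicinalJ] ", fmt), ...))

writeProvenance <- function(cfg, outDir, extra = list()) {
  rec <- c(list(
    package = "vicinalJ",
    version = as.character(utils::packageVersion("vicinalJ")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = cfg), extra)
  jsonlite::write_json(rec, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
}

loadEnsembleFile <- function(path) {
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) readXYZFrames(path)
  else readMultimodelPDB(path)
}

resolveParams <- function(cfg) {
  if (!is.null(cfg$params)) readKarplusParameters(cfg$params)
  else karplusParameters()
}

# predict reports for one ensemble over all couplings of a topology
predictForEnsemble <- function(ensemble, topology, params, maxFrames) {
  lapply(topology$couplings, function(cp) {
    ensembleAverageJ(ensemble, cp, params, maxFrames = maxFrames)
  })
}

#' Run the prediction workflow
#'
#' Reads a conformer ensemble and a coupling topology, computes
#' ensemble-averaged couplings for every defined coupling, and writes TSV +
#' JSON reports plus a provenance record into the output directory. The log
#' records frame counts, orientation-factor assignments and the convergence
#' verdict per coupling.
#'
#' Config keys: \code{ensemble} (PDB/XYZ path), \code{topology} (YAML path),
#' \code{params} (optional YAML path), \code{n_frames} (frame budget,
#' default 2000), \code{out} (output directory).
#'
#' @param configPath YAML run config
#' @param overrides named list of config overrides (e.g. from CLI flags)
#' @return invisibly, the list of \linkS4class{JPredictionReport}
#' @export
runPredict <- function(configPath, overrides = list()) {
  cfg <- readRunConfig(configPath, overrides)
  for (key in c("ensemble", "topology", "out"))
    if (is.null(cfg[[key]]))
      vjStop("vicinalJ_config_error", "predict config needs '%s'", key)
  if (!file.exists(cfg$topology))
    vjStop("vicinalJ_config_error", "topology file not found: %s", cfg$topology)
  nf <- if (is.null(cfg$n_frames)) 2000L else as.integer(cfg$n_frames)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  topology <- readTopologyConfig(cfg$topology)
  ensemble <- loadEnsembleFile(cfg$ensemble)
  if (nf > nFrames(ensemble)) {
    warning(sprintf("requested %d frames but ensemble has %d; using all",
                    nf, nFrames(ensemble)))
    nf <- nFrames(ensemble)
  }
  vjLog("predict: %d atoms, %d frames, %d coupling(s)",
        nAtoms(ensemble), nFrames(ensemble), length(topology$couplings))
  params <- resolveParams(cfg)
  reports <- predictForEnsemble(ensemble, topology, params, nf)
  for (r in reports) {
    cv <- convergenceCheck(r, window = min(200L, max(1L, r@nFrames - 1L)))
    vjLog("  %-12s n=%d  <J>=%.2f Hz  xi=[%s]  convergence %s (drift %.3f Hz)",
          r@couplingLabel, r@nFrames, r@jMean,
          paste(sprintf("%s:%+d", names(r@xi), r@xi), collapse = " "),
          if (cv$pass) "ok" else "NOT converged", cv$drift)
  }
  writePredictionTSV(reports, file.path(cfg$out, "predictions.tsv"),
                     perFrame = if (isTRUE(cfg$per_frame))
                       file.path(cfg$out, "j_per_frame.tsv") else NULL)
  jsonlite::write_json(
    lapply(reports, function(r) list(
      coupling = r@couplingLabel, n_frames = r@nFrames, j_mean = r@jMean,
      j_sd = r@jSD, j_se_naive = r@jSE[["naive"]],
      j_se_block = r@jSE[["block"]], xi = as.list(r@xi))),
    file.path(cfg$out, "predictions.json"), auto_unbox = TRUE, digits = NA)
  writeProvenance(cfg, cfg$out)
  invisible(reports)
}

# a candidate entry: label + either 'ensemble' (structure file) or
# 'predictions' (TSV with columns label, j_mean or label, j_hz)
loadCandidatePredictions <- function(cand, topology, params, maxFrames) {
  if (!is.null(cand$predictions)) {
    df <- utils::read.delim(cand$predictions, stringsAsFactors = FALSE)
    jcol <- intersect(c("j_mean", "j_hz", "jHz"), names(df))
    if (!length(jcol) || is.null(df$label))
      vjStop("vicinalJ_config_error",
             "prediction table %s needs columns 'label' and 'j_mean' (or 'j_hz')",
             cand$predictions)
    data.frame(label = df$label, jHz = df[[jcol[1]]], stringsAsFactors = FALSE)
  } else if (!is.null(cand$ensemble)) {
    reports <- predictForEnsemble(loadEnsembleFile(cand$ensemble), topology,
                                  params, maxFrames)
    data.frame(
      label = vapply(reports, function(r) r@couplingLabel, character(1)),
      jHz = vapply(reports, function(r) r@jMean, numeric(1)),
      stringsAsFactors = FALSE)
  } else {
    vjStop("vicinalJ_config_error",
           "candidate '%s' needs 'ensemble' or 'predictions'", cand$label)
  }
}

#' Run the epimer-comparison workflow
#'
#' Scores two or more stereochemical candidates against a measured coupling
#' set and writes a comparison table (TSV), a decision record (JSON) and
#' provenance. Candidates may be conformer ensembles (predicted here) or
#' pre-computed prediction tables, so published calculated values can be
#' compared without any ensemble.
#'
#' Config keys: \code{topology} (YAML with \code{couplings} and
#' \code{measured}), \code{candidates} (list of \code{{label, ensemble}} or
#' \code{{label, predictions}}), \code{params}, \code{n_frames},
#' \code{margin} (ambiguity guard, Hz, default 0.5), \code{out}.
#'
#' @param configPath YAML run config
#' @param overrides named list of config overrides
#' @return invisibly, list with \code{comparisons} and \code{decision}
#' @export
runCompare <- function(configPath, overrides = list()) {
  cfg <- readRunConfig(configPath, overrides)
  for (key in c("topology", "candidates", "out"))
    if (is.null(cfg[[key]]))
      vjStop("vicinalJ_config_error", "compare config needs '%s'", key)
  if (length(cfg$candidates) < 2L)
    vjStop("vicinalJ_config_error", "compare needs at least two candidates")
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  topology <- readTopologyConfig(cfg$topology)
  if (!nrow(topology$measured))
    vjStop("vicinalJ_config_error",
           "topology config must carry a 'measured' section for compare")
  params <- resolveParams(cfg)
  nf <- if (is.null(cfg$n_frames)) 2000L else as.integer(cfg$n_frames)
  margin <- if (is.null(cfg$margin)) 0.5 else as.numeric(cfg$margin)
  comparisons <- lapply(cfg$candidates, function(cand) {
    pred <- loadCandidatePredictions(cand, topology, params, nf)
    compareJSets(topology$measured, pred, cand$label)
  })
  decision <- decideEpimer(comparisons, margin = margin)
  vjLog("compare: decision '%s' (margin %.3f Hz)", decision$decision,
        decision$marginAchieved)
  writeComparisonReport(comparisons, decision,
                        file.path(cfg$out, "comparison.tsv"),
                        file.path(cfg$out, "decision.json"))
  writeProvenance(cfg, cfg$out)
  invisible(list(comparisons = comparisons, decision = decision))
}

#' Run the simulation workflow
#'
#' Generates seeded rotamer ensembles with ground truth for one or both
#' epimers of the built-in chiral fragment and writes multi-model PDB files
#' plus JSON truth sidecars. Identical seeds give byte-identical output.
#'
#' Config keys: \code{seed} (required), \code{n_frames} (default 2000),
#' \code{chirality} (\code{"R"}, \code{"S"} or a list of both; default
#' both), \code{hbond_bias} (default TRUE), \code{rotamers} (optional list
#' of \code{{torsion, centers, weights, kappa}} overriding the defaults),
#' \code{out}.
#'
#' @param configPath YAML run config
#' @param overrides named list of config overrides
#' @return invisibly, named list of generation results per chirality
#' @export
runSimulate <- function(configPath, overrides = list()) {
  cfg <- readRunConfig(configPath, overrides)
  if (is.null(cfg$out))
    vjStop("vicinalJ_config_error", "simulate config needs 'out'")
  if (is.null(cfg$seed))
    vjStop("vicinalJ_config_error", "simulate requires a seed")
  nf <- if (is.null(cfg$n_frames)) 2000L else as.integer(cfg$n_frames)
  chir <- if (is.null(cfg$chirality)) c("R", "S") else unlist(cfg$chirality)
  specs <- NULL
  if (!is.null(cfg$rotamers))
    specs <- lapply(cfg$rotamers, function(rs)
      rotamerSpec(rs$torsion, unlist(rs$centers), unlist(rs$weights),
                  if (is.null(rs$kappa)) 20 else unlist(rs$kappa)))
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  for (ch in chir) {
    bp <- fragmentBlueprint(ch,
                            hbondBias = if (is.null(cfg$hbond_bias)) TRUE
                                        else cfg$hbond_bias,
                            sampledTorsions = specs)
    gen <- generateRotamerEnsemble(bp, nf, seed = as.integer(cfg$seed))
    writeEnsembleWithTruth(gen,
                           file.path(cfg$out, sprintf("ensemble_%s.pdb", ch)),
                           file.path(cfg$out, sprintf("truth_%s.json", ch)))
    vjLog("simulate: wrote %d-frame %s ensemble (seed %d)", nf, ch,
          as.integer(cfg$seed))
    results[[ch]] <- gen
  }
  writeProvenance(cfg, cfg$out, extra = list(seed = as.integer(cfg$seed)))
  invisible(results)
}
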