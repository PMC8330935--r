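## Pipeline orchestration: simulate/load -> preprocess -> binarize ->
## quantify -> annotate -> fit, with a JSON run manifest and optional
## settings-grid mode.

#' Pipeline configuration
#'
#' Exactly one input source: a \linkS4class{SimulationConfig} (or the path
#' to its YAML) or a fixture directory written by
#' \code{\link{writeFixtureSet}}.
#'
#' @param simulation \linkS4class{SimulationConfig}, YAML path, or NULL.
#' @param fixtures fixture directory, or NULL.
#' @param slab "10@31" or "20@29" (simulation input only).
#' @param compensation,radiusPolicy,icdUm,vesselDilationUm quantification
#'   settings (see \code{\link{quantifyOptions}}).
#' @param grid when TRUE, runs all four compensation-by-radius
#'   combinations and tabulates FD% per combination (slabs are never mixed
#'   within one fit).
#' @param statsMinEyes smallest per-group size for which the statistical
#'   stage runs (default 10; below it the stage is skipped with a warning
#'   rather than fitting unstable models).
#' @param outDir output directory.
#' @return named list, validated.
#' @export
pipelineConfig <- function(simulation = NULL, fixtures = NULL,
                           slab = "10@31", compensation = TRUE,
                           radiusPolicy = "15", icdUm = 24,
                           vesselDilationUm = 12, grid = FALSE,
                           statsMinEyes = 10, outDir = tempfile("ccfdq")) {
  if (is.null(simulation) == is.null(fixtures))
    stop("exactly one input source (simulation or fixtures) is required")
  if (is.character(simulation)) {
    if (!file.exists(simulation))
      stop("simulation config not found: ", simulation)
    simulation <- readSimulationConfig(simulation)
  }
  if (!is.null(fixtures) && !dir.exists(fixtures))
    stop("fixture directory not found: ", fixtures)
  list(simulation = simulation, fixtures = fixtures, slab = slab,
       compensation = compensation, radiusPolicy = radiusPolicy,
       icdUm = icdUm, vesselDilationUm = vesselDilationUm, grid = grid,
       statsMinEyes = statsMinEyes, outDir = outDir)
}

.statsReport <- function(sectors, eyes) {
  fd <- fitFDMixedModel(fdModelRows(sectors))
  uni <- fitLCVGlmm(sectors, c("ct", "group", "orientation"),
                    "univariate")
  multi <- tryCatch(
    fitLCVGlmm(sectors, c("ct", "group", "orientation"), "multivariable"),
    error = function(e) NULL)
  cut <- youdenCutoff(sectors$ct_um, sectors$lcv, sectors$eye_id)
  eyeCct <- tryCatch(fitEyeLevelLogistic(eyes, "cct_um"),
                     error = function(e) NULL)
  list(
    fd_mixed_model = list(
      contrasts = fd@contrasts,
      ranef_var = fd@ranefVar, resid_var = fd@residVar),
    lcv_univariate = lapply(uni, function(r)
      list(terms = r@terms, n_obs = r@nObs, n_patients = r@nPatients,
           separation = r@separation)),
    lcv_multivariable = if (!is.null(multi))
      list(terms = multi@terms, n_obs = multi@nObs,
           separation = multi@separation),
    eye_level_cct = if (!is.null(eyeCct)) list(terms = eyeCct@terms),
    ct_cutoff = list(threshold_um = cut@thresholdUm,
                     sensitivity = cut@sensitivity,
                     specificity = cut@specificity,
                     youden_j = cut@youdenJ,
                     sens_ci = cut@sensCi, spec_ci = cut@specCi,
                     n = cut@n))
}

#' Run the full pipeline
#'
#' Simulates or loads a cohort, quantifies FD% in the four corner sectors
#' of every eye, annotates CT/LCV/drusen, optionally fits the statistical
#' layer, and writes the sector table (CSV), the stats report (JSON), and
#' a run manifest (JSON with file checksums and the configuration).
#' Reruns with an identical configuration are bit-identical.
#'
#' @param config list from \code{\link{pipelineConfig}}.
#' @return list with \code{sectors}, \code{eyes}, \code{stats} (NULL when
#'   skipped), \code{grid} (NULL unless grid mode), \code{manifest};
#'   invisibly.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  scenes <- tryCatch({
    if (!is.null(config$simulation))
      simulateCohort(config$simulation, slab = config$slab)
    else
      readFixtureSet(config$fixtures)
  }, error = function(e) stop("[stage simulate/load] ",
                              conditionMessage(e), call. = FALSE))

  opts <- quantifyOptions(compensation = config$compensation,
                          radiusPolicy = config$radiusPolicy,
                          icdUm = config$icdUm,
                          vesselDilationUm = config$vesselDilationUm)
  tab <- tryCatch(buildSectorTable(scenes, opts),
                  error = function(e) stop("[stage quantify] ",
                                           conditionMessage(e),
                                           call. = FALSE))
  sectors <- tab$sectors
  eyes <- tab$eyes

  gridTab <- NULL
  if (isTRUE(config$grid)) {
    combos <- expand.grid(compensation = c(TRUE, FALSE),
                          radiusPolicy = c("15", "adjusted"),
                          stringsAsFactors = FALSE)
    gridTab <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
      o <- quantifyOptions(compensation = combos$compensation[k],
                           radiusPolicy = combos$radiusPolicy[k],
                           icdUm = config$icdUm,
                           vesselDilationUm = config$vesselDilationUm)
      s <- buildSectorTable(scenes, o)$sectors
      data.frame(compensation = combos$compensation[k],
                 radius = combos$radiusPolicy[k],
                 eye_id = s$eye_id, sector = s$sector,
                 fd_percent = s$fd_percent)
    }))
  }

  nPerGroup <- table(eyes$group)
  stats <- NULL
  if (length(nPerGroup) == 2 && all(nPerGroup >= config$statsMinEyes)) {
    stats <- tryCatch(.statsReport(sectors, eyes),
                      error = function(e) stop("[stage stats] ",
                                               conditionMessage(e),
                                               call. = FALSE))
  } else {
    warning("statistics stage skipped: fewer than ", config$statsMinEyes,
            " eyes in a group")
  }

  secPath <- file.path(config$outDir, "sectors.csv")
  write.csv(sectors, secPath, row.names = FALSE)
  eyePath <- file.path(config$outDir, "eyes.csv")
  write.csv(eyes, eyePath, row.names = FALSE)
  outFiles <- c(secPath, eyePath)
  if (!is.null(stats)) {
    statsPath <- file.path(config$outDir, "stats.json")
    jsonlite::write_json(stats, statsPath, auto_unbox = TRUE, digits = NA,
                         force = TRUE, dataframe = "columns")
    outFiles <- c(outFiles, statsPath)
  }
  if (!is.null(gridTab)) {
    gridPath <- file.path(config$outDir, "grid.csv")
    write.csv(gridTab, gridPath, row.names = FALSE)
    outFiles <- c(outFiles, gridPath)
  }

  cfgEcho <- config
  cfgEcho$simulation <- if (!is.null(config$simulation))
    lapply(slotNames(config$simulation), function(s)
      slot(config$simulation, s))
  if (!is.null(cfgEcho$simulation))
    names(cfgEcho$simulation) <- slotNames(config$simulation)
  manifest <- list(
    tool = "ccfdq", stage_outputs = as.list(
      stats::setNames(unname(tools::md5sum(outFiles)),
                      basename(outFiles))),
    n_eyes = nrow(eyes), n_sectors = nrow(sectors),
    config = cfgEcho)
  jsonlite::write_json(manifest, file.path(config$outDir,
                                           "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sectors = sectors, eyes = eyes, stats = stats,
                 grid = gridTab, manifest = manifest))
}
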