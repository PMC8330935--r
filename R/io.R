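## Fixture IO: TIFF images, PNG masks, CSV truth tables, JSON manifest.
##
## Images are 16-bit grayscale TIFF; scene pixels are already quantized to
## the 16-bit grid, so the round trip is lossless. Depth maps are stored on
## a 0.1 um grid in 16-bit TIFF (scale recorded in the manifest). Masks are
## 8-bit PNG holding {0, 255}; the reader re-binarises.

.DEPTH_SCALE <- 10  # stored integer units per micrometre

.writeTiff16 <- function(m, path) {
  tiff::writeTIFF(m, path, bits.per.sample = 16, compression = "none")
}

.readTiff16 <- function(path) {
  m <- tiff::readTIFF(path)
  round(m * 65535) / 65535
}

.writeMask <- function(m, path) {
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
}

.readMask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

.writeDepth <- function(m, path) {
  .writeTiff16(m * .DEPTH_SCALE / 65535, path)
}

.readDepth <- function(path) {
  round(tiff::readTIFF(path) * 65535) / .DEPTH_SCALE
}

#' Write a fixture set of synthetic scenes
#'
#' Writes one directory per eye (angio/structural TIFF, LCV/drusen/vessel
#' PNG masks, BM and sclera depth TIFFs), a cohort truth CSV, a metadata
#' CSV, and a JSON manifest listing every file with its MD5 checksum. The
#' set round-trips losslessly through \code{\link{readFixtureSet}}.
#'
#' @param scenes list of \linkS4class{EyeScene}.
#' @param directory output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
writeFixtureSet <- function(scenes, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  eyeEntries <- list()
  truthRows <- list()
  metaRows <- list()
  for (sc in scenes) {
    ed <- file.path(directory, sc@eyeId)
    dir.create(ed, showWarnings = FALSE)
    tr <- sc@truth
    files <- c(angio = "angio.tif", structural = "structural.tif",
               lcv_mask = "lcv_mask.png", drusen_mask = "drusen_mask.png",
               vessel_mask = "vessel_mask.png", bm_depth = "bm_depth.tif",
               sclera_depth = "sclera_depth.tif")
    .writeTiff16(sc@angio@pixels, file.path(ed, files["angio"]))
    .writeTiff16(sc@structural@pixels, file.path(ed, files["structural"]))
    .writeMask(tr@lcvMask, file.path(ed, files["lcv_mask"]))
    .writeMask(tr@drusenMask, file.path(ed, files["drusen_mask"]))
    .writeMask(tr@vesselMask, file.path(ed, files["vessel_mask"]))
    .writeDepth(tr@bmOuterDepth, file.path(ed, files["bm_depth"]))
    .writeDepth(tr@scleraInnerDepth, file.path(ed, files["sclera_depth"]))
    sums <- tools::md5sum(file.path(ed, files))
    names(sums) <- NULL
    eyeEntries[[sc@eyeId]] <- list(
      group = sc@group, laterality = sc@laterality,
      slab_offset_um = sc@angio@slab$offset_um,
      slab_thickness_um = sc@angio@slab$thickness_um,
      pitch_um = sc@angio@pitchUm,
      rasters = as.list(stats::setNames(
        file.path(sc@eyeId, files), names(files))),
      md5 = as.list(stats::setNames(sums, names(files))))
    sec <- cornerSectors(nrow(sc@angio@pixels), sc@angio@pitchUm,
                         sc@laterality)
    truthRows[[sc@eyeId]] <- data.frame(
      eye_id = sc@eyeId, group = sc@group, laterality = sc@laterality,
      sector = 1:4, orientation = sec$orientation, ct_um = tr@ctUm,
      true_fd_fraction = tr@fdFraction, lcv = tr@lcvSector,
      drusen = tr@drusenSector)
    metaRows[[sc@eyeId]] <- data.frame(
      eye_id = sc@eyeId, group = sc@group, laterality = sc@laterality,
      cct_um = tr@cctUm, eye_color = sc@metadata$eye_color,
      spherical_equivalent = sc@metadata$se)
  }
  write.csv(do.call(rbind, truthRows), file.path(directory, "truth.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, metaRows), file.path(directory, "metadata.csv"),
            row.names = FALSE)
  manifest <- list(
    format = "ccfdq-fixture-set", version = 1L,
    depth_scale_per_um = .DEPTH_SCALE,
    truth_csv = "truth.csv", metadata_csv = "metadata.csv",
    truth_md5 = unname(tools::md5sum(file.path(directory, "truth.csv"))),
    metadata_md5 = unname(tools::md5sum(file.path(directory,
                                                  "metadata.csv"))),
    eyes = eyeEntries)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture set back into scenes
#'
#' Verifies every MD5 checksum recorded in the manifest before loading;
#' tampered or corrupted files raise an error.
#'
#' @param directory a directory written by \code{\link{writeFixtureSet}}.
#' @return list of \linkS4class{EyeScene}.
#' @export
readFixtureSet <- function(directory) {
  mf <- jsonlite::read_json(file.path(directory, "manifest.json"),
                            simplifyVector = FALSE)
  if (!identical(mf$format, "ccfdq-fixture-set"))
    stop("not a ccfdq fixture set: ", directory)
  .checkSum <- function(path, expected) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, expected))
      stop("checksum mismatch for ", path)
  }
  .checkSum(file.path(directory, mf$truth_csv), mf$truth_md5)
  .checkSum(file.path(directory, mf$metadata_csv), mf$metadata_md5)
  truth <- read.csv(file.path(directory, mf$truth_csv))
  meta <- read.csv(file.path(directory, mf$metadata_csv))

  scenes <- vector("list", length(mf$eyes))
  for (i in seq_along(mf$eyes)) {
    id <- names(mf$eyes)[i]
    e <- mf$eyes[[i]]
    paths <- lapply(e$rasters, function(p) file.path(directory, p))
    for (nm in names(paths)) .checkSum(paths[[nm]], e$md5[[nm]])
    angio <- .readTiff16(paths$angio)
    structural <- .readTiff16(paths$structural)
    slab <- list(offset_um = e$slab_offset_um,
                 thickness_um = e$slab_thickness_um)
    trRows <- truth[truth$eye_id == id, ]
    trRows <- trRows[order(trRows$sector), ]
    mRow <- meta[meta$eye_id == id, ]
    tr <- new("GroundTruth",
              fdFraction = trRows$true_fd_fraction,
              lcvMask = .readMask(paths$lcv_mask),
              drusenMask = .readMask(paths$drusen_mask),
              vesselMask = .readMask(paths$vessel_mask),
              bmOuterDepth = .readDepth(paths$bm_depth),
              scleraInnerDepth = .readDepth(paths$sclera_depth),
              ctUm = trRows$ct_um, cctUm = mRow$cct_um,
              lcvSector = trRows$lcv, drusenSector = trRows$drusen)
    scenes[[i]] <- new("EyeScene", eyeId = id, group = e$group,
      laterality = e$laterality,
      angio = new("EnFaceImage", pixels = angio, pitchUm = e$pitch_um,
                  laterality = e$laterality, kind = "angio", slab = slab),
      structural = new("EnFaceImage", pixels = structural,
                       pitchUm = e$pitch_um, laterality = e$laterality,
                       kind = "structural", slab = slab),
      truth = tr,
      metadata = list(se = mRow$spherical_equivalent,
                      eye_color = mRow$eye_color, cct_um = mRow$cct_um))
  }
  scenes
}

#' Read a SimulationConfig from YAML
#'
#' Keys use the underscore naming of the fixture format (seed, n_iamd,
#' n_control, image_size_px, ...); missing keys keep the calibrated
#' defaults.
#'
#' @param path YAML file.
#' @return A \linkS4class{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  map <- c(seed = "seed", n_iamd = "nIamd", n_control = "nControl",
    image_size_px = "imageSizePx", scan_size_um = "scanSizeUm",
    fd_fraction_iamd = "fdFractionIamd",
    fd_fraction_control = "fdFractionControl",
    fd_fraction_sd = "fdFractionSd",
    lcv_intercept = "lcvIntercept", lcv_ct_slope = "lcvCtSlope",
    lcv_nasal_shift = "lcvNasalShift", lcv_re_sd = "lcvReSd",
    ct_sector_means_um = "ctSectorMeansUm", ct_sector_sd_um = "ctSectorSdUm",
    cct_mean_um = "cctMeanUm", cct_sd_um = "cctSdUm", ct_min_um = "ctMinUm",
    noise_sd = "noiseSd", lcv_width_um_range = "lcvWidthUmRange",
    lcv_intensity_factor = "lcvIntensityFactor",
    lcv_structural_factor = "lcvStructuralFactor",
    drusen_rate = "drusenRate",
    drusen_radius_um_range = "drusenRadiusUmRange",
    render_lcv = "renderLcv", render_vessels = "renderVessels",
    texture_sigma_um = "textureSigmaUm", flow_level = "flowLevel",
    fd_level = "fdLevel", structural_base = "structuralBase")
  args <- list()
  for (k in names(y)) {
    if (!k %in% names(map)) stop("unknown simulation key: ", k)
    args[[map[[k]]]] <- if (is.list(y[[k]])) unlist(y[[k]]) else y[[k]]
  }
  do.call(SimulationConfig, args)
}
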