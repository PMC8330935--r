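## Flow-deficit particle analysis and corner-sector FD% measurement.
##
## Connected FD regions are detected with 8-connectivity (ImageJ "analyze
## particles" behaviour: diagonal neighbours join one particle), regions
## smaller than the mean intercapillary distance are discarded, and FD% is
## measured within four 1x1 mm squares flush to the image corners.

#' Label connected flow-deficit components
#'
#' 8-connected component labelling of an FD mask. Pixels flagged invalid
#' (e.g. below superficial-plexus projections) never join a component.
#'
#' @param fdMask \linkS4class{BinaryMask} of FD pixels.
#' @param valid optional logical matrix; FALSE pixels are skipped.
#' @return A list with \code{labels} (integer matrix, 0 = background) and
#'   \code{components}, a data.frame with one row per component: id,
#'   pixel_count, centroid (px, row/col), bounding box.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' labelFDComponents(BinaryMask(m))$components$pixel_count  # one particle
#' @export
labelFDComponents <- function(fdMask, valid = NULL) {
  stopifnot(is(fdMask, "BinaryMask"))
  px <- fdMask@pixels
  if (is.null(valid)) valid <- matrix(TRUE, nrow(px), ncol(px))
  lab <- .labelComponents(px, valid)
  nc <- max(lab)
  if (nc == 0L) {
    comp <- data.frame(id = integer(), pixel_count = integer(),
                       centroid_row = numeric(), centroid_col = numeric(),
                       row_min = integer(), row_max = integer(),
                       col_min = integer(), col_max = integer())
    return(list(labels = lab, components = comp))
  }
  idx <- which(lab > 0L)
  id <- lab[idx]
  ri <- (idx - 1L) %% nrow(lab) + 1L
  ci <- (idx - 1L) %/% nrow(lab) + 1L
  comp <- data.frame(
    id = seq_len(nc),
    pixel_count = as.integer(tabulate(id, nc)),
    centroid_row = as.numeric(tapply(ri, id, mean)),
    centroid_col = as.numeric(tapply(ci, id, mean)),
    row_min = as.integer(tapply(ri, id, min)),
    row_max = as.integer(tapply(ri, id, max)),
    col_min = as.integer(tapply(ci, id, min)),
    col_max = as.integer(tapply(ci, id, max)))
  list(labels = lab, components = comp)
}

#' Minimum FD area from the intercapillary distance
#'
#' Area in pixels of a circle whose diameter is the mean intercapillary
#' distance: \code{ceiling(pi * (icd/2)^2 / pitch^2)}. FDs smaller than
#' this are indistinguishable from normal capillary spacing and noise.
#'
#' @param icdUm mean intercapillary distance in micrometres (~24).
#' @param pitchUm micrometres per pixel.
#' @return integer minimum component size in pixels (>= 1).
#' @examples
#' minFDAreaPx(24, 6000 / 1024)  # 14
#' @export
minFDAreaPx <- function(icdUm, pitchUm) {
  if (icdUm <= 0 || pitchUm <= 0) stop("all inputs must be positive")
  max(1L, as.integer(ceiling(pi * (icdUm / 2)^2 / pitchUm^2)))
}

#' Remove flow deficits below the size limit
#'
#' Components with \code{pixel_count < minAreaPx} are removed (strict
#' inequality: "smaller than" the ICD area). The returned mask contains
#' exactly the union of the kept components.
#'
#' @param labelled result of \code{\link{labelFDComponents}}.
#' @param minAreaPx integer >= 1.
#' @return A list with \code{components} (kept rows) and \code{mask}
#'   (logical matrix of kept FD pixels).
#' @export
filterSmallFD <- function(labelled, minAreaPx) {
  if (minAreaPx < 1) stop("minAreaPx must be >= 1")
  comp <- labelled$components
  keep <- comp[comp$pixel_count >= minAreaPx, , drop = FALSE]
  mask <- matrix(labelled$labels %in% keep$id, nrow(labelled$labels),
                 ncol(labelled$labels))
  list(components = keep, mask = mask)
}

#' Lay out the four 1x1 mm corner sectors
#'
#' Squares of side \code{round(1000 / pitch)} pixels flush to the four
#' image corners, numbered clockwise from top-left (1 = top-left,
#' 2 = top-right, 3 = bottom-right, 4 = bottom-left). Orientation follows
#' fundus display convention: for a right eye (OD) the nasal side is the
#' right image half, for a left eye (OS) the left half; two sectors are
#' always nasal and two temporal.
#'
#' @param imageSizePx image side in pixels.
#' @param pitchUm micrometres per pixel.
#' @param laterality "OD" or "OS".
#' @param nasalSide overrides the laterality convention; "right" or "left"
#'   half of the image (device dialects differ).
#' @return data.frame with one row per sector: index, row0/row1, col0/col1
#'   (half-open pixel intervals), orientation, vertical position, centre.
#' @examples
#' cornerSectors(1024, 6000 / 1024, "OD")
#' @export
cornerSectors <- function(imageSizePx, pitchUm, laterality = "OD",
                          nasalSide = NULL) {
  imageSizePx <- as.integer(imageSizePx)
  side <- as.integer(round(1000 / pitchUm))
  if (side > imageSizePx / 2)
    stop("image too small: sectors would overlap")
  if (is.null(nasalSide))
    nasalSide <- if (laterality == "OD") "right" else "left"
  lo <- c(0L, imageSizePx - side)
  sec <- data.frame(
    index = 1:4,
    row0 = c(lo[1], lo[1], lo[2], lo[2]),
    row1 = c(side, side, imageSizePx, imageSizePx),
    col0 = c(lo[1], lo[2], lo[2], lo[1]),
    col1 = c(side, imageSizePx, imageSizePx, side),
    vertical = c("superior", "superior", "inferior", "inferior"))
  rightHalf <- (sec$col0 + sec$col1) / 2 >= imageSizePx / 2
  sec$orientation <- ifelse(rightHalf == (nasalSide == "right"),
                            "nasal", "temporal")
  sec$centre_row <- (sec$row0 + sec$row1 + 1) / 2
  sec$centre_col <- (sec$col0 + sec$col1 + 1) / 2
  sec
}

#' FD% of one sector
#'
#' 100 times the number of valid FD pixels over the number of valid pixels
#' inside the sector. Errors when the sector has no valid pixel left.
#'
#' @param fdMask logical matrix of (size-filtered) FD pixels.
#' @param valid logical matrix of usable pixels.
#' @param sector one row of \code{\link{cornerSectors}}.
#' @return FD percentage in [0, 100].
#' @export
sectorFDPercent <- function(fdMask, valid, sector) {
  ri <- (sector$row0 + 1L):sector$row1
  ci <- (sector$col0 + 1L):sector$col1
  v <- valid[ri, ci]
  nv <- sum(v)
  if (nv == 0L) stop("sector has no valid pixels; FD% undefined")
  100 * sum(fdMask[ri, ci] & v) / nv
}

#' Quantification options for the imaging pipeline
#'
#' @param compensation apply structural signal compensation (default TRUE).
#' @param smoothingSigmaUm,floor compensation parameters.
#' @param radiusPolicy Phansalkar radius: "15" (literature default) or
#'   "adjusted" (ICD-derived, \code{\link{adjustedRadiusPx}}).
#' @param icdUm mean intercapillary distance (um), driving both the
#'   adjusted radius and the minimum FD size.
#' @param vesselDilationUm dilation of the superficial-vessel exclusion
#'   mask (um).
#' @param phansalkar constants from \code{\link{phansalkarParams}} (the
#'   radius entry is overridden by \code{radiusPolicy}).
#' @return named list of options.
#' @export
quantifyOptions <- function(compensation = TRUE, smoothingSigmaUm = 10,
                            floor = 0.05, radiusPolicy = c("15", "adjusted"),
                            icdUm = 24, vesselDilationUm = 12,
                            phansalkar = phansalkarParams()) {
  radiusPolicy <- match.arg(radiusPolicy)
  list(compensation = compensation, smoothingSigmaUm = smoothingSigmaUm,
       floor = floor, radiusPolicy = radiusPolicy, icdUm = icdUm,
       vesselDilationUm = vesselDilationUm, phansalkar = phansalkar)
}

#' Quantify FD% in the four corner sectors of one eye
#'
#' Runs the full imaging chain: optional compensation, Phansalkar
#' binarization, particle labelling, ICD size filter, corner-sector FD%.
#'
#' @param angio,structural the \linkS4class{EnFaceImage} pair.
#' @param vesselMask \linkS4class{BinaryMask} of superficial-plexus
#'   vessels, or NULL.
#' @param options list from \code{\link{quantifyOptions}}.
#' @return list with \code{sectors} (data.frame: index, orientation,
#'   fd_percent, valid_px), \code{fdMask}, \code{valid}, \code{components},
#'   \code{radiusPx}, \code{minAreaPx}.
#' @export
quantifyEye <- function(angio, structural = NULL, vesselMask = NULL,
                        options = quantifyOptions()) {
  stopifnot(is(angio, "EnFaceImage"))
  img <- angio
  if (options$compensation) {
    if (is.null(structural))
      stop("compensation requested but no structural image given")
    img <- compensateSignal(angio, structural, options$smoothingSigmaUm,
                            options$floor)
  }
  n <- nrow(img@pixels)
  radiusPx <- if (options$radiusPolicy == "adjusted")
    adjustedRadiusPx(options$icdUm, n * img@pitchUm, n) else 15L
  par <- options$phansalkar
  par$radiusPx <- radiusPx
  thr <- phansalkarThreshold(img, par)
  fd <- binarizeFD(img, thr)

  valid <- matrix(TRUE, n, n)
  if (!is.null(vesselMask)) {
    excl <- buildVesselMask(vesselMask, options$vesselDilationUm,
                            img@pitchUm)
    valid <- applyExclusion(fd, excl)$valid
  }
  lab <- labelFDComponents(fd, valid)
  minAreaPx <- minFDAreaPx(options$icdUm, img@pitchUm)
  filt <- filterSmallFD(lab, minAreaPx)
  sec <- cornerSectors(n, img@pitchUm, img@laterality)
  sec$valid_px <- vapply(seq_len(4), function(s) {
    ri <- (sec$row0[s] + 1L):sec$row1[s]
    ci <- (sec$col0[s] + 1L):sec$col1[s]
    sum(valid[ri, ci])
  }, integer(1))
  sec$fd_percent <- vapply(seq_len(4), function(s)
    sectorFDPercent(filt$mask, valid, sec[s, ]), numeric(1))
  list(sectors = sec, fdMask = filt$mask, valid = valid,
       components = filt$components, radiusPx = radiusPx,
       minAreaPx = minAreaPx)
}

#' Build the sector and eye tables of a cohort
#'
#' Applies \code{\link{quantifyEye}} to every scene and attaches the
#' ground-truth annotations (CT at sector centres, LCV and drusen flags).
#' Sectors containing drusen of any size are flagged and excluded from the
#' FD mixed model (but retained for the LCV-visibility models). The
#' eye-level table aggregates LCV presence in at least one sector.
#'
#' @param scenes list of \linkS4class{EyeScene}.
#' @param options list from \code{\link{quantifyOptions}}.
#' @return list with \code{sectors} (one row per eye and sector) and
#'   \code{eyes} (one row per eye: lcv_any, cct_um, eye_color,
#'   spherical_equivalent, group).
#' @export
buildSectorTable <- function(scenes, options = quantifyOptions()) {
  stopifnot(length(scenes) >= 1)
  secList <- vector("list", length(scenes))
  eyeList <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    tr <- sc@truth
    vm <- BinaryMask(tr@vesselMask, "vessel-exclusion")
    q <- quantifyEye(sc@angio, sc@structural, vm, options)
    sec <- q$sectors
    df <- data.frame(eye_id = sc@eyeId, group = sc@group,
                     laterality = sc@laterality, sector = sec$index,
                     orientation = sec$orientation,
                     fd_percent = sec$fd_percent, ct_um = tr@ctUm,
                     lcv = tr@lcvSector, drusen = tr@drusenSector,
                     valid_px = sec$valid_px,
                     true_fd_fraction = tr@fdFraction)
    secList[[i]] <- df
    eyeList[[i]] <- data.frame(eye_id = sc@eyeId, group = sc@group,
                               laterality = sc@laterality,
                               lcv_any = any(tr@lcvSector),
                               cct_um = tr@cctUm,
                               eye_color = sc@metadata$eye_color,
                               spherical_equivalent = sc@metadata$se)
  }
  list(sectors = do.call(rbind, secList), eyes = do.call(rbind, eyeList))
}

#' Rows entering the FD% mixed model
#'
#' Drops sectors flagged for drusen; squares with drusen of any size are
#' excluded from FD% analyses (drusen alter the FD signal locally), while
#' the LCV-visibility models keep them.
#'
#' @param sectorTable sector data.frame from \code{\link{buildSectorTable}}
#'   or \code{\link{simulateSectorData}}.
#' @return the drusen-free subset.
#' @export
fdModelRows <- function(sectorTable) {
  sectorTable[!sectorTable$drusen, , drop = FALSE]
}
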