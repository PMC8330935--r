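## Choroidal thickness measurement and sector annotation.

#' Measure choroidal thickness at a point
#'
#' Axial distance between the inner scleral border and the outer Bruch's
#' membrane border at the given pixel. With \code{tiltCorrection} the axial
#' distance is multiplied by the cosine of the local BM surface inclination
#' (estimated from a least-squares plane over a 5-px-radius neighbourhood),
#' approximating a measurement perpendicular to the surface tangent.
#'
#' @param bmOuterDepth,scleraInnerDepth axial depth maps in micrometres,
#'   aligned to the en-face grid.
#' @param pointPx numeric length-2 (row, col) pixel position.
#' @param pitchUm micrometres per pixel (needed for the tilt estimate).
#' @param tiltCorrection logical, default FALSE.
#' @param label location label ("fovea" or "sector 1".."sector 4").
#' @return list(location, ct_um).
#' @examples
#' bm <- matrix(0, 32, 32); sc <- matrix(150, 32, 32)
#' measureCT(bm, sc, c(16, 16), pitchUm = 10)$ct_um  # 150
#' @export
measureCT <- function(bmOuterDepth, scleraInnerDepth, pointPx,
                      pitchUm = 1, tiltCorrection = FALSE,
                      label = "fovea") {
  i <- round(pointPx[1]); j <- round(pointPx[2])
  n <- nrow(bmOuterDepth); m <- ncol(bmOuterDepth)
  if (i < 1 || i > n || j < 1 || j > m)
    stop("measurement point outside the raster")
  ct <- scleraInnerDepth[i, j] - bmOuterDepth[i, j]
  if (ct <= 0)
    stop("sclera must lie below Bruch's membrane (CT > 0)")
  if (tiltCorrection) {
    ri <- max(1, i - 5):min(n, i + 5)
    ci <- max(1, j - 5):min(m, j + 5)
    g <- expand.grid(r = ri, c = ci)
    d2 <- (g$r - i)^2 + (g$c - j)^2
    g <- g[d2 <= 25, ]
    z <- bmOuterDepth[cbind(g$r, g$c)]
    fit <- stats::lm.fit(cbind(1, g$r * pitchUm, g$c * pitchUm), z)
    slope2 <- sum(fit$coefficients[2:3]^2)
    ct <- ct * cos(atan(sqrt(slope2)))
  }
  list(location = label, ct_um = ct)
}

#' Annotate sectors with CT, LCV and drusen
#'
#' Completes a sector table: CT is taken from the supplied samples, and the
#' binary flags are resolved either from given flags or from masks, where a
#' sector is positive iff at least one mask pixel lies inside it (the
#' "drusen of any size" / any-LCV-pixel rule). The operation is
#' idempotent.
#'
#' @param sectorTable data.frame with columns sector, and the pixel bounds
#'   row0/row1/col0/col1 when masks are used.
#' @param ctSamples numeric length-4 CT (um), indexed by sector.
#' @param lcv either a logical length-4 vector or a logical matrix mask.
#' @param drusen same convention as \code{lcv}.
#' @return the completed sector table (columns ct_um, lcv, drusen).
#' @export
annotateSectors <- function(sectorTable, ctSamples, lcv, drusen) {
  stopifnot(all(sectorTable$sector %in% 1:4))
  sectorTable$ct_um <- ctSamples[sectorTable$sector]
  sectorTable$lcv <- .resolveFlag(sectorTable, lcv)
  sectorTable$drusen <- .resolveFlag(sectorTable, drusen)
  sectorTable
}

.resolveFlag <- function(sectorTable, x) {
  if (is.matrix(x)) {
    vapply(seq_len(nrow(sectorTable)), function(k) {
      ri <- (sectorTable$row0[k] + 1L):sectorTable$row1[k]
      ci <- (sectorTable$col0[k] + 1L):sectorTable$col1[k]
      any(x[ri, ci])
    }, logical(1))
  } else {
    as.logical(x)[sectorTable$sector]
  }
}
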