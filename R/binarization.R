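## Phansalkar auto-local thresholding.
##
## The threshold at each pixel is computed from the mean and population
## standard deviation over a digital-disk window (mirror-padded at the
## borders):
##
##   t = mu * (1 + p * exp(-q * mu) + k * (sigma / r - 1))
##
## with the ImageJ-variant constants k = 0.25, r = 0.5, p = 2, q = 10.
## Pixels with intensity <= t are classified as flow deficit (dark =
## deficit; ties go to deficit, so an all-zero image is all-FD).

#' Phansalkar parameters
#'
#' @param radiusPx window radius in pixels (>= 1).
#' @param k,r,p,q the Phansalkar constants: weight of the normalised
#'   standard deviation, its dynamic-range normaliser, and the exponential
#'   weight/rate boosting thresholds in dark regions.
#' @return A named list of validated parameters.
#' @export
phansalkarParams <- function(radiusPx = 15L, k = 0.25, r = 0.5, p = 2.0,
                             q = 10.0) {
  radiusPx <- as.integer(radiusPx)
  if (radiusPx < 1L) stop("radiusPx must be >= 1")
  if (r <= 0) stop("r must be > 0")
  list(radiusPx = radiusPx, k = k, r = r, p = p, q = q)
}

#' Size-adjusted Phansalkar radius
#'
#' Converts the mean intercapillary distance (ICD) into a window radius in
#' pixels for the given scan geometry: \code{round(icdUm / pitch)} with a
#' floor of 1 pixel. For 6x6 mm scans at 1024 px and the ~24 um ICD this
#' gives the size-adjusted radius of 4 pixels.
#'
#' @param icdUm mean intercapillary distance in micrometres.
#' @param scanSizeUm physical scan side in micrometres.
#' @param imageSizePx image side in pixels.
#' @return integer radius in pixels.
#' @examples
#' adjustedRadiusPx(24, 6000, 1024)  # 4
#' @export
adjustedRadiusPx <- function(icdUm, scanSizeUm, imageSizePx) {
  if (icdUm <= 0 || scanSizeUm <= 0 || imageSizePx <= 0)
    stop("all inputs must be positive")
  max(1L, as.integer(round(icdUm / (scanSizeUm / imageSizePx))))
}

#' Phansalkar threshold map
#'
#' Computes the per-pixel local threshold over a digital disk of the given
#' radius, mirror-padded at the image borders. The window standard
#' deviation uses the population (divide-by-N) estimator.
#'
#' @param image \linkS4class{EnFaceImage} with intensities in [0, 1].
#' @param params list from \code{\link{phansalkarParams}}.
#' @return numeric matrix of thresholds, same shape as the image.
#' @examples
#' img <- EnFaceImage(matrix(0.5, 16, 16))
#' unique(as.vector(phansalkarThreshold(img, phansalkarParams(4))))
#' @export
phansalkarThreshold <- function(image, params = phansalkarParams()) {
  stopifnot(is(image, "EnFaceImage"))
  .phansalkarMap(image@pixels, params$radiusPx, params$k, params$r,
                 params$p, params$q)
}

#' Binarize into flow vs flow-deficit pixels
#'
#' A pixel is a flow deficit iff its intensity is \emph{at most} the local
#' threshold (dark = deficit; the tie goes to deficit).
#'
#' @param image \linkS4class{EnFaceImage}.
#' @param thresholds threshold raster from
#'   \code{\link{phansalkarThreshold}}.
#' @return \linkS4class{BinaryMask} with semantics "fd".
#' @export
binarizeFD <- function(image, thresholds) {
  stopifnot(is(image, "EnFaceImage"))
  if (!identical(dim(image@pixels), dim(thresholds)))
    stop("threshold raster must be aligned to the image")
  new("BinaryMask", pixels = image@pixels <= thresholds, semantics = "fd")
}
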