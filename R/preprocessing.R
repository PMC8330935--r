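## Signal compensation and exclusion masks.
##
## The angiographic slab is divided by a smoothed, max-normalised version of
## its structural counterpart to undo shared attenuation (RPE/BM shadowing,
## drusen). The exact arithmetic of published compensation methods is not
## standardised; the floored-division form used here keeps the operation an
## identity under flat illumination, which is the property the downstream
## FD% invariance checks rely on.

#' Compensate an angiographic slab with its structural counterpart
#'
#' The structural image is Gaussian-smoothed (sigma given in micrometres and
#' converted through the pixel pitch), rescaled to (0, 1] by its maximum,
#' clamped below at \code{floor}, and divided into the angiographic image;
#' the quotient is re-clipped to [0, 1]. Under a flat structural field the
#' operation is an identity for any illumination level, so compensation on
#' and off give identical FD% there.
#'
#' @param angio \linkS4class{EnFaceImage} of kind "angio".
#' @param structural co-registered \linkS4class{EnFaceImage} of kind
#'   "structural" (same grid and pitch).
#' @param smoothingSigmaUm Gaussian sigma in micrometres (default 10,
#'   kept below the narrowest vessel calibre whose attenuation is
#'   corrected);
#'   0 disables smoothing.
#' @param floor lower clamp for the normalised structural signal, in (0, 1)
#'   (default 0.05). Prevents division blow-up in deeply shadowed areas.
#' @return A compensated \linkS4class{EnFaceImage} of kind "angio".
#' @examples
#' a <- EnFaceImage(matrix(0.3, 32, 32))
#' s <- EnFaceImage(matrix(1, 32, 32), kind = "structural")
#' identical(pixels(compensateSignal(a, s)), pixels(a))
#' @export
compensateSignal <- function(angio, structural, smoothingSigmaUm = 10,
                             floor = 0.05) {
  stopifnot(is(angio, "EnFaceImage"), is(structural, "EnFaceImage"))
  if (!identical(dim(angio@pixels), dim(structural@pixels)))
    stop("angio and structural images must share one grid")
  if (angio@pitchUm != structural@pitchUm)
    stop("angio and structural images must share one pitch")
  if (structural@kind != "structural")
    stop("second image must be of kind 'structural'")
  if (floor <= 0 || floor >= 1) stop("floor must lie in (0, 1)")

  s <- structural@pixels
  sigmaPx <- smoothingSigmaUm / angio@pitchUm
  if (sigmaPx > 0)
    s <- .gaussSmooth(s, sigmaPx)
  mx <- max(s)
  if (mx <= 0) stop("structural image carries no signal")
  s <- s / mx
  s[s < floor] <- floor
  out <- angio@pixels / s
  out[out > 1] <- 1
  out[out < 0] <- 0
  new("EnFaceImage", pixels = out, pitchUm = angio@pitchUm,
      laterality = angio@laterality, kind = "angio", slab = angio@slab)
}

## Gaussian smoothing; EBImage's filter radius requires 2*ceil(3*sigma)+1 to
## fit inside the image, so sigma is capped for very small test images.
.gaussSmooth <- function(m, sigmaPx) {
  if (sigmaPx <= 0) return(m)
  maxSigma <- (min(dim(m)) %/% 2 - 1) / 3
  sigmaPx <- min(sigmaPx, maxSigma)
  if (sigmaPx <= 0) return(m)
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigmaPx))
}

#' Dilate a vessel raster into an exclusion mask
#'
#' Morphological dilation by a digital disk (pixel included iff its centre
#' distance is at most the radius); the radius is \code{dilationUm / pitch},
#' rounded to the nearest integer with a floor of 0. Used to widen
#' superficial-plexus projection streaks before excluding them from all FD
#' counts.
#'
#' @param vesselRaster \linkS4class{BinaryMask} of the segmented vessels.
#' @param dilationUm dilation radius in micrometres (>= 0).
#' @param pitchUm micrometres per pixel of the target grid.
#' @return A \linkS4class{BinaryMask} with semantics "vessel-exclusion".
#' @export
buildVesselMask <- function(vesselRaster, dilationUm, pitchUm) {
  stopifnot(is(vesselRaster, "BinaryMask"))
  if (dilationUm < 0) stop("dilation must be >= 0")
  r <- round(dilationUm / pitchUm)
  px <- .dilateDisk(vesselRaster@pixels, r)
  new("BinaryMask", pixels = px, semantics = "vessel-exclusion")
}

## Dilation by the digital disk of integer radius r via offset shifts.
.dilateDisk <- function(mask, r) {
  r <- as.integer(r)
  if (r <= 0L || !any(mask)) return(mask)
  n <- nrow(mask); m <- ncol(mask)
  out <- matrix(FALSE, n, m)
  for (dx in -r:r) for (dy in -r:r) {
    if (dx * dx + dy * dy > r * r) next
    ri <- max(1, 1 - dy):min(n, n - dy)
    ci <- max(1, 1 - dx):min(m, m - dx)
    out[ri, ci] <- out[ri, ci] | mask[ri + dy, ci + dx]
  }
  out
}

#' Flag excluded pixels as invalid
#'
#' Attaches a validity channel to an image or mask: pixels under the
#' exclusion mask are invalid and are never counted as flow deficit nor in
#' any denominator downstream.
#'
#' @param x an \linkS4class{EnFaceImage} or \linkS4class{BinaryMask}.
#' @param exclusion \linkS4class{BinaryMask} of pixels to drop (TRUE =
#'   excluded), aligned to \code{x}.
#' @return A list with elements \code{entity} (\code{x} unchanged) and
#'   \code{valid} (logical matrix, TRUE = usable pixel).
#' @export
applyExclusion <- function(x, exclusion) {
  stopifnot(is(exclusion, "BinaryMask"))
  d <- if (is(x, "EnFaceImage") || is(x, "BinaryMask")) dim(x@pixels)
       else dim(x)
  if (!identical(d, dim(exclusion@pixels)))
    stop("exclusion mask must be aligned to its image")
  list(entity = x, valid = !exclusion@pixels)
}
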