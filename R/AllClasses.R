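#' @import methods
#' @importFrom stats rnorm rbinom runif quantile qnorm pnorm plogis rpois
#'   sd median coef vcov complete.cases
#' @importFrom utils head tail read.csv write.csv
#' @useDynLib ccfdq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## EnFaceImage: one 2-D grayscale en-face OCTA raster.
## ---------------------------------------------------------------------------

#' En-face OCTA image
#'
#' A square grayscale raster holding one en-face slab projection together
#' with its physical pixel pitch, the eye's laterality and the slab it was
#' extracted from. Intensities are stored normalized to [0, 1] (by the
#' source dtype's full range, not per-image maximum, so thresholds are
#' portable across scans).
#'
#' @slot pixels numeric matrix of intensities in [0, 1].
#' @slot pitchUm micrometres per pixel (scan size / width).
#' @slot laterality "OD" or "OS".
#' @slot kind "angio" or "structural".
#' @slot slab list with elements \code{offset_um} (depth below the RPE-fit
#'   reference) and \code{thickness_um}.
#'
#' @exportClass EnFaceImage
setClass("EnFaceImage",
  representation(pixels = "matrix", pitchUm = "numeric",
                 laterality = "character", kind = "character",
                 slab = "list"),
  prototype(pitchUm = 6000 / 1024, laterality = "OD", kind = "angio",
            slab = list(offset_um = 31, thickness_um = 10)))

setValidity("EnFaceImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) != ncol(p)) return("en-face grid must be square")
  if (length(object@pitchUm) != 1L || object@pitchUm <= 0)
    return("pitchUm must be a single positive number")
  if (!object@laterality %in% c("OD", "OS"))
    return("laterality must be 'OD' or 'OS'")
  if (!object@kind %in% c("angio", "structural"))
    return("kind must be 'angio' or 'structural'")
  rng <- range(p)
  if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
    return("intensities must lie within [0, 1]")
  sl <- object@slab
  if (!is.null(sl$thickness_um) && sl$thickness_um <= 0)
    return("slab thickness_um must be > 0")
  if (!is.null(sl$offset_um) && sl$offset_um < 0)
    return("slab offset_um must be >= 0")
  TRUE
})

#' Construct an EnFaceImage
#'
#' @param pixels numeric matrix in [0, 1].
#' @param pitchUm micrometres per pixel.
#' @param laterality "OD" or "OS".
#' @param kind "angio" or "structural".
#' @param slab list(offset_um, thickness_um).
#' @return An \linkS4class{EnFaceImage}.
#' @examples
#' img <- EnFaceImage(matrix(0.5, 64, 64), pitchUm = 6000 / 64)
#' pitchUm(img)
#' @export
EnFaceImage <- function(pixels, pitchUm = 6000 / ncol(pixels),
                        laterality = "OD", kind = "angio",
                        slab = list(offset_um = 31, thickness_um = 10)) {
  new("EnFaceImage", pixels = pixels, pitchUm = pitchUm,
      laterality = laterality, kind = kind, slab = slab)
}

## ---------------------------------------------------------------------------
## BinaryMask
## ---------------------------------------------------------------------------

#' Binary mask aligned to an en-face grid
#'
#' @slot pixels logical matrix.
#' @slot semantics one of "vessel-exclusion", "LCV", "drusen", "sector",
#'   "fd", "valid".
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(pixels = "matrix", semantics = "character"),
  prototype(semantics = "fd"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels)) return("mask pixels must be logical")
  ok <- c("vessel-exclusion", "LCV", "drusen", "sector", "fd", "valid")
  if (!object@semantics %in% ok)
    return(paste("semantics must be one of:", paste(ok, collapse = ", ")))
  TRUE
})

#' Construct a BinaryMask
#' @param pixels logical matrix.
#' @param semantics semantic label of the mask.
#' @return A \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(pixels, semantics = "fd") {
  new("BinaryMask", pixels = pixels, semantics = semantics)
}

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic OCTA cohort generator
#'
#' Holds every generative parameter of the synthetic scene generator. The
#' defaults encode the study conditions the statistical layer is validated
#' against: sector choroidal thickness (CT) distributions with a
#' nasal-temporal gradient, a logistic law for large-choroidal-vessel (LCV)
#' visibility in CT with odds ratio 0.94 per micrometre and a nasal odds
#' shift of 6.23, and group-dependent true flow-deficit fractions
#' (intermediate AMD above control).
#'
#' @slot seed integer RNG seed; identical configs give bit-identical cohorts.
#' @slot nIamd,nControl eyes per group (one eye per patient).
#' @slot imageSizePx image side in pixels (1024 for 6x6 mm device scans).
#' @slot scanSizeUm physical scan side in micrometres.
#' @slot fdFractionIamd,fdFractionControl group-mean true FD fraction of the
#'   pre-LCV flow texture.
#' @slot fdFractionSd between-sector SD of the true FD fraction.
#' @slot lcvIntercept,lcvCtSlope,lcvNasalShift log-odds intercept, slope per
#'   um CT, and nasal shift of the LCV visibility law.
#' @slot lcvReSd SD of the per-eye random intercept of the LCV law.
#' @slot ctSectorMeansUm CT means (um) for the four anatomical corner
#'   positions (supero-temporal, supero-nasal, infero-nasal, infero-temporal).
#' @slot ctSectorSdUm between-eye CT SD (um).
#' @slot cctMeanUm,cctSdUm sub-foveal CT distribution (um).
#' @slot ctMinUm truncation floor for all CT draws (um).
#' @slot noiseSd additive Gaussian intensity noise SD.
#' @slot lcvWidthUmRange LCV tube width range (um).
#' @slot lcvIntensityFactor multiplicative angio signal suppression inside
#'   LCV (<= 0.2: tubes carry at most 20\% of the local flow signal).
#' @slot lcvStructuralFactor multiplicative structural suppression inside
#'   LCV; kept below the angio factor because the lumen's reflectivity
#'   drops more than its decorrelation signal, which is what lets
#'   compensation restore the lumen to flow-level brightness.
#' @slot drusenRate expected drusen per iAMD eye (controls have none).
#' @slot drusenRadiusUmRange drusen blotch radius range (um).
#' @slot renderLcv,renderVessels toggles for LCV tubes and superficial-plexus
#'   projection streaks.
#' @slot textureSigmaUm correlation length of the flow texture (um).
#' @slot flowLevel,fdLevel,structuralBase radiometric levels of bright flow,
#'   deficit pixels and the structural base signal.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(seed = "integer", nIamd = "integer", nControl = "integer",
    imageSizePx = "integer", scanSizeUm = "numeric",
    fdFractionIamd = "numeric", fdFractionControl = "numeric",
    fdFractionSd = "numeric",
    lcvIntercept = "numeric", lcvCtSlope = "numeric",
    lcvNasalShift = "numeric", lcvReSd = "numeric",
    ctSectorMeansUm = "numeric", ctSectorSdUm = "numeric",
    cctMeanUm = "numeric", cctSdUm = "numeric", ctMinUm = "numeric",
    noiseSd = "numeric", lcvWidthUmRange = "numeric",
    lcvIntensityFactor = "numeric", lcvStructuralFactor = "numeric",
    drusenRate = "numeric", drusenRadiusUmRange = "numeric",
    renderLcv = "logical", renderVessels = "logical",
    textureSigmaUm = "numeric", flowLevel = "numeric", fdLevel = "numeric",
    structuralBase = "numeric"))

setValidity("SimulationConfig", function(object) {
  prop <- c(object@fdFractionIamd, object@fdFractionControl)
  if (any(prop < 0 | prop > 1)) return("FD fractions must lie in [0, 1]")
  if (object@fdFractionSd < 0) return("fdFractionSd must be >= 0")
  lens <- c(object@scanSizeUm, object@ctSectorMeansUm, object@ctSectorSdUm,
            object@cctMeanUm, object@cctSdUm, object@ctMinUm,
            object@lcvWidthUmRange, object@drusenRadiusUmRange,
            object@textureSigmaUm)
  if (any(lens <= 0)) return("all physical lengths must be > 0")
  if (object@imageSizePx < 8L) return("imageSizePx too small")
  if (object@nIamd + object@nControl < 2L)
    return("cohort must contain at least 2 eyes")
  if (length(object@ctSectorMeansUm) != 4L)
    return("ctSectorMeansUm must have 4 entries")
  if (length(object@lcvWidthUmRange) != 2L ||
      diff(object@lcvWidthUmRange) < 0)
    return("lcvWidthUmRange must be an increasing pair")
  if (object@lcvIntensityFactor < 0 || object@lcvIntensityFactor > 1)
    return("lcvIntensityFactor must lie in [0, 1]")
  if (object@lcvStructuralFactor < 0 || object@lcvStructuralFactor > 1)
    return("lcvStructuralFactor must lie in [0, 1]")
  if (object@lcvReSd < 0) return("lcvReSd must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@drusenRate < 0) return("drusenRate must be >= 0")
  TRUE
})

#' Construct a SimulationConfig
#'
#' All arguments default to the calibrated study conditions; see
#' \linkS4class{SimulationConfig} for their meaning.
#'
#' @param seed integer seed.
#' @param nIamd,nControl group sizes.
#' @param imageSizePx,scanSizeUm image geometry.
#' @param fdFractionIamd,fdFractionControl,fdFractionSd true FD fractions.
#' @param lcvIntercept,lcvCtSlope,lcvNasalShift,lcvReSd LCV logistic law.
#' @param ctSectorMeansUm,ctSectorSdUm,cctMeanUm,cctSdUm,ctMinUm CT law (um).
#' @param noiseSd intensity noise SD.
#' @param lcvWidthUmRange,lcvIntensityFactor,lcvStructuralFactor LCV tube
#'   geometry and per-channel contrast.
#' @param drusenRate,drusenRadiusUmRange drusen model.
#' @param renderLcv,renderVessels rendering toggles.
#' @param textureSigmaUm,flowLevel,fdLevel,structuralBase radiometry.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- SimulationConfig(seed = 1, nIamd = 2, nControl = 2,
#'                         imageSizePx = 128)
#' @export
SimulationConfig <- function(seed = 1L, nIamd = 69L, nControl = 49L,
    imageSizePx = 1024L, scanSizeUm = 6000,
    fdFractionIamd = 0.09, fdFractionControl = 0.06, fdFractionSd = 0.02,
    lcvIntercept = 5.7, lcvCtSlope = log(0.94),
    lcvNasalShift = log(6.23), lcvReSd = 1.0,
    ctSectorMeansUm = c(194, 148, 121, 157), ctSectorSdUm = 63,
    cctMeanUm = 197, cctSdUm = 82, ctMinUm = 30,
    noiseSd = 0.03, lcvWidthUmRange = c(50, 150),
    lcvIntensityFactor = 0.18, lcvStructuralFactor = 0.14,
    drusenRate = 0.7, drusenRadiusUmRange = c(60, 180),
    renderLcv = TRUE, renderVessels = TRUE,
    textureSigmaUm = 12, flowLevel = 0.65, fdLevel = 0.08,
    structuralBase = 0.85) {
  new("SimulationConfig", seed = as.integer(seed),
      nIamd = as.integer(nIamd), nControl = as.integer(nControl),
      imageSizePx = as.integer(imageSizePx),
      scanSizeUm = as.numeric(scanSizeUm),
      fdFractionIamd = as.numeric(fdFractionIamd),
      fdFractionControl = as.numeric(fdFractionControl),
      fdFractionSd = as.numeric(fdFractionSd),
      lcvIntercept = as.numeric(lcvIntercept),
      lcvCtSlope = as.numeric(lcvCtSlope),
      lcvNasalShift = as.numeric(lcvNasalShift),
      lcvReSd = as.numeric(lcvReSd),
      ctSectorMeansUm = as.numeric(ctSectorMeansUm),
      ctSectorSdUm = as.numeric(ctSectorSdUm),
      cctMeanUm = as.numeric(cctMeanUm), cctSdUm = as.numeric(cctSdUm),
      ctMinUm = as.numeric(ctMinUm), noiseSd = as.numeric(noiseSd),
      lcvWidthUmRange = as.numeric(lcvWidthUmRange),
      lcvIntensityFactor = lcvIntensityFactor,
      lcvStructuralFactor = lcvStructuralFactor,
      drusenRate = drusenRate, drusenRadiusUmRange = drusenRadiusUmRange,
      renderLcv = renderLcv, renderVessels = renderVessels,
      textureSigmaUm = textureSigmaUm, flowLevel = flowLevel,
      fdLevel = fdLevel, structuralBase = structuralBase)
}

## ---------------------------------------------------------------------------
## GroundTruth and EyeScene
## ---------------------------------------------------------------------------

#' Per-eye simulation ground truth
#'
#' @slot fdFraction per-sector true FD fraction (length 4).
#' @slot lcvMask,drusenMask,vesselMask logical rasters on the image grid.
#' @slot bmOuterDepth,scleraInnerDepth axial depth maps (um); their
#'   difference is the CT surface and is positive everywhere.
#' @slot ctUm per-sector CT drawn at the sector centres (um).
#' @slot cctUm sub-foveal CT (um).
#' @slot lcvSector,drusenSector per-sector flags; deterministic given the
#'   masks (a sector is positive iff >= 1 mask pixel lies inside it).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(fdFraction = "numeric", lcvMask = "matrix",
    drusenMask = "matrix", vesselMask = "matrix",
    bmOuterDepth = "matrix", scleraInnerDepth = "matrix",
    ctUm = "numeric", cctUm = "numeric",
    lcvSector = "logical", drusenSector = "logical"))

setValidity("GroundTruth", function(object) {
  if (!all(dim(object@lcvMask) == dim(object@drusenMask)) ||
      !all(dim(object@lcvMask) == dim(object@vesselMask)))
    return("masks must share one grid")
  if (any(object@scleraInnerDepth - object@bmOuterDepth <= 0))
    return("CT surface difference must be > 0 everywhere")
  if (length(object@fdFraction) != 4L || length(object@ctUm) != 4L ||
      length(object@lcvSector) != 4L || length(object@drusenSector) != 4L)
    return("per-sector truth must have 4 entries")
  TRUE
})

#' One synthetic eye: image pair, truth and metadata
#'
#' @slot eyeId character id ("eye001", ...); one eye per synthetic patient,
#'   so patient and eye ids coincide.
#' @slot group "iamd" or "control".
#' @slot laterality "OD" or "OS".
#' @slot angio,structural the co-registered \linkS4class{EnFaceImage} pair.
#' @slot truth a \linkS4class{GroundTruth}.
#' @slot metadata list: spherical equivalent, eye colour, cCT (um).
#' @exportClass EyeScene
setClass("EyeScene",
  representation(eyeId = "character", group = "character",
    laterality = "character", angio = "EnFaceImage",
    structural = "EnFaceImage", truth = "GroundTruth",
    metadata = "list"))

setValidity("EyeScene", function(object) {
  if (!object@group %in% c("iamd", "control"))
    return("group must be 'iamd' or 'control'")
  if (!identical(dim(object@angio@pixels), dim(object@structural@pixels)))
    return("angio and structural must share one grid")
  if (object@angio@pitchUm != object@structural@pitchUm)
    return("angio and structural must share one pitch")
  TRUE
})

## ---------------------------------------------------------------------------
## CutoffResult
## ---------------------------------------------------------------------------

#' Youden-optimal CT cutoff for LCV visibility
#'
#' @slot thresholdUm chosen CT threshold (um); a sector is called
#'   LCV-positive iff CT <= threshold.
#' @slot sensitivity,specificity operating characteristics at the threshold.
#' @slot youdenJ sensitivity + specificity - 1.
#' @slot sensCi,specCi cluster-adjusted 95\% confidence intervals
#'   (ratio-estimator variance over patient clusters).
#' @slot n number of observations used.
#' @exportClass CutoffResult
setClass("CutoffResult",
  representation(thresholdUm = "numeric", sensitivity = "numeric",
    specificity = "numeric", youdenJ = "numeric",
    sensCi = "numeric", specCi = "numeric", n = "integer"))

setValidity("CutoffResult", function(object) {
  j <- object@sensitivity + object@specificity - 1
  if (abs(j - object@youdenJ) > 1e-9) return("J must equal sens + spec - 1")
  if (object@youdenJ < -1 || object@youdenJ > 1)
    return("J must lie in [-1, 1]")
  ci <- c(object@sensCi, object@specCi)
  if (any(ci < 0 | ci > 1, na.rm = TRUE))
    return("CIs must lie within [0, 1]")
  TRUE
})

## ---------------------------------------------------------------------------
## Model result containers
## ---------------------------------------------------------------------------

#' Linear mixed-model result for FD%
#'
#' @slot fixef data.frame of fixed-effect estimates and SEs.
#' @slot ranefVar random-intercept variance (patient).
#' @slot residVar residual variance.
#' @slot contrasts data.frame with the 4 planned comparisons (estimate, SE,
#'   df, raw and Bonferroni-adjusted CI and p, label).
#' @slot model the fitted lmerTest model.
#' @exportClass MixedModelResult
setClass("MixedModelResult",
  representation(fixef = "data.frame", ranefVar = "numeric",
    residVar = "numeric", contrasts = "data.frame", model = "ANY"))

#' Logistic-regression result (possibly mixed)
#'
#' @slot label "univariate", "multivariable" or "eye-level".
#' @slot terms data.frame: term, or (per unit; per um for CT), ci_lo, ci_hi,
#'   p.
#' @slot nObs,nPatients observation and cluster counts.
#' @slot reVar random-intercept variance (NA for eye-level fits).
#' @slot separation TRUE when (quasi-)separation was flagged during fitting.
#' @slot model the fitted model object.
#' @exportClass LogisticResult
setClass("LogisticResult",
  representation(label = "character", terms = "data.frame",
    nObs = "integer", nPatients = "integer", reVar = "numeric",
    separation = "logical", model = "ANY"))
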