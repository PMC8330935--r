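#' Pixel matrix of an image or mask
#' @param x an \linkS4class{EnFaceImage} or \linkS4class{BinaryMask}.
#' @return the underlying matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "EnFaceImage", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' Physical pixel pitch in micrometres
#' @param x an \linkS4class{EnFaceImage}.
#' @return micrometres per pixel.
#' @export
setGeneric("pitchUm", function(x) standardGeneric("pitchUm"))

#' @rdname pitchUm
#' @export
setMethod("pitchUm", "EnFaceImage", function(x) x@pitchUm)

#' Laterality of an image or scene
#' @param x an \linkS4class{EnFaceImage} or \linkS4class{EyeScene}.
#' @return "OD" or "OS".
#' @export
setGeneric("laterality", function(x) standardGeneric("laterality"))

#' @rdname laterality
#' @export
setMethod("laterality", "EnFaceImage", function(x) x@laterality)

#' @rdname laterality
#' @export
setMethod("laterality", "EyeScene", function(x) x@laterality)

#' Image kind ("angio" or "structural")
#' @param x an \linkS4class{EnFaceImage}.
#' @return character kind.
#' @export
setGeneric("imageKind", function(x) standardGeneric("imageKind"))

#' @rdname imageKind
#' @export
setMethod("imageKind", "EnFaceImage", function(x) x@kind)

#' Semantic label of a mask
#' @param x a \linkS4class{BinaryMask}.
#' @return character label.
#' @export
setGeneric("semantics", function(x) standardGeneric("semantics"))

#' @rdname semantics
#' @export
setMethod("semantics", "BinaryMask", function(x) x@semantics)

#' Ground truth of a synthetic scene
#' @param x an \linkS4class{EyeScene}.
#' @return a \linkS4class{GroundTruth}.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "EyeScene", function(x) x@truth)

setMethod("show", "EnFaceImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("EnFaceImage: %dx%d px, %.4g um/px, %s, %s slab %g um @ %g um\n",
              d[1], d[2], object@pitchUm, object@laterality, object@kind,
              object@slab$thickness_um, object@slab$offset_um))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BinaryMask <%s>: %dx%d px, %d positive\n", object@semantics,
              d[1], d[2], sum(object@pixels)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d iAMD + %d control eyes, %d px / %g um\n",
              object@nIamd, object@nControl, object@imageSizePx,
              object@scanSizeUm))
  cat(sprintf("  true FD fraction %.3f (iAMD) / %.3f (control), seed %d\n",
              object@fdFractionIamd, object@fdFractionControl, object@seed))
  cat(sprintf("  LCV law: logit P = %.3g + %.4g*CT + %.3g*nasal (RE sd %.2g)\n",
              object@lcvIntercept, object@lcvCtSlope, object@lcvNasalShift,
              object@lcvReSd))
})

setMethod("show", "EyeScene", function(object) {
  cat(sprintf("EyeScene %s (%s, %s): %dx%d px; LCV sectors %d/4, drusen %d/4\n",
              object@eyeId, object@group, object@laterality,
              nrow(object@angio@pixels), ncol(object@angio@pixels),
              sum(object@truth@lcvSector), sum(object@truth@drusenSector)))
})

setMethod("show", "CutoffResult", function(object) {
  cat(sprintf(
    "Youden CT cutoff: <= %.4g um (J = %.3f)\n  sensitivity %.3f [%.3f; %.3f], specificity %.3f [%.3f; %.3f], n = %d\n",
    object@thresholdUm, object@youdenJ,
    object@sensitivity, object@sensCi[1], object@sensCi[2],
    object@specificity, object@specCi[1], object@specCi[2], object@n))
})

setMethod("show", "MixedModelResult", function(object) {
  cat("Linear mixed model for FD% (random intercept per patient)\n")
  cat(sprintf("  random-intercept var %.3g, residual var %.3g\n",
              object@ranefVar, object@residVar))
  print(object@contrasts[, c("label", "estimate", "ci_lo_adj", "ci_hi_adj",
                             "p_adj")], row.names = FALSE)
})

setMethod("show", "LogisticResult", function(object) {
  cat(sprintf("Logistic model (%s), n = %d obs / %d patients%s\n",
              object@label, object@nObs, object@nPatients,
              if (object@separation) " [separation flagged]" else ""))
  print(object@terms, row.names = FALSE)
})
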