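## Synthetic OCTA scene generator.
##
## Generates seeded synthetic eyes (angio + structural en-face pair, truth
## masks, CT surfaces, metadata) carrying the statistical structure the
## downstream analyses assume: a granular choriocapillaris flow texture
## whose dark fraction equals a configured per-sector true FD fraction, a
## nasal-temporal CT gradient, LCV rendered as smooth dark tubes whose
## per-sector visibility follows a logistic law in CT, drusen attenuation
## blotches, and superficial-plexus projection streaks. Images are
## quantized to the 16-bit grid at creation so the fixture IO layer
## round-trips losslessly.

.SLAB_SPECS <- list("10@31" = list(offset_um = 31, thickness_um = 10),
                    "20@29" = list(offset_um = 29, thickness_um = 20))

## Anatomical order of ctSectorMeansUm is (supero-temporal, supero-nasal,
## infero-nasal, infero-temporal); image sectors are numbered clockwise
## from top-left. For OD (nasal = right half) the two orders coincide; for
## OS they mirror.
.sectorMeanMap <- function(laterality) {
  if (laterality == "OD") 1:4 else c(2L, 1L, 4L, 3L)
}

.truncNorm <- function(n, mean, sd, lower) {
  if (sd <= 0) return(pmax(rep(mean, n), lower))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower)
  }
  x
}

.quantize16 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  round(m * 65535) / 65535
}

## Rasterize a quadratic Bezier tube of the given half-width (px) into a
## logical mask, clipped to the rectangle [r0,r1] x [c0,c1] (1-based).
.bezierTube <- function(mask, p0, p1, p2, halfWidthPx, r0, r1, c0, c1) {
  tt <- seq(0, 1, length.out = max(64L, 4L * (r1 - r0)))
  bx <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
  by <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
  r <- ceiling(halfWidthPx)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= halfWidthPx^2, ]
  ri <- round(rep(bx, each = nrow(off)) + off$dr)
  ci <- round(rep(by, each = nrow(off)) + off$dc)
  ok <- ri >= r0 & ri <= r1 & ci >= c0 & ci <= c1
  mask[cbind(ri[ok], ci[ok])] <- TRUE
  mask
}

## Quadratic CT surface c0 + c1 x + c2 y + c3 xy + c4 (x^2 + y^2) exactly
## interpolating the sub-foveal CT at the centre and the four drawn sector
## CTs at the sector centres.
.ctSurface <- function(n, centres, ctUm, cctUm, ctMinUm) {
  cx <- (n + 1) / 2
  pts <- rbind(c(cx, cx), centres)
  x <- pts[, 1] - cx
  y <- pts[, 2] - cx
  A <- cbind(1, x, y, x * y, x^2 + y^2)
  cf <- solve(A, c(cctUm, ctUm))
  gx <- matrix(seq_len(n) - cx, n, n)
  gy <- matrix(seq_len(n) - cx, n, n, byrow = TRUE)
  ct <- cf[1] + cf[2] * gx + cf[3] * gy + cf[4] * gx * gy +
    cf[5] * (gx^2 + gy^2)
  pmax(ct, ctMinUm)
}

#' Simulate one synthetic eye
#'
#' Draws the eye's structural truth (per-sector CT, LCV visibility from the
#' configured logistic law, drusen, superficial-vessel streaks) and renders
#' the co-registered angio/structural en-face pair. The flow texture is
#' built by smoothing seeded white noise and thresholding at each sector's
#' true-FD quantile, so the pre-LCV dark-pixel fraction matches the drawn
#' true FD fraction exactly (up to pixel-count rounding). Visible LCV are
#' rendered as homogeneous dark tubes carrying at most
#' \code{lcvIntensityFactor} of the local flow signal, identically in both
#' slab settings; they replace (never add to) the underlying texture, which
#' is the mechanism by which they mask flow deficits.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param eyeIndex 1-based index within the cohort; drives the per-eye RNG
#'   stream, so any eye can be regenerated independently.
#' @param group "iamd" or "control".
#' @param laterality "OD" or "OS"; defaults to alternating by index.
#' @param slab "10@31" (10 um slab at 31 um below RPE-fit) or "20@29".
#' @return An \linkS4class{EyeScene}.
#' @examples
#' cfg <- SimulationConfig(seed = 7, nIamd = 1, nControl = 1,
#'                         imageSizePx = 128)
#' simulateEye(cfg, 1, "iamd")
#' @export
simulateEye <- function(config, eyeIndex, group,
                        laterality = c("OD", "OS")[(eyeIndex + 1) %% 2 + 1],
                        slab = c("10@31", "20@29")) {
  stopifnot(is(config, "SimulationConfig"))
  slab <- match.arg(slab)
  if (!group %in% c("iamd", "control"))
    stop("invalid group label: ", group)
  if (eyeIndex < 1 || eyeIndex > config@nIamd + config@nControl)
    stop("eyeIndex outside the configured cohort")
  n <- config@imageSizePx
  pitch <- config@scanSizeUm / n
  sec <- cornerSectors(n, pitch, laterality)
  nasal <- sec$orientation == "nasal"
  centres <- cbind(sec$centre_row, sec$centre_col)

  ## --- structure stream: truth shared by both slab settings ------------
  set.seed((config@seed + 7919L * eyeIndex) %% .Machine$integer.max)
  meanIdx <- .sectorMeanMap(laterality)
  ctUm <- vapply(1:4, function(s)
    .truncNorm(1, config@ctSectorMeansUm[meanIdx[s]], config@ctSectorSdUm,
               config@ctMinUm), numeric(1))
  cctUm <- .truncNorm(1, config@cctMeanUm, config@cctSdUm, config@ctMinUm)
  b <- rnorm(1, 0, config@lcvReSd)
  pLcv <- plogis(config@lcvIntercept + config@lcvCtSlope * ctUm +
                 config@lcvNasalShift * as.numeric(nasal) + b)
  lcvDrawn <- rbinom(4, 1, pLcv) == 1

  fdTarget <- if (group == "iamd") config@fdFractionIamd else
    config@fdFractionControl
  fdFraction <- pmin(pmax(rnorm(4, fdTarget, config@fdFractionSd), 0), 0.5)
  if (fdTarget == 0 && config@fdFractionSd == 0) fdFraction <- rep(0, 4)

  lcvMask <- matrix(FALSE, n, n)
  if (config@renderLcv) {
    nTube <- sample(2:4, 4, replace = TRUE)
    for (s in which(lcvDrawn)) {
      r0 <- sec$row0[s] + 1L; r1 <- sec$row1[s]
      c0 <- sec$col0[s] + 1L; c1 <- sec$col1[s]
      for (k in seq_len(nTube[s])) {
        pts <- cbind(runif(3, r0, r1), runif(3, c0, c1))
        lcvMask <- .bezierTube(lcvMask, pts[1, ], pts[2, ], pts[3, ],
                               runif(1, config@lcvWidthUmRange[1],
                                     config@lcvWidthUmRange[2]) / (2 * pitch),
                               r0, r1, c0, c1)
      }
    }
  }

  drusenMask <- matrix(FALSE, n, n)
  nDrusen <- if (group == "iamd") rpois(1, config@drusenRate) else 0L
  drusenCentres <- NULL
  if (nDrusen > 0) {
    for (k in seq_len(nDrusen)) {
      s <- sample.int(4, 1)
      rad <- runif(1, config@drusenRadiusUmRange[1],
                   config@drusenRadiusUmRange[2]) / pitch
      cen <- c(runif(1, sec$row0[s] + 1 + rad, sec$row1[s] - rad),
               runif(1, sec$col0[s] + 1 + rad, sec$col1[s] - rad))
      drusenCentres <- rbind(drusenCentres, c(cen, rad))
      rr <- max(1, floor(cen[1] - rad)):min(n, ceiling(cen[1] + rad))
      cc <- max(1, floor(cen[2] - rad)):min(n, ceiling(cen[2] + rad))
      dd <- outer((rr - cen[1])^2, (cc - cen[2])^2, "+") <= rad^2
      drusenMask[rr, cc] <- drusenMask[rr, cc] | dd
    }
  }

  vesselMask <- matrix(FALSE, n, n)
  if (config@renderVessels) {
    nv <- sample(3:5, 1)
    vw <- 35 / (2 * pitch)
    for (k in seq_len(nv)) {
      edge <- sample.int(4, 1)
      p0 <- switch(edge, c(1, runif(1, 1, n)), c(runif(1, 1, n), 1),
                   c(n, runif(1, 1, n)), c(runif(1, 1, n), n))
      p2 <- c(n + 1 - p0[1], n + 1 - p0[2]) + runif(2, -n / 4, n / 4)
      p1 <- (p0 + p2) / 2 + runif(2, -n / 6, n / 6)
      vesselMask <- .bezierTube(vesselMask, p0, p1, p2, vw, 1, n, 1, n)
    }
  }

  se <- abs(rnorm(1, 1.6, 1.15))
  eyeColor <- sample(c("brown", "green", "blue"), 1)

  ## --- texture stream: slab-dependent rendering ------------------------
  slabCode <- if (slab == "10@31") 1L else 2L
  set.seed((config@seed + 7919L * eyeIndex + 31L * slabCode) %%
             .Machine$integer.max)
  sigmaPx <- config@textureSigmaUm / pitch * (if (slabCode == 2L) 1.25 else 1)
  z <- .gaussSmooth(matrix(rnorm(n * n), n, n), sigmaPx)

  ## dark (deficit) pixels: per-sector exact quantile thresholding
  dark <- matrix(FALSE, n, n)
  inSector <- matrix(FALSE, n, n)
  for (s in 1:4) {
    ri <- (sec$row0[s] + 1L):sec$row1[s]
    ci <- (sec$col0[s] + 1L):sec$col1[s]
    inSector[ri, ci] <- TRUE
    zs <- z[ri, ci]
    k <- round(fdFraction[s] * length(zs))
    if (k > 0) {
      d <- matrix(FALSE, length(ri), length(ci))
      d[order(zs)[seq_len(k)]] <- TRUE
      dark[ri, ci] <- d
    }
  }
  out <- which(!inSector)
  kOut <- round(fdTarget * length(out))
  if (kOut > 0) dark[out[order(z[out])[seq_len(kOut)]]] <- TRUE

  ## radiometry: granular bright flow, dark deficits. The bright band is
  ## kept above the Phansalkar threshold response (t ~ 0.8*mu for bright
  ## fields), so binarization recovers the drawn deficit fraction and the
  ## contrast carries the perfusion signal.
  u <- pnorm((z - mean(z)) / max(sd(z), 1e-12))
  angio <- config@flowLevel * (1 + 0.3 * u)
  angio[dark] <- config@fdLevel
  structural <- matrix(config@structuralBase, n, n)

  ## LCV replace the texture with a homogeneous dark tube in both images.
  ## The tube profile is feathered over ~15 um (about the lateral optical
  ## resolution) and shared between the channels, so the angio/structural
  ## ratio stays smooth through the vessel edge.
  if (any(lcvMask)) {
    w <- .gaussSmooth(matrix(as.numeric(lcvMask), n, n), 15 / pitch)
    w[w < 0.02] <- 0
    w[w > 1] <- 1
    angio <- angio * (1 - w) + (config@lcvIntensityFactor *
                                  config@flowLevel) * w
    structural <- structural * (1 - w) +
      (config@lcvStructuralFactor * config@structuralBase) * w
    lcvMask <- w > 0
  }

  ## drusen: shared smooth attenuation blotches
  if (!is.null(drusenCentres)) {
    atten <- matrix(1, n, n)
    for (k in seq_len(nrow(drusenCentres))) {
      cen <- drusenCentres[k, 1:2]; rad <- drusenCentres[k, 3]
      rr <- max(1, floor(cen[1] - 2 * rad)):min(n, ceiling(cen[1] + 2 * rad))
      cc <- max(1, floor(cen[2] - 2 * rad)):min(n, ceiling(cen[2] + 2 * rad))
      d2 <- outer((rr - cen[1])^2, (cc - cen[2])^2, "+")
      atten[rr, cc] <- atten[rr, cc] * (1 - 0.45 * exp(-d2 / (2 * (rad / 1.5)^2)))
    }
    angio <- angio * atten
    structural <- structural * atten
  }

  ## superficial-plexus projection streaks: strong in angio, mild in
  ## structural
  if (any(vesselMask)) {
    angio[vesselMask] <- angio[vesselMask] * 0.45
    structural[vesselMask] <- structural[vesselMask] * 0.85
  }

  if (config@noiseSd > 0) {
    angio <- angio + rnorm(n * n, 0, config@noiseSd)
    structural <- structural + rnorm(n * n, 0, config@noiseSd)
  }
  angio <- .quantize16(angio)
  structural <- .quantize16(structural)

  ## CT surfaces (0.1 um grid so fixture IO is lossless)
  ctq <- round(ctUm * 10) / 10
  cctq <- round(cctUm * 10) / 10
  bm <- matrix(300, n, n)
  ctSurf <- round(.ctSurface(n, centres, ctq, cctq, config@ctMinUm) * 10) / 10
  sclera <- bm + ctSurf

  truth <- new("GroundTruth", fdFraction = fdFraction, lcvMask = lcvMask,
               drusenMask = drusenMask, vesselMask = vesselMask,
               bmOuterDepth = bm, scleraInnerDepth = sclera,
               ctUm = ctq, cctUm = cctq,
               lcvSector = vapply(1:4, function(s)
                 any(lcvMask[(sec$row0[s] + 1):sec$row1[s],
                             (sec$col0[s] + 1):sec$col1[s]]), logical(1)),
               drusenSector = vapply(1:4, function(s)
                 any(drusenMask[(sec$row0[s] + 1):sec$row1[s],
                                (sec$col0[s] + 1):sec$col1[s]]), logical(1)))

  slabSpec <- .SLAB_SPECS[[slab]]
  new("EyeScene",
      eyeId = sprintf("eye%03d", eyeIndex), group = group,
      laterality = laterality,
      angio = new("EnFaceImage", pixels = angio, pitchUm = pitch,
                  laterality = laterality, kind = "angio", slab = slabSpec),
      structural = new("EnFaceImage", pixels = structural, pitchUm = pitch,
                       laterality = laterality, kind = "structural",
                       slab = slabSpec),
      truth = truth,
      metadata = list(se = se, eye_color = eyeColor, cct_um = cctq))
}

#' Simulate a synthetic cohort
#'
#' One eye per synthetic patient: the first \code{nIamd} eyes are iAMD, the
#' rest controls; laterality alternates OD/OS. Deterministic under the
#' config seed, and each eye is drawn from its own RNG stream.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param slab slab setting passed to \code{\link{simulateEye}}.
#' @return list of \linkS4class{EyeScene}.
#' @export
simulateCohort <- function(config, slab = "10@31") {
  stopifnot(is(config, "SimulationConfig"))
  nTot <- config@nIamd + config@nControl
  lapply(seq_len(nTot), function(i)
    simulateEye(config, i,
                if (i <= config@nIamd) "iamd" else "control", slab = slab))
}

#' Simulate a sector-level statistical cohort
#'
#' Generates the per-sector measurement table directly from the generative
#' statistical laws, without image rendering: CT from the sector normal
#' laws (with a between-eye component), LCV visibility from the logistic
#' law with a per-eye random intercept, and FD% from a linear mixed model
#' with configurable fixed effects. This is the engine for parameter
#' recovery studies of the statistical layer, where effects must be imposed
#' exactly.
#'
#' @param nIamd,nControl eyes per group.
#' @param seed integer seed.
#' @param ctSectorMeansUm,ctEyeSdUm,ctWithinSdUm,ctMinUm CT law: sector
#'   means (anatomical order), between-eye SD, within-eye SD, floor. The
#'   default 45/44 split reproduces the ~63 um marginal sector SD.
#' @param lcvIntercept,lcvCtSlope,lcvNasalShift,lcvReSd LCV logistic law
#'   (log-odds; slope per um).
#' @param fdIntercept,fdGroupEffect,fdLcvIamd,fdLcvControl,fdNasalEffect
#'   fixed effects of the FD% law (percent): control/temporal/no-LCV mean,
#'   iAMD shift, LCV effect within each group, nasal shift.
#' @param fdReSd,fdResidSd random-intercept and residual SD of FD%.
#' @param drusenSectorProb per-sector drusen probability in iAMD eyes.
#' @param cctMeanUm,cctSdUm sub-foveal CT law; the eye's CT random
#'   component is shared with cCT, giving the within-eye correlation the
#'   eye-level models assume.
#' @return list with \code{sectors} and \code{eyes} data.frames.
#' @examples
#' d <- simulateSectorData(nIamd = 5, nControl = 5, seed = 1)
#' nrow(d$sectors)  # 40
#' @export
simulateSectorData <- function(nIamd = 69, nControl = 49, seed = 1,
    ctSectorMeansUm = c(194, 148, 121, 157), ctEyeSdUm = 45,
    ctWithinSdUm = 44, ctMinUm = 30,
    lcvIntercept = 5.7, lcvCtSlope = log(0.94),
    lcvNasalShift = log(6.23), lcvReSd = 1.0,
    fdIntercept = 6.0, fdGroupEffect = 1.8, fdLcvIamd = -1.3,
    fdLcvControl = 0, fdNasalEffect = -1.16,
    fdReSd = 1.5, fdResidSd = 2.0,
    drusenSectorProb = 0.17, cctMeanUm = 197, cctSdUm = 82) {
  set.seed(seed)
  nEye <- nIamd + nControl
  eyeId <- sprintf("eye%03d", seq_len(nEye))
  group <- c(rep("iamd", nIamd), rep("control", nControl))
  orientation <- c("temporal", "nasal", "nasal", "temporal")

  u <- rnorm(nEye, 0, ctEyeSdUm)          # between-eye CT component
  bLcv <- rnorm(nEye, 0, lcvReSd)
  aFd <- rnorm(nEye, 0, fdReSd)

  rows <- vector("list", nEye)
  for (i in seq_len(nEye)) {
    ct <- pmax(ctSectorMeansUm + u[i] + rnorm(4, 0, ctWithinSdUm), ctMinUm)
    nasal <- orientation == "nasal"
    lcv <- rbinom(4, 1, plogis(lcvIntercept + lcvCtSlope * ct +
                               lcvNasalShift * nasal + bLcv[i])) == 1
    iamd <- group[i] == "iamd"
    fd <- fdIntercept + fdGroupEffect * iamd +
      (if (iamd) fdLcvIamd else fdLcvControl) * lcv +
      fdNasalEffect * nasal + aFd[i] + rnorm(4, 0, fdResidSd)
    drusen <- if (iamd) rbinom(4, 1, drusenSectorProb) == 1 else
      rep(FALSE, 4)
    rows[[i]] <- data.frame(eye_id = eyeId[i], group = group[i],
                            sector = 1:4, orientation = orientation,
                            fd_percent = pmin(pmax(fd, 0), 100),
                            ct_um = ct, lcv = lcv, drusen = drusen)
  }
  sectors <- do.call(rbind, rows)
  cct <- pmax(cctMeanUm + u + rnorm(nEye, 0, 30), ctMinUm)
  eyes <- data.frame(eye_id = eyeId, group = group,
                     lcv_any = tapply(sectors$lcv, sectors$eye_id,
                                      any)[eyeId],
                     cct_um = cct,
                     eye_color = sample(c("brown", "green", "blue"), nEye,
                                        replace = TRUE),
                     spherical_equivalent = abs(rnorm(nEye, 1.6, 1.15)))
  rownames(eyes) <- NULL
  list(sectors = sectors, eyes = eyes)
}
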