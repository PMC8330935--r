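## Statistical layer: mixed FD% model with four planned comparisons,
## mixed logistic models of LCV visibility, eye-level logistic models,
## Youden-index CT cutoff with cluster-adjusted CIs.

#' Bonferroni adjustment
#'
#' \code{min(1, m * p)} elementwise. Used to adjust the four planned group
#' comparisons of the FD% mixed model within each analysis setting.
#'
#' @param p numeric p values in [0, 1].
#' @param m number of comparisons (>= 1).
#' @return adjusted p values.
#' @examples
#' bonferroniAdjust(0.000725, 4)  # 0.0029
#' @export
bonferroniAdjust <- function(p, m) {
  if (m < 1) stop("m must be >= 1")
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Cluster-adjusted ratio-estimator confidence interval
#'
#' Wald interval for a proportion from cluster totals, with the ratio
#' estimator variance accounting for within-cluster correlation:
#' \deqn{\hat p = \sum x_i / \sum n_i,\quad
#'   \widehat{var} = \frac{m}{(m-1)(\sum n_i)^2} \sum (x_i - \hat p n_i)^2}
#' with m the number of clusters with at least one trial. The interval is
#' clipped to [0, 1]. As the within-cluster correlation vanishes it
#' approaches the ordinary binomial Wald interval.
#'
#' @param successes,trials integer vectors per cluster.
#' @param level confidence level (default 0.95).
#' @return list(estimate, var, lower, upper, m).
#' @examples
#' clusterRatioCI(c(2, 1, 0, 1), c(2, 2, 2, 2))
#' @export
clusterRatioCI <- function(successes, trials, level = 0.95) {
  stopifnot(length(successes) == length(trials))
  keep <- trials > 0
  x <- successes[keep]; n <- trials[keep]
  m <- length(n)
  if (m < 2) stop("need >= 2 clusters with trials > 0")
  if (sum(n) == 0) stop("no trials")
  if (any(x < 0) || any(x > n)) stop("successes must lie in [0, trials]")
  p <- sum(x) / sum(n)
  v <- m / ((m - 1) * sum(n)^2) * sum((x - p * n)^2)
  z <- qnorm(1 - (1 - level) / 2)
  list(estimate = p, var = v,
       lower = max(0, p - z * sqrt(v)), upper = min(1, p + z * sqrt(v)),
       m = m)
}

#' Linear mixed model for FD%
#'
#' Fits \code{fd_percent ~ lcv * group + orientation + (1 | eye_id)} by
#' REML (the final model after dropping the non-significant
#' LCV-by-orientation and orientation-by-group interactions) and derives
#' the four planned comparisons: the LCV effect within each group and the
#' group effect within each LCV level, each with a Bonferroni adjustment
#' for the four comparisons (adjusted p = min(1, 4p); CIs widened to the
#' 1 - 0.05/4 level).
#'
#' @param fdRows sector data.frame without drusen sectors (see
#'   \code{\link{fdModelRows}}); needs columns fd_percent, lcv, group,
#'   orientation, eye_id.
#' @return A \linkS4class{MixedModelResult}.
#' @export
fitFDMixedModel <- function(fdRows) {
  need <- c("fd_percent", "lcv", "group", "orientation", "eye_id")
  if (!all(need %in% names(fdRows)))
    stop("missing columns: ", paste(setdiff(need, names(fdRows)),
                                    collapse = ", "))
  if (any(isTRUE(fdRows$drusen)) || (is.logical(fdRows$drusen) &&
                                     any(fdRows$drusen)))
    stop("drusen sectors must be removed before the FD model ",
         "(use fdModelRows)")
  d <- data.frame(
    fd_percent = fdRows$fd_percent,
    lcv = factor(ifelse(as.logical(fdRows$lcv), "present", "absent"),
                 levels = c("absent", "present")),
    group = factor(fdRows$group, levels = c("control", "iamd")),
    orientation = factor(fdRows$orientation,
                         levels = c("temporal", "nasal")),
    eye_id = factor(fdRows$eye_id))
  byGroup <- table(d$group[!duplicated(d$eye_id)])
  if (any(byGroup < 2)) stop("need >= 2 eyes per group")

  fit <- lmerTest::lmer(fd_percent ~ lcv * group + orientation +
                          (1 | eye_id), data = d, REML = TRUE)
  emLcv <- emmeans::emmeans(fit, ~ lcv | group)
  cLcv <- emmeans::contrast(emLcv, "revpairwise")
  emGrp <- emmeans::emmeans(fit, ~ group | lcv)
  cGrp <- emmeans::contrast(emGrp, "revpairwise")

  lv <- 1 - 0.05 / 4
  sRaw <- rbind(as.data.frame(summary(cLcv, infer = TRUE, level = 0.95)),
                as.data.frame(summary(cGrp, infer = TRUE, level = 0.95)))
  sAdj <- rbind(as.data.frame(summary(cLcv, infer = TRUE, level = lv)),
                as.data.frame(summary(cGrp, infer = TRUE, level = lv)))
  lab <- c(paste("LCV present - absent |", sRaw$group[1:2]),
           paste("iAMD - control | LCV", sRaw$lcv[3:4]))
  contrasts <- data.frame(
    label = lab, estimate = sRaw$estimate, se = sRaw$SE, df = sRaw$df,
    ci_lo = sRaw$lower.CL, ci_hi = sRaw$upper.CL, p = sRaw$p.value,
    ci_lo_adj = sAdj$lower.CL, ci_hi_adj = sAdj$upper.CL,
    p_adj = bonferroniAdjust(sRaw$p.value, 4))

  vc <- as.data.frame(lme4::VarCorr(fit))
  new("MixedModelResult",
      fixef = as.data.frame(coef(summary(fit))),
      ranefVar = vc$vcov[vc$grp == "eye_id"],
      residVar = vc$vcov[vc$grp == "Residual"],
      contrasts = contrasts, model = fit)
}

.glmmTerms <- function(fit) {
  s <- coef(summary(fit))
  est <- s[, "Estimate"]; se <- s[, "Std. Error"]; p <- s[, 4]
  data.frame(term = rownames(s), or = exp(est), se = se,
             ci_lo = exp(est - qnorm(0.975) * se),
             ci_hi = exp(est + qnorm(0.975) * se), p = p)
}

.fitOneGlmm <- function(formula, d, label) {
  sep <- FALSE
  fit <- withCallingHandlers(
    lme4::glmer(formula, data = d, family = stats::binomial),
    warning = function(w) {
      if (grepl("failed to converge|nearly unidentifiable|singular",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  terms <- .glmmTerms(fit)
  if (any(terms$se > 50) || any(!is.finite(terms$or))) sep <- TRUE
  vc <- as.data.frame(lme4::VarCorr(fit))
  new("LogisticResult", label = label,
      terms = terms[terms$term != "(Intercept)", ],
      nObs = nrow(d), nPatients = nlevels(d$eye_id),
      reVar = vc$vcov[1], separation = sep, model = fit)
}

#' Mixed logistic models of LCV visibility
#'
#' Sector-level logistic regression of the LCV flag with a random
#' intercept per patient. In univariate mode one model per requested
#' predictor (group, ct, orientation) is fitted. In multivariable mode the
#' predictors whose univariate p is below 0.05 are combined, plus the
#' CT-by-orientation interaction when both enter; with the interaction the
#' CT odds ratio is additionally reported within each orientation.
#' Sectors containing drusen are \emph{not} excluded from these analyses.
#' CT is mean-centred internally; its odds ratios are per micrometre.
#'
#' @param rows sector data.frame (columns lcv, eye_id and the predictors).
#' @param predictors subset of c("ct", "group", "orientation").
#' @param mode "univariate" or "multivariable".
#' @return univariate mode: named list of \linkS4class{LogisticResult};
#'   multivariable mode: one \linkS4class{LogisticResult}.
#' @export
fitLCVGlmm <- function(rows, predictors = c("ct", "group", "orientation"),
                       mode = c("univariate", "multivariable")) {
  mode <- match.arg(mode)
  predictors <- match.arg(predictors, c("ct", "group", "orientation"),
                          several.ok = TRUE)
  lcv <- as.logical(rows$lcv)
  if (length(unique(lcv)) < 2)
    stop("single-class outcome: LCV flag does not vary")
  d <- data.frame(
    lcv = lcv,
    ct = rows$ct_um - mean(rows$ct_um),
    group = factor(rows$group, levels = c("control", "iamd")),
    orientation = factor(rows$orientation,
                         levels = c("temporal", "nasal")),
    eye_id = factor(rows$eye_id))

  uni <- lapply(predictors, function(pr)
    .fitOneGlmm(stats::as.formula(paste("lcv ~", pr, "+ (1 | eye_id)")),
                d, "univariate"))
  names(uni) <- predictors
  if (mode == "univariate") return(uni)

  keep <- predictors[vapply(uni, function(r) min(r@terms$p) < 0.05,
                            logical(1))]
  if (length(keep) == 0)
    stop("no predictor reached univariate p < 0.05")
  rhs <- paste(keep, collapse = " + ")
  withInt <- all(c("ct", "orientation") %in% keep)
  if (withInt) rhs <- paste(rhs, "+ ct:orientation")
  res <- .fitOneGlmm(stats::as.formula(
    paste("lcv ~", rhs, "+ (1 | eye_id)")), d, "multivariable")
  if (withInt) {
    ## CT odds ratio within each orientation
    b <- lme4::fixef(res@model)
    V <- as.matrix(vcov(res@model))
    iCt <- which(names(b) == "ct")
    iInt <- grep("ct:orientation", names(b))
    estT <- b[iCt]; seT <- sqrt(V[iCt, iCt])
    estN <- b[iCt] + b[iInt]
    seN <- sqrt(V[iCt, iCt] + V[iInt, iInt] + 2 * V[iCt, iInt])
    z <- qnorm(0.975)
    extra <- data.frame(
      term = c("ct | temporal", "ct | nasal"),
      or = exp(c(estT, estN)), se = c(seT, seN),
      ci_lo = exp(c(estT - z * seT, estN - z * seN)),
      ci_hi = exp(c(estT + z * seT, estN + z * seN)),
      p = 2 * pnorm(-abs(c(estT / seT, estN / seN))))
    res@terms <- rbind(res@terms, extra)
  }
  res
}

#' Eye-level logistic model of LCV presence
#'
#' Ordinary logistic regression (one row per eye, no random effect) of
#' "LCV present in at least one sector" on a single predictor: sub-foveal
#' choroidal thickness (OR per um), eye colour (overall likelihood-ratio
#' p, per-level ORs against brown), or spherical equivalent.
#'
#' @param eyes eye-level data.frame (columns lcv_any and the predictor).
#' @param predictor one of "cct_um", "eye_color", "spherical_equivalent".
#' @return A \linkS4class{LogisticResult}.
#' @export
fitEyeLevelLogistic <- function(eyes,
    predictor = c("cct_um", "eye_color", "spherical_equivalent")) {
  predictor <- match.arg(predictor)
  y <- as.logical(eyes$lcv_any)
  if (length(unique(y)) < 2)
    stop("single-class outcome: lcv_any does not vary")
  d <- data.frame(y = y, x = eyes[[predictor]])
  d <- d[complete.cases(d), ]
  if (is.character(d$x)) d$x <- factor(d$x)
  fit <- stats::glm(y ~ x, data = d, family = stats::binomial)
  s <- coef(summary(fit))
  z <- qnorm(0.975)
  terms <- data.frame(term = rownames(s)[-1], or = exp(s[-1, 1]),
                      se = s[-1, 2],
                      ci_lo = exp(s[-1, 1] - z * s[-1, 2]),
                      ci_hi = exp(s[-1, 1] + z * s[-1, 2]),
                      p = s[-1, 4])
  if (is.factor(d$x)) {
    lrt <- stats::anova(fit, test = "Chisq")
    terms <- rbind(terms, data.frame(term = paste(predictor, "(overall)"),
                                     or = NA, se = NA, ci_lo = NA,
                                     ci_hi = NA, p = lrt$`Pr(>Chi)`[2]))
  }
  new("LogisticResult", label = "eye-level", terms = terms,
      nObs = nrow(d), nPatients = nrow(d), reVar = NA_real_,
      separation = FALSE, model = fit)
}

#' Youden-index CT cutoff for LCV visibility
#'
#' Scans the midpoints between adjacent distinct sorted CT values as
#' candidate thresholds; a sector is called LCV-positive iff its CT is at
#' most the threshold. The threshold maximising J = sensitivity +
#' specificity - 1 is chosen (ties broken toward the smallest threshold).
#' Sensitivity and specificity CIs account for the repeated sectors per
#' patient through the cluster ratio estimator
#' (\code{\link{clusterRatioCI}}).
#'
#' @param ctValues numeric CT per sector (um).
#' @param lcvLabels logical/0-1 LCV flags.
#' @param clusterIds patient/eye id per sector.
#' @return A \linkS4class{CutoffResult}.
#' @examples
#' youdenCutoff(c(100, 110, 130, 140), c(1, 1, 0, 0), c(1, 1, 2, 2))
#' @export
youdenCutoff <- function(ctValues, lcvLabels, clusterIds) {
  lcv <- as.logical(lcvLabels)
  stopifnot(length(ctValues) == length(lcv),
            length(clusterIds) == length(lcv))
  if (length(unique(lcv)) < 2)
    stop("both classes must be present")
  ctS <- sort(unique(ctValues))
  if (length(ctS) < 2) stop("need >= 2 distinct CT values")
  cand <- (head(ctS, -1) + tail(ctS, -1)) / 2
  sens <- vapply(cand, function(t) mean(ctValues[lcv] <= t), numeric(1))
  spec <- vapply(cand, function(t) mean(ctValues[!lcv] > t), numeric(1))
  J <- sens + spec - 1
  i <- which.max(J)  # candidates ascend, so the first max is the smallest
  thr <- cand[i]

  pos <- ctValues <= thr
  ci <- function(hit, cls) {
    x <- tapply(hit, cls, sum)
    n <- tapply(hit, cls, length)
    if (length(x) < 2) return(c(NA_real_, NA_real_))  # CI undefined
    r <- clusterRatioCI(x, n)
    c(r$lower, r$upper)
  }
  new("CutoffResult", thresholdUm = thr, sensitivity = sens[i],
      specificity = spec[i], youdenJ = J[i],
      sensCi = ci(pos[lcv], clusterIds[lcv]),
      specCi = ci(!pos[!lcv], clusterIds[!lcv]),
      n = length(ctValues))
}
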