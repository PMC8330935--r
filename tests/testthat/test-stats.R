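test_that("cluster ratio CI reproduces the closed form", {
  ci <- clusterRatioCI(c(2, 1, 0, 1), c(2, 2, 2, 2))
  expect_equal(ci$estimate, 0.5)
  expect_equal(ci$var, 0.0416667, tolerance = 1e-5)
  expect_equal(ci$lower, 0.100, tolerance = 1e-3)
  expect_equal(ci$upper, 0.900, tolerance = 1e-3)
  # identical cluster proportions -> degenerate interval at p-hat
  d <- clusterRatioCI(c(1, 1, 1), c(2, 2, 2))
  expect_equal(d$var, 0)
  expect_equal(c(d$lower, d$upper), c(0.5, 0.5))
  expect_error(clusterRatioCI(1, 2), "clusters")
})

test_that("Bernoulli clusters match the brute-force ratio formula", {
  set.seed(17)
  x <- rbinom(20, 1, 0.4)
  ci <- clusterRatioCI(x, rep(1L, 20))
  p <- mean(x)
  v <- 20 / (19 * 400) * sum((x - p)^2)
  expect_equal(ci$var, v)
  expect_equal(ci$lower, max(0, p - qnorm(0.975) * sqrt(v)))
})

test_that("ratio CI approaches the binomial Wald interval without clustering", {
  set.seed(19)
  m <- 200; n <- rep(4L, m)
  x <- rbinom(m, 4, 0.3)  # independent within clusters
  ci <- clusterRatioCI(x, n)
  p <- sum(x) / sum(n)
  wald <- sqrt(p * (1 - p) / sum(n))
  expect_equal(sqrt(ci$var) / wald, 1, tolerance = 0.1)
})

test_that("Bonferroni adjustment caps at one", {
  expect_equal(bonferroniAdjust(0.01, 4), 0.04)
  expect_equal(bonferroniAdjust(0.5, 4), 1.0)
  expect_equal(bonferroniAdjust(0.000725, 4), 0.0029)
  expect_error(bonferroniAdjust(1.2, 4), "\\[0, 1\\]")
})

test_that("Youden cutoff solves the separable case exactly", {
  cut <- youdenCutoff(c(100, 110, 130, 140), c(1, 1, 0, 0),
                      c("a", "a", "b", "b"))
  expect_equal(cut@thresholdUm, 120)
  expect_equal(cut@sensitivity, 1)
  expect_equal(cut@specificity, 1)
  expect_equal(cut@youdenJ, 1)
})

test_that("Youden scan equals brute-force candidate evaluation", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    ct <- round(runif(n, 50, 300))
    lcv <- rbinom(n, 1, plogis(2 - 0.02 * ct)) == 1
    if (length(unique(lcv)) < 2 || length(unique(ct)) < 2) next
    cl <- sample(5, n, replace = TRUE)
    got <- youdenCutoff(ct, lcv, cl)
    ref <- bruteForceYouden(ct, lcv)
    expect_equal(got@thresholdUm, ref$threshold)
    expect_equal(got@youdenJ, ref$J)
  }
})

test_that("Youden on permuted labels gives near-zero J", {
  set.seed(29)
  d <- simulateSectorData(nIamd = 69, nControl = 49, seed = 31)
  s <- d$sectors
  J <- replicate(60, {
    perm <- sample(s$lcv)
    youdenCutoff(s$ct_um, perm, s$eye_id)@youdenJ
  })
  expect_lt(median(J), 0.15)
})

test_that("degenerate cutoff inputs error", {
  expect_error(youdenCutoff(c(1, 2, 3), c(1, 1, 1), 1:3), "classes")
  expect_error(youdenCutoff(c(5, 5, 5, 5), c(1, 1, 0, 0), 1:4),
               "distinct")
})

test_that("FD mixed model recovers planned contrasts and adjusts them", {
  d <- simulateSectorData(nIamd = 60, nControl = 60, seed = 41,
                          fdLcvIamd = -3, fdLcvControl = 0,
                          drusenSectorProb = 0)
  res <- fitFDMixedModel(fdModelRows(d$sectors))
  expect_identical(nrow(res@contrasts), 4L)
  expect_true(all(res@contrasts$p_adj >= res@contrasts$p))
  expect_true(all(res@contrasts$ci_lo_adj <= res@contrasts$ci_lo + 1e-12))
  iamdLcv <- res@contrasts[res@contrasts$label ==
                             "LCV present - absent | iamd", ]
  expect_lt(abs(iamdLcv$estimate - (-3)), 1.2)
  expect_lt(iamdLcv$p_adj, 0.05)
  withDrusen <- d$sectors
  withDrusen$drusen[1] <- TRUE
  expect_error(fitFDMixedModel(withDrusen), "drusen")
})

test_that("sector GLMM recovers the nasal odds shift in isolation", {
  set.seed(43)
  ors <- replicate(15, {
    d <- simulateSectorData(nIamd = 69, nControl = 49,
                            seed = sample.int(1e6, 1),
                            lcvCtSlope = 0, lcvIntercept = -2,
                            lcvNasalShift = log(6.23))
    fitLCVGlmm(d$sectors, "orientation")$orientation@terms$or[1]
  })
  gm <- exp(mean(log(ors)))
  expect_gt(gm, 6.23 * 0.75)
  expect_lt(gm, 6.23 * 1.25)
})

test_that("multivariable GLMM adds the CT-orientation interaction", {
  d <- simulateSectorData(nIamd = 69, nControl = 49, seed = 47)
  multi <- fitLCVGlmm(d$sectors, c("ct", "orientation"),
                      mode = "multivariable")
  expect_true(any(grepl("ct:orientation", multi@terms$term)))
  expect_true(all(c("ct | temporal", "ct | nasal") %in% multi@terms$term))
  expect_true(all(multi@terms$or > 0))
  expect_identical(multi@nObs, 472L)
})

test_that("GLMM rejects single-class outcomes", {
  d <- simulateSectorData(nIamd = 10, nControl = 10, seed = 53)
  d$sectors$lcv <- TRUE
  expect_error(fitLCVGlmm(d$sectors, "ct"), "single-class")
})

test_that("eye-level logistic recovers a cCT effect and validates input", {
  set.seed(59)
  ors <- replicate(30, {
    n <- 118
    cct <- rnorm(n, 205, 80)
    y <- rbinom(n, 1, plogis(3.72 + log(0.982) * cct)) == 1
    if (length(unique(y)) < 2) return(NA)
    eyes <- data.frame(lcv_any = y, cct_um = cct)
    fitEyeLevelLogistic(eyes, "cct_um")@terms$or[1]
  })
  gm <- exp(mean(log(ors), na.rm = TRUE))
  expect_gt(gm, 0.976)
  expect_lt(gm, 0.989)
  eyesBad <- data.frame(lcv_any = rep(TRUE, 20), cct_um = rnorm(20, 200))
  expect_error(fitEyeLevelLogistic(eyesBad, "cct_um"), "single-class")
})

test_that("eye-level logistic handles categorical eye colour", {
  d <- simulateSectorData(nIamd = 40, nControl = 40, seed = 61)
  res <- fitEyeLevelLogistic(d$eyes, "eye_color")
  expect_true(any(grepl("overall", res@terms$term)))
})
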