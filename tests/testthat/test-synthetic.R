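test_that("identical configs give bit-identical scenes", {
  cfg <- smallConfig(seed = 7)
  a <- simulateEye(cfg, 1, "iamd")
  b <- simulateEye(cfg, 1, "iamd")
  expect_identical(pixels(a@angio), pixels(b@angio))
  expect_identical(pixels(a@structural), pixels(b@structural))
  expect_identical(a@truth@lcvMask, b@truth@lcvMask)
  expect_identical(a@truth@ctUm, b@truth@ctUm)
})

test_that("different seeds give different cohorts", {
  a <- simulateEye(smallConfig(seed = 1), 1, "iamd")
  b <- simulateEye(smallConfig(seed = 2), 1, "iamd")
  expect_false(identical(pixels(a@angio), pixels(b@angio)))
})

test_that("the degenerate no-deficit scene has no dark pixels", {
  cfg <- smallConfig(seed = 3, fdFractionControl = 0, fdFractionSd = 0,
                     noiseSd = 0, renderLcv = FALSE,
                     renderVessels = FALSE)
  sc <- simulateEye(cfg, 3, "control")
  expect_identical(sc@truth@fdFraction, rep(0, 4))
  # all pixels carry flow signal well above the deficit level
  expect_gt(min(pixels(sc@angio)), cfg@fdLevel + 0.05)
})

test_that("the dark-pixel fraction matches the drawn true FD fraction", {
  cfg <- smallConfig(seed = 5, fdFractionIamd = 0.12, fdFractionSd = 0.03,
                     noiseSd = 0, renderLcv = FALSE,
                     renderVessels = FALSE, drusenRate = 1e-9)
  sc <- simulateEye(cfg, 1, "iamd")
  sec <- cornerSectors(cfg@imageSizePx, cfg@scanSizeUm / cfg@imageSizePx,
                       laterality(sc))
  for (s in 1:4) {
    px <- pixels(sc@angio)[(sec$row0[s] + 1):sec$row1[s],
                           (sec$col0[s] + 1):sec$col1[s]]
    darkFrac <- mean(px <= cfg@fdLevel + 1 / 65535)  # 16-bit grid
    expect_lt(abs(darkFrac - sc@truth@fdFraction[s]), 0.01)
  }
})

test_that("cohorts have the configured size and laterality alternates", {
  cfg <- smallConfig(seed = 11, nIamd = 1, nControl = 1)
  scenes <- simulateCohort(cfg)
  expect_length(scenes, 2L)
  expect_identical(vapply(scenes, laterality, ""), c("OD", "OS"))
  expect_identical(vapply(scenes, function(s) s@group, ""),
                   c("iamd", "control"))
  d <- simulateSectorData(nIamd = 1, nControl = 1, seed = 1)
  expect_identical(nrow(d$sectors), 8L)
})

test_that("invalid group labels are rejected", {
  expect_error(simulateEye(smallConfig(), 1, "amd"), "group")
  expect_error(simulateEye(smallConfig(), 9, "iamd"), "cohort")
})

test_that("LCV masks are identical across slab settings", {
  cfg <- smallConfig(seed = 13, lcvIntercept = 20)  # LCV near-certain
  a <- simulateEye(cfg, 1, "iamd", slab = "10@31")
  b <- simulateEye(cfg, 1, "iamd", slab = "20@29")
  expect_true(any(a@truth@lcvMask))
  expect_identical(a@truth@lcvMask, b@truth@lcvMask)
  expect_identical(a@truth@lcvSector, b@truth@lcvSector)
  expect_false(identical(pixels(a@angio), pixels(b@angio)))
})

test_that("sector flags are deterministic given the masks", {
  cfg <- smallConfig(seed = 17, lcvIntercept = 2)
  sc <- simulateEye(cfg, 1, "iamd")
  sec <- cornerSectors(cfg@imageSizePx, cfg@scanSizeUm / cfg@imageSizePx,
                       laterality(sc))
  flags <- vapply(1:4, function(s)
    any(sc@truth@lcvMask[(sec$row0[s] + 1):sec$row1[s],
                         (sec$col0[s] + 1):sec$col1[s]]), logical(1))
  expect_identical(flags, sc@truth@lcvSector)
})

test_that("LCV replace signal: texture outside tubes is unchanged", {
  cfgL <- smallConfig(seed = 19, fdFractionIamd = 0.15, lcvIntercept = 20,
                      drusenRate = 1e-9, renderVessels = FALSE)
  cfgN <- cfgL; cfgN@renderLcv <- FALSE
  validObject(cfgN)
  a <- simulateEye(cfgL, 1, "iamd")
  b <- simulateEye(cfgN, 1, "iamd")
  out <- !a@truth@lcvMask
  expect_identical(pixels(a@angio)[out], pixels(b@angio)[out])
})

test_that("simulated LCV frequency follows the configured logistic law", {
  # alpha for P = 0.26 at CT 150 with no nasal shift or clustering
  alpha <- qlogis(0.26) - log(0.94) * 150
  d <- simulateSectorData(nIamd = 100, nControl = 100, seed = 23,
                          ctSectorMeansUm = rep(150, 4), ctEyeSdUm = 1e-6,
                          ctWithinSdUm = 1e-6, lcvIntercept = alpha,
                          lcvNasalShift = 0, lcvReSd = 1e-6)
  freq <- mean(d$sectors$lcv)
  se <- sqrt(0.26 * 0.74 / nrow(d$sectors))
  expect_lt(abs(freq - 0.26), 3 * se)
})

test_that("the generator's logistic law is recovered by regression", {
  d <- simulateSectorData(nIamd = 150, nControl = 150, seed = 29,
                          lcvReSd = 1e-6)
  fit <- glm(lcv ~ ct_um + I(orientation == "nasal"),
             data = d$sectors, family = binomial)
  s <- coef(summary(fit))
  expect_lt(abs(s["ct_um", 1] - log(0.94)), 3 * s["ct_um", 2])
})

test_that("CT truth is internally consistent", {
  cfg <- smallConfig(seed = 31)
  sc <- simulateEye(cfg, 2, "control")
  tr <- sc@truth
  expect_true(all(tr@scleraInnerDepth > tr@bmOuterDepth))
  sec <- cornerSectors(cfg@imageSizePx, cfg@scanSizeUm / cfg@imageSizePx,
                       laterality(sc))
  for (s in 1:4) {
    ct <- measureCT(tr@bmOuterDepth, tr@scleraInnerDepth,
                    c(sec$centre_row[s], sec$centre_col[s]))$ct_um
    expect_lt(abs(ct - tr@ctUm[s]), 1)
  }
})
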