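test_that("compensation is an identity under flat structural fields", {
  set.seed(9)
  a <- EnFaceImage(matrix(runif(32 * 32), 32, 32))
  for (level in c(0.3, 0.5, 1)) {
    s <- EnFaceImage(matrix(level, 32, 32), kind = "structural")
    out <- compensateSignal(a, s)
    expect_equal(pixels(out), pixels(a), tolerance = 1e-12)
  }
})

test_that("compensation divides by the normalised structural field", {
  # checkerboard structural {0.25, 1}, flat angio 0.2, no smoothing
  chk <- matrix(0.25, 8, 8)
  chk[(row(chk) + col(chk)) %% 2 == 0] <- 1
  a <- EnFaceImage(matrix(0.2, 8, 8))
  s <- EnFaceImage(chk, kind = "structural")
  out <- pixels(compensateSignal(a, s, smoothingSigmaUm = 0))
  expect_setequal(round(unique(as.vector(out)), 10), c(0.8, 0.2))
})

test_that("compensation is monotone in the angio intensity", {
  set.seed(10)
  s <- EnFaceImage(matrix(runif(16 * 16, 0.3, 1), 16, 16),
                   kind = "structural")
  a1 <- matrix(runif(16 * 16), 16, 16)
  a2 <- pmin(a1 + runif(16 * 16, 0, 0.2), 1)
  o1 <- pixels(compensateSignal(EnFaceImage(a1), s))
  o2 <- pixels(compensateSignal(EnFaceImage(a2), s))
  expect_true(all(o2 - o1 >= -1e-12))
})

test_that("compensation changes FD% negligibly for flat structural", {
  set.seed(12)
  a <- EnFaceImage(matrix(runif(128 * 128), 128, 128), pitchUm = 23.4375)
  s <- EnFaceImage(matrix(0.7, 128, 128), pitchUm = 23.4375,
                   kind = "structural")
  opts <- quantifyOptions(radiusPolicy = "adjusted")
  qOn <- quantifyEye(a, s, options = opts)
  optsOff <- quantifyOptions(compensation = FALSE,
                             radiusPolicy = "adjusted")
  qOff <- quantifyEye(a, options = optsOff)
  expect_lt(max(abs(qOn$sectors$fd_percent - qOff$sectors$fd_percent)),
            1e-9)
})

test_that("compensation validates its inputs", {
  a <- EnFaceImage(matrix(0.5, 8, 8))
  s <- EnFaceImage(matrix(0.5, 8, 8), kind = "structural")
  expect_error(compensateSignal(a, EnFaceImage(matrix(0.5, 9, 9),
    kind = "structural")), "grid")
  expect_error(compensateSignal(a, s, floor = 0), "floor")
  expect_error(compensateSignal(a, a), "structural")
})

test_that("vessel dilation uses the digital disk", {
  m <- matrix(FALSE, 11, 11); m[6, 6] <- TRUE
  mask <- BinaryMask(m, "vessel-exclusion")
  d0 <- buildVesselMask(mask, 0, 1)
  expect_identical(pixels(d0), m)
  d2 <- buildVesselMask(mask, 2, 1)
  expect_identical(sum(pixels(d2)), 13L)  # radius-2 digital disk
  # enumeration: exactly the pixels within centre distance 2
  ref <- outer((1:11 - 6)^2, (1:11 - 6)^2, "+") <= 4
  expect_identical(pixels(d2), ref)
  full <- BinaryMask(matrix(TRUE, 5, 5), "vessel-exclusion")
  expect_true(all(pixels(buildVesselMask(full, 3, 1))))
  expect_error(buildVesselMask(mask, -1, 1), ">= 0")
})

test_that("exclusion flags pixels invalid and preserves mask algebra", {
  img <- EnFaceImage(matrix(0.5, 10, 10))
  none <- applyExclusion(img, BinaryMask(matrix(FALSE, 10, 10),
                                         "vessel-exclusion"))
  expect_true(all(none$valid))
  some <- matrix(FALSE, 10, 10); some[1:3, ] <- TRUE
  res <- applyExclusion(img, BinaryMask(some, "vessel-exclusion"))
  expect_identical(sum(res$valid) + sum(some), 100L)
  all <- applyExclusion(img, BinaryMask(matrix(TRUE, 10, 10),
                                        "vessel-exclusion"))
  expect_identical(sum(all$valid), 0L)
  sec <- data.frame(row0 = 0L, row1 = 10L, col0 = 0L, col1 = 10L)
  expect_error(sectorFDPercent(matrix(FALSE, 10, 10), all$valid, sec))
})
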