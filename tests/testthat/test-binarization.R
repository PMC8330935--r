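test_that("size-adjusted radius follows the scan geometry", {
  expect_identical(adjustedRadiusPx(24, 6000, 1024), 4L)
  expect_identical(adjustedRadiusPx(24, 6000, 512), 2L)
  expect_identical(adjustedRadiusPx(5.86, 6000, 1024), 1L)
  expect_error(adjustedRadiusPx(-1, 6000, 1024), "positive")
})

test_that("threshold map matches the closed form on uniform images", {
  img <- EnFaceImage(matrix(0.5, 24, 24))
  t05 <- 0.5 * (1 + 2 * exp(-5) - 0.25)
  expect_equal(unique(as.vector(phansalkarThreshold(img,
    phansalkarParams(7)))), t05)
  expect_equal(round(t05, 6), 0.381738)
  img0 <- EnFaceImage(matrix(0, 24, 24))
  expect_true(all(phansalkarThreshold(img0, phansalkarParams(7)) == 0))
})

test_that("binarization is dark-means-deficit with ties going to deficit", {
  img <- EnFaceImage(matrix(0.5, 16, 16))
  thr <- phansalkarThreshold(img, phansalkarParams(3))
  expect_false(any(pixels(binarizeFD(img, thr))))
  img0 <- EnFaceImage(matrix(0, 16, 16))
  thr0 <- phansalkarThreshold(img0, phansalkarParams(3))
  expect_true(all(pixels(binarizeFD(img0, thr0))))
  # exact ties classify as deficit
  expect_true(all(pixels(binarizeFD(img, matrix(0.5, 16, 16)))))
})

test_that("threshold map equals the brute-force oracle bit-for-bit", {
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(7:20, 1)
    radius <- sample(1:4, 1)
    img <- matrix(runif(n * n), n, n)
    fast <- phansalkarThreshold(EnFaceImage(img, pitchUm = 10),
                                phansalkarParams(radius))
    expect_identical(fast, bruteForcePhansalkar(img, radius))
  }
})

test_that("window sigma uses the population estimator", {
  # a sample-sd (divide by N-1) variant must give a different map
  set.seed(5)
  img <- matrix(runif(49), 7, 7)
  fast <- phansalkarThreshold(EnFaceImage(img, pitchUm = 10),
                              phansalkarParams(2))
  sampleSd <- bruteForcePhansalkar(img, 2)
  # recompute with N-1 normalisation
  n <- 7
  refl <- function(i, nn) if (i < 0) -1 - i else if (i >= nn)
    2 * nn - 1 - i else i
  offs <- expand.grid(dx = -2:2, dy = -2:2)
  offs <- offs[offs$dx^2 + offs$dy^2 <= 4, ]
  alt <- matrix(0, n, n)
  for (j in 0:(n - 1)) for (i in 0:(n - 1)) {
    v <- mapply(function(dx, dy)
      img[refl(i + dy, n) + 1, refl(j + dx, n) + 1], offs$dx, offs$dy)
    mu <- mean(v)
    sg <- stats::sd(v)  # divide by N-1
    alt[i + 1, j + 1] <- mu * (1 + 2 * exp(-10 * mu) + 0.25 * (sg / 0.5 - 1))
  }
  expect_identical(fast, sampleSd)
  expect_false(isTRUE(all.equal(fast, alt)))
})

test_that("bright uniform fields stay classified as flow after a shift", {
  img <- EnFaceImage(matrix(0.6, 16, 16))
  for (c in c(0, 0.1, 0.2, 0.3)) {
    shifted <- EnFaceImage(pmin(pixels(img) + c, 1))
    thr <- phansalkarThreshold(shifted, phansalkarParams(3))
    expect_false(any(pixels(binarizeFD(shifted, thr))))
  }
})

test_that("radius larger than the image is rejected", {
  img <- EnFaceImage(matrix(0.5, 8, 8))
  expect_error(phansalkarThreshold(img, phansalkarParams(8)), "radius")
})
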