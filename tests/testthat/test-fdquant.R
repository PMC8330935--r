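test_that("particle labelling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # touch only diagonally
  comp <- labelFDComponents(BinaryMask(m))$components
  expect_identical(nrow(comp), 1L)
  expect_identical(comp$pixel_count, 2L)
})

test_that("labelling matches flood-fill enumeration on random masks", {
  set.seed(21)
  for (rep in 1:8) {
    m <- matrix(runif(16 * 16) < 0.35, 16, 16)
    got <- labelFDComponents(BinaryMask(m))
    ref <- floodFillComponents(m)
    expect_identical(componentSizes(got$labels), componentSizes(ref))
    expect_identical(max(got$labels), max(ref))
  }
})

test_that("empty masks and invalid pixels are handled", {
  empty <- labelFDComponents(BinaryMask(matrix(FALSE, 5, 5)))
  expect_identical(nrow(empty$components), 0L)
  m <- matrix(TRUE, 3, 3)
  valid <- matrix(TRUE, 3, 3); valid[2, 2] <- FALSE
  comp <- labelFDComponents(BinaryMask(m), valid)$components
  expect_identical(sum(comp$pixel_count), 8L)
})

test_that("minimum FD area follows the ICD circle rule", {
  expect_identical(minFDAreaPx(24, 6000 / 1024), 14L)
  expect_identical(minFDAreaPx(24, 24), 1L)
  expect_identical(minFDAreaPx(10, 10), 1L)
  expect_error(minFDAreaPx(0, 1), "positive")
})

test_that("size filter removes strictly-smaller components only", {
  m <- matrix(FALSE, 40, 40)
  m[1:1, 1:3] <- TRUE                 # size 3
  m[10:10, 1:14] <- TRUE              # size 14
  m[20:29, 1:20] <- TRUE              # size 200
  lab <- labelFDComponents(BinaryMask(m))
  filt <- filterSmallFD(lab, 14L)
  expect_setequal(filt$components$pixel_count, c(14L, 200L))
  expect_identical(sum(filt$mask), 214L)
  ident <- filterSmallFD(lab, 1L)
  expect_identical(sum(ident$mask), sum(m))
  # kept-pixel count equals the component-size recount
  expect_identical(sum(filt$components$pixel_count), sum(filt$mask))
})

test_that("FD% is non-increasing in the minimum area", {
  set.seed(33)
  m <- matrix(runif(64 * 64) < 0.3, 64, 64)
  lab <- labelFDComponents(BinaryMask(m))
  valid <- matrix(TRUE, 64, 64)
  sec <- data.frame(row0 = 0L, row1 = 32L, col0 = 0L, col1 = 32L)
  fd <- vapply(1:8, function(a)
    sectorFDPercent(filterSmallFD(lab, a)$mask, valid, sec), numeric(1))
  expect_true(all(diff(fd) <= 0))
})

test_that("corner sectors tile the corners with correct orientation", {
  sec <- cornerSectors(1024, 6000 / 1024, "OD")
  expect_identical(sec$row0, c(0L, 0L, 853L, 853L))
  expect_identical(sec$row1, c(171L, 171L, 1024L, 1024L))
  expect_identical(sec$col0, c(0L, 853L, 853L, 0L))
  expect_identical(sec$orientation,
                   c("temporal", "nasal", "nasal", "temporal"))
  os <- cornerSectors(1024, 6000 / 1024, "OS")
  expect_identical(os$orientation,
                   c("nasal", "temporal", "temporal", "nasal"))
  # boundary case: sectors exactly tile the quadrants
  tight <- cornerSectors(342, 6000 / 1024, "OD")
  expect_identical(unique(tight$row1 - tight$row0), 171L)
  expect_identical(tight$row0[3], 171L)
  # disjointness
  expect_true(all(tight$row1 <= 342) && all(tight$col1 <= 342))
  expect_error(cornerSectors(128, 6000 / 1024, "OD"), "small")
})

test_that("sector FD% counts only valid pixels", {
  n <- 171L
  fd <- matrix(FALSE, n, n); fd[seq_len(2844)] <- TRUE
  valid <- matrix(TRUE, n, n)
  excl <- rep(FALSE, n * n); excl[seq_len(20)] <- TRUE  # 20 FD excluded
  excl[2845:3824] <- TRUE                               # 980 flow excluded
  valid[excl] <- FALSE
  sec <- data.frame(row0 = 0L, row1 = n, col0 = 0L, col1 = n)
  expect_equal(sectorFDPercent(fd, valid, sec), 100 * 2824 / 28241)
  expect_equal(sectorFDPercent(matrix(FALSE, n, n),
                               matrix(TRUE, n, n), sec), 0)
  expect_equal(sectorFDPercent(matrix(TRUE, n, n),
                               matrix(TRUE, n, n), sec), 100)
  expect_error(sectorFDPercent(fd, matrix(FALSE, n, n), sec), "valid")
})

test_that("drusen squares leave the FD model but not the LCV models", {
  d <- simulateSectorData(nIamd = 10, nControl = 10, seed = 2,
                          drusenSectorProb = 0.5)
  fdRows <- fdModelRows(d$sectors)
  expect_identical(nrow(fdRows) + sum(d$sectors$drusen), 80L)
  expect_false(any(fdRows$drusen))
})

test_that("measured FD% tracks the simulated true FD fraction", {
  # 60-eye cohort without LCV/drusen, compensated, radius 15; 256 px keeps
  # each sector at ~1850 px while the whole chain runs in about a minute
  cfg <- SimulationConfig(seed = 71, nIamd = 30, nControl = 30,
                          imageSizePx = 256, renderLcv = FALSE,
                          drusenRate = 1e-9)
  tab <- buildSectorTable(simulateCohort(cfg))
  expect_identical(nrow(tab$sectors), 240L)
  expect_gte(cor(tab$sectors$fd_percent, tab$sectors$true_fd_fraction),
             0.8)
})
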