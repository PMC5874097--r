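test_that("label resampling preserves geometry", {
  ## identity on identical grids
  m <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  expect_identical(resampleROI(m, c(1, 1), c(8L, 8L), c(1, 1)), m)
  ## 512 -> 160 downsampling of a centered disc preserves its area to
  ## within one voxel ring (analytic disc-area oracle)
  n <- 512L; fov <- 120
  spS <- rep(fov / n, 2)
  ix <- matrix(seq_len(n), n, n); iy <- t(ix)
  rMM <- 20
  disc <- ((ix - n / 2 - 0.5) * spS[1])^2 +
    ((iy - n / 2 - 0.5) * spS[2])^2 <= rMM^2
  src <- array(as.integer(disc), dim(disc))
  tDim <- c(160L, 160L); spT <- rep(fov / 160, 2)
  out <- resampleROI(src, spS, tDim, spT)
  areaOut <- sum(out == 1L) * prod(spT)
  rVox <- rMM / spT[1]
  ringArea <- (pi * (rVox + 1)^2 - pi * (rVox - 1)^2) * prod(spT)
  expect_lt(abs(areaOut - pi * rMM^2), ringArea)
  ## all-background stays all-background
  expect_true(all(resampleROI(array(0L, dim(src)), spS, tDim, spT) == 0L))
  ## incompatible physical extents are rejected
  expect_error(resampleROI(src, spS, c(64L, 64L), spT), "extent")
})

test_that("neighborhood mean is the brute-force 9-voxel average", {
  m <- matrix(0, 5, 5); m[3, 3] <- 9
  expect_equal(neighborhoodMean(m, c(3, 3)), 1)
  expect_equal(neighborhoodMean(matrix(7, 4, 4), c(2, 2)), 7)
  set.seed(20)
  a <- array(rnorm(125), c(5, 5, 5))
  for (ctr in list(c(2, 2, 1), c(3, 4, 3), c(4, 2, 5))) {
    manual <- mean(vapply(1:9, function(q) {
      di <- (q - 1) %% 3 - 1; dj <- (q - 1) %/% 3 - 1
      a[ctr[1] + di, ctr[2] + dj, ctr[3]]
    }, numeric(1)))
    expect_equal(neighborhoodMean(a, ctr), manual)
  }
  expect_error(neighborhoodMean(a, c(1, 3, 2)), "edge")
})

test_that("window placement is deterministic and representative", {
  ## a single 3x3 region: its center voxel is chosen
  lab <- array(0L, c(5, 5, 1)); lab[2:4, 2:4, 1] <- 2L
  k <- array(seq_len(25), c(5, 5, 1))
  ctr <- pickRegionCenter(lab, 2L, k)
  expect_equal(as.integer(ctr[1:2]), c(3L, 3L))
  ## constant map: lowest-linear-index eligible voxel
  lab2 <- array(0L, c(7, 7, 1)); lab2[2:6, 2:6, 1] <- 3L
  kc <- array(1, c(7, 7, 1))
  ctr2 <- pickRegionCenter(lab2, 3L, kc)
  expect_equal(as.integer(ctr2[1:2]), c(3L, 3L))
  ## region too thin for any interior window: centroid fallback, flagged
  lab3 <- array(0L, c(7, 7, 1)); lab3[4, 2:6, 1] <- 1L
  ctr3 <- pickRegionCenter(lab3, 1L, kc)
  expect_true(attr(ctr3, "fallback"))
  expect_error(pickRegionCenter(lab3, 2L, kc), "not present")
})

test_that("phantom window means land near the region ground truth", {
  st <- smallStudyFixture()
  lab <- labelMap(st$truth)
  lab[!(lab %in% 1:3)] <- 0L
  for (code in 2:3) {   # ring regions wide enough for interior windows
    ctr <- pickRegionCenter(lab, code, ktransMap(st$truth))
    wm <- neighborhoodMean(ktransMap(st$truth), ctr)
    truthMean <- mean(ktransMap(st$truth)[lab == code])
    expect_lt(abs(wm - truthMean) / truthMean, 0.10)
  }
})

test_that("tumor summaries join parameters with MVD per region", {
  st <- smallStudyFixture()
  lab <- labelMap(st$truth)
  lab[!(lab %in% 1:3)] <- 0L
  maps <- new("ParameterMaps", ktrans = ktransMap(st$truth),
              ve = veMap(st$truth), vp = vpMap(st$truth),
              t0 = ktransMap(st$truth) * 0, rss = ktransMap(st$truth) * 0,
              converged = array(TRUE, dim(lab)),
              mask = array(TRUE, dim(lab)))
  rows <- summarizeTumor(maps, lab, st$mvd, tumorId = 3L)
  expect_equal(nrow(rows), 3L)
  expect_equal(rows$region, c("CNA", "PNA", "VTA"))
  ## truth ordering propagates to the summary
  expect_lt(rows$ktrans[1], rows$ktrans[2])
  expect_lt(rows$ktrans[2], rows$ktrans[3])
  expect_equal(rows$mvd, st$mvd$mvd)
  ## only one region present: one row; missing MVD row warns
  labV <- lab; labV[labV != 3L] <- 0L
  one <- summarizeTumor(maps, labV, st$mvd, tumorId = 1L)
  expect_equal(nrow(one), 1L)
  expect_warning(
    summarizeTumor(maps, lab, st$mvd[st$mvd$region != "PNA", ]),
    "PNA")
})

test_that("the bundled table round-trips through the summary CSV", {
  tab <- loadTable1Fixture()
  path <- tempfile(fileext = ".csv")
  writeSummary(tab, path)
  back <- readSummary(path)
  expect_equal(back, tab)
})
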