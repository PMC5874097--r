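test_that("curve-shape metrics interpolate the half-maximum crossings", {
  tg <- seq(0, 60, by = 2.4)
  ## triangular bolus with known width
  cv <- pmax(0, 1 - abs(tg - 24) / 12)
  m <- curveShapeMetrics(cv, tg)
  expect_equal(unname(m["peak"]), 1)
  expect_equal(unname(m["ttp"]), 24)
  expect_equal(unname(m["fwhm"]), 12, tolerance = 1e-9)
})

test_that("candidate ranking is deterministic with index tie-break", {
  acq <- acquisitionParams(nDynamics = 20L)
  tg <- dynamicTimes(acq)
  bolus <- simulateBloodCurve(3, tg, shape = list(
    ta = 4, alpha = 2, beta = 2, recircFrac = 0.1, tauIn = 10,
    tauOut = 40))
  d <- c(3, 3, 1)
  conc <- array(0, c(d, length(tg)))
  ## voxel 2: the only enhancing voxel in a single-voxel mask
  conc[2, 1, 1, ] <- bolus
  cs <- new("ConcentrationSeries", conc = conc, times = tg,
            nBaseline = 2L)
  mask <- array(FALSE, d); mask[2, 1, 1] <- TRUE
  one <- scoreAIFCandidates(cs, mask)
  expect_equal(one$voxel, 2L)
  ## two identical curves: lower linear index first
  conc[1, 2, 1, ] <- bolus
  conc[3, 2, 1, ] <- bolus
  cs2 <- new("ConcentrationSeries", conc = conc, times = tg,
             nBaseline = 2L)
  full <- array(TRUE, d)
  r <- scoreAIFCandidates(cs2, full)
  ties <- r$voxel[r$score == max(r$score)]
  expect_equal(ties, sort(ties))
  ## no enhancing voxel: empty with a warning
  csz <- new("ConcentrationSeries",
             conc = array(0, c(d, length(tg))) - 0.01, times = tg,
             nBaseline = 2L)
  expect_warning(out <- scoreAIFCandidates(csz, full), "no enhancing")
  expect_equal(nrow(out), 0L)
})

test_that("phantom blood pool dominates the candidate ranking", {
  st <- smallStudyFixture()
  searchMask <- labelMap(st$truth) %in% c(3L, 4L, 5L)
  dim(searchMask) <- dim(labelMap(st$truth))
  cand <- scoreAIFCandidates(st$conc, searchMask)
  top10 <- cand$voxel[1:10]
  expect_true(all(labelMap(st$truth)[top10] == 5L))
})

test_that("extraction averages, deduplicates and corrects for Hct", {
  st <- smallStudyFixture()
  blood <- which(labelMap(st$truth) == 5L)
  ## one voxel at hct = 0: the voxel's own whole-blood curve
  one <- extractAIF(st$conc, blood[1], hct = 0)
  d <- dim(labelMap(st$truth))
  raw <- matrix(concArray(st$conc), nrow = prod(d))[blood[1], ]
  expect_equal(plasmaCurve(one), raw, tolerance = 1e-12)
  ## duplicated voxel list changes nothing
  a1 <- extractAIF(st$conc, blood[1:4], hct = 0.45)
  a2 <- extractAIF(st$conc, c(blood[1:4], blood[1:4]), hct = 0.45)
  expect_equal(plasmaCurve(a1), plasmaCurve(a2))
  ## round trip: recovered Cp equals the simulated plasma input
  all_ <- extractAIF(st$conc, blood, hct = st$acq@hct)
  expect_lt(max(abs(plasmaCurve(all_) - plasmaCurve(st$aif))), 1e-9)
  ## voxels outside the volume are rejected
  expect_error(extractAIF(st$conc, prod(d) + 10L), "outside")
})

test_that("extraction commutes with global concentration scaling", {
  st <- smallStudyFixture()
  blood <- which(labelMap(st$truth) == 5L)[1:5]
  sc <- new("ConcentrationSeries", conc = 3 * concArray(st$conc),
            times = timeGrid(st$conc), nBaseline = 2L)
  a1 <- extractAIF(st$conc, blood, 0.45)
  a3 <- extractAIF(sc, blood, 0.45)
  expect_equal(plasmaCurve(a3), 3 * plasmaCurve(a1), tolerance = 1e-12)
})
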