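test_that("forward model degenerates correctly", {
  aif <- defaultAIF()
  ## ktrans = 0: pure plasma term with the delay applied
  p <- ketyParams(0, 0.2, 0.05, 4.8)
  ct <- ketyForward(p, aif)
  cpd <- approx(timeGrid(aif), plasmaCurve(aif),
                xout = timeGrid(aif) - 4.8, yleft = 0, rule = 2)$y
  expect_equal(ct, 0.05 * cpd, tolerance = 1e-12)
  ## vp = 0, ktrans = 0: identically zero
  expect_equal(ketyForward(ketyParams(0, 0.2, 0), aif),
               numeric(length(plasmaCurve(aif))))
  ## ktrans > 0 with ve = 0 is rejected
  expect_error(ketyForward(list(ktrans = 0.2, ve = 0, vp = 0, t0 = 0),
                           aif), "ve")
})

test_that("numerical convolution matches the analytic impulse response", {
  ## unit impulse in Cp at frame j with vp = 0 has the closed form
  ## Ktrans * dt * exp(-(Ktrans/ve)(t - t_j)) for t > t_j
  acq <- acquisitionParams()
  tg <- dynamicTimes(acq)
  j <- 10L
  cp <- numeric(length(tg)); cp[j] <- 1
  aif <- new("AIF", cp = cp, times = tg, sourceVoxels = integer(),
             peak = 1, ttp = tg[j], fwhm = acq@dt)
  for (th in list(c(0.45, 0.084), c(1.5, 0.2), c(0.05, 0.3))) {
    ktrans <- th[1]; ve <- th[2]
    ct <- ketyForward(list(ktrans = ktrans, ve = ve, vp = 0, t0 = 0), aif)
    after <- seq(j + 1L, length(tg))
    analytic <- ktrans / 60 * acq@dt *
      exp(-(ktrans / ve) / 60 * (tg[after] - tg[j]))
    expect_lt(max(abs(ct[after] - analytic) / analytic), 0.005)
  }
})

test_that("quadrature converges: halving dt changes the fit by < 1%", {
  acq <- acquisitionParams()
  tgC <- dynamicTimes(acq)
  tgF <- seq(0, max(tgC), by = acq@dt / 2)
  thTrue <- ketyParams(0.45, 0.084, 0.0237, 4.8)
  mk <- function(tg) {
    aif <- aifCurve(bloodToPlasma(simulateBloodCurve(5, tg), acq@hct), tg)
    fitKetyVoxel(ketyForward(thTrue, aif), aif,
                 multistart = TRUE)$params$ktrans
  }
  expect_lt(abs(mk(tgF) - mk(tgC)) / mk(tgC), 0.01)
})

test_that("voxel fit recovers parameters in the viable-tumor regime", {
  aif <- defaultAIF()
  thTrue <- ketyParams(0.45, 0.084, 0.0237, 4.8)
  ct <- ketyForward(thTrue, aif)
  f <- fitKetyVoxel(ct, aif)
  expect_true(f$converged)
  expect_lt(abs(f$params$ktrans - 0.45) / 0.45, 0.01)
  expect_lt(abs(f$params$ve - 0.084), 0.005)
  expect_lt(abs(f$params$vp - 0.0237), 0.005)
  ## descent: the optimum cannot be worse than the starting point
  init <- ketyParams(0.1, 0.2, 0.02, 0)
  rss0 <- sum((ct - ketyForward(init, aif))^2)
  expect_lte(f$rss, rss0)
})

test_that("all-zero and invalid curves are handled without error", {
  aif <- defaultAIF()
  z <- fitKetyVoxel(numeric(length(plasmaCurve(aif))), aif)
  expect_true(z$converged)
  expect_equal(z$params$ktrans, 0)
  expect_equal(z$params$vp, 0)
  expect_equal(z$rss, 0)
  expect_false(z$veIdentifiable)
  bad <- fitKetyVoxel(rep(NA_real_, length(plasmaCurve(aif))), aif)
  expect_false(bad$converged)
})

test_that("noisy replicate fits recover the median Ktrans within 5%", {
  aif <- defaultAIF()
  ct <- ketyForward(ketyParams(0.45, 0.084, 0.0237, 4.8), aif)
  set.seed(314)
  ks <- vapply(1:100, function(i) {
    fitKetyVoxel(ct + rnorm(length(ct), 0, 0.01), aif,
                 multistart = TRUE)$params$ktrans
  }, numeric(1))
  expect_lt(abs(median(ks) - 0.45) / 0.45, 0.05)
})

test_that("map fitting is consistent with voxel fitting and order-free", {
  st <- smallStudyFixture()
  d <- dim(labelMap(st$truth))
  ## one-voxel mask equals the voxel fit
  v <- which(labelMap(st$truth) == 2L)[5]
  mask1 <- array(FALSE, d); mask1[v] <- TRUE
  maps1 <- fitKetyMap(st$conc, st$aifHat, mask1, multistart = TRUE)
  curve <- matrix(concArray(st$conc), nrow = prod(d))[v, ]
  f <- fitKetyVoxel(curve, st$aifHat, multistart = TRUE)
  expect_equal(ktransMap(maps1)[v], f$params$ktrans, tolerance = 1e-12)
  expect_true(all(is.na(ktransMap(maps1)[-v])))
  ## empty mask warns
  expect_warning(fitKetyMap(st$conc, st$aifHat, array(FALSE, d)),
                 "empty")
})

test_that("noise-free phantom region medians are recovered within 2%", {
  st <- smallStudyFixture()
  maps <- fitKetyMap(st$conc, st$aifHat, st$roi, multistart = TRUE)
  for (code in 1:3) {
    sel <- labelMap(st$truth) == code
    expect_lt(abs(median(ktransMap(maps)[sel]) -
                    median(ktransMap(st$truth)[sel])) /
                median(ktransMap(st$truth)[sel]), 0.02)
  }
  ## automatic vs ground-truth-mask AIF selection: fitted Ktrans agree
  bloodMask <- labelMap(st$truth) == 5L
  dim(bloodMask) <- dim(labelMap(st$truth))
  aifAll <- extractAIF(st$conc, which(bloodMask), st$acq@hct)
  vox <- which(st$roi)[seq(1, sum(st$roi), by = 7)]
  m2 <- array(FALSE, dim(st$roi)); m2[vox] <- TRUE
  mapsB <- fitKetyMap(st$conc, aifAll, m2, multistart = TRUE)
  relDiff <- abs(ktransMap(mapsB)[vox] - ktransMap(maps)[vox]) /
    ktransMap(maps)[vox]
  expect_lt(median(relDiff), 0.03)
})
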