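test_that("ground truth orders region Ktrans and is reproducible", {
  cfg <- smallPhantomConfig()
  t1 <- makeGroundTruth(cfg, seed = 1)
  t2 <- makeGroundTruth(cfg, seed = 1)
  expect_identical(ktransMap(t1), ktransMap(t2))
  expect_identical(labelMap(t1), labelMap(t2))
  k <- ktransMap(t1); lab <- labelMap(t1)
  expect_lt(mean(k[lab == 1]), mean(k[lab == 2]))
  expect_lt(mean(k[lab == 2]), mean(k[lab == 3]))
  ## a different seed changes the draws
  t3 <- makeGroundTruth(cfg, seed = 2)
  expect_false(identical(ktransMap(t1), ktransMap(t3)))
  ## invariants hold
  expect_true(all(veMap(t1) + vpMap(t1) <= 1))
  expect_true(all(k[lab == 0] == 0))
})

test_that("zero within-region variability gives uniform regions", {
  truth <- makeGroundTruth(smallPhantomConfig(intraCV = 0), seed = 5)
  for (code in 1:3) {
    v <- ktransMap(truth)[labelMap(truth) == code]
    expect_equal(max(v) - min(v), 0)
  }
})

test_that("configs that could breach ve + vp <= 1 are rejected", {
  expect_error(smallPhantomConfig(regionMeans = list(
    ktrans = c(cna = 0.04, pna = 0.3, vta = 1),
    ve = c(cna = 0.6, pna = 0.6, vta = 0.6),
    vp = c(cna = 0.3, pna = 0.3, vta = 0.3))), "exceed")
  expect_error(smallPhantomConfig(regionMeans = list(
    ktrans = c(cna = 1, pna = 0.3, vta = 0.04),
    ve = c(cna = 0.2, pna = 0.2, vta = 0.2),
    vp = c(cna = 0.02, pna = 0.02, vta = 0.02))), "increase")
})

test_that("synthetic bolus has the required first-pass shape", {
  tg <- dynamicTimes(acquisitionParams())
  cb <- simulateBloodCurve(5, tg)
  expect_equal(cb[1], 0)
  expect_equal(max(cb), 5)
  ## single global maximum, fast wash-in, washed out by the end
  expect_lt(tg[which.max(cb)], 30)
  expect_lt(cb[length(cb)], 0.2 * 5)
  ## monotone decay after the recirculation shoulder
  post <- cb[tg > 60]
  expect_true(all(diff(post) <= 0))
  ## peak is a pure scale factor
  expect_equal(simulateBloodCurve(2.5, tg), cb / 2, tolerance = 1e-12)
  expect_equal(simulateBloodCurve(0, tg), numeric(length(tg)))
  expect_error(simulateBloodCurve(5, c(0, 1, 3)), "uniform")
})

test_that("noise-free VFA rendering equals the SPGR forward model and
           round-trips through the VFA fit", {
  st <- smallStudyFixture()
  acq <- st$acq; truth <- st$truth
  v <- which(labelMap(truth) == 3L)[1]
  expect_equal(st$vfa[["fa10"]][v],
               spgrSignal(s0Map(truth)[v], t10Map(truth)[v], 10, acq@tr))
  ## recovered T10 equals the ground-truth map where tissue exists
  ok <- fitMask(st$t1set) & s0Map(truth) > 0
  expect_lt(max(abs(t10Map(st$t1set)[ok] - t10Map(truth)[ok]) /
                  t10Map(truth)[ok]), 1e-6)
  ## zero flip angle renders a zero image
  z <- renderVFAImages(truth, acq, noiseSd = 0)
  expect_equal(spgrSignal(s0Map(truth), t10Map(truth), 0, acq@tr),
               array(0, dim(labelMap(truth))))
})

test_that("dynamic rendering is deterministic with flat curves where no
           contrast arrives", {
  st <- smallStudyFixture()
  acq <- st$acq
  ## background voxel: constant (zero-signal) curve across all frames
  bg <- which(labelMap(st$truth) == 0L)[1]
  d <- dim(labelMap(st$truth))
  curve <- matrix(signalArray(st$dyn), nrow = prod(d))[bg, ]
  expect_equal(max(curve) - min(curve), 0)
  ## same seed, same render, bit for bit (with noise)
  d1 <- renderDynamicSeries(st$truth, st$aif, acq, noiseSd = 2, seed = 9)
  d2 <- renderDynamicSeries(st$truth, st$aif, acq, noiseSd = 2, seed = 9)
  expect_identical(signalArray(d1), signalArray(d2))
})

test_that("MVD sampling follows the linear link with truncation at zero", {
  st <- smallStudyFixture()
  link0 <- mvdLink(noiseSd = 0)
  mvd <- sampleMVD(st$truth, link0, nFields = 5, seed = 1)
  kP <- mvd$mean_ktrans[mvd$region == "PNA"]
  expect_equal(mvd$mvd[mvd$region == "PNA"],
               link0$slope * kP + link0$intercept)
  expect_equal(mvd$mvd[mvd$region == "CNA"], link0$cnaRate)
  ## counts never negative even under heavy noise
  noisy <- sampleMVD(st$truth, mvdLink(noiseSd = 50), seed = 3)
  expect_true(all(noisy$mvd >= 0))
})

test_that("cohort simulation is reproducible and respects a null link", {
  c1 <- simulateCohort(seed = 11)
  c2 <- simulateCohort(seed = 11)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 45L)
  ## slope = 0 breaks the Ktrans-MVD association (null r on average)
  rs <- vapply(1:50, function(s) {
    co <- simulateCohort(link = mvdLink(slope = 0), seed = s)
    pna <- co[co$region == "PNA", ]
    pearsonCorrelation(pna$ktrans, pna$mvd)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
})
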