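## Shared small-phantom fixture: a 48 x 48 x 3 grid with one concentric
## tumor (CNA/PNA/VTA), liver and a blood pool, cached per test run so
## the expensive end-to-end objects are built once.

smallPhantomConfig <- function(...) {
  phantomConfig(dim = c(48L, 48L, 3L), tumorCenter = c(24, 26),
                tumorSlices = 2L, liverCenter = c(24, 27),
                liverSemiAxesMM = c(15, 12), bloodCenter = c(8, 8),
                radiiMM = c(cna = 3, pna = 6, vta = 9), ...)
}

.cache <- new.env(parent = emptyenv())

## noise-free small study pushed through relaxometry + concentration +
## AIF extraction (shared by the aif/kety/pipeline tests)
smallStudyFixture <- function() {
  if (!is.null(.cache$study)) return(.cache$study)
  acq <- acquisitionParams()
  cfg <- smallPhantomConfig()
  st <- simulatePhantomStudy(cfg, acq, noiseSd = 0, seed = 1)
  t1set <- fitVFAMap(st$vfa, acq@flipAngles, acq@tr)
  conc <- concentrationSeries(st$dyn, t1set)
  bloodMask <- labelMap(st$truth) == 5L
  dim(bloodMask) <- dim(labelMap(st$truth))
  cand <- scoreAIFCandidates(conc, bloodMask)
  aifHat <- extractAIF(conc, cand$voxel[1:5], acq@hct)
  roi <- labelMap(st$truth) %in% 1:3
  dim(roi) <- dim(labelMap(st$truth))
  .cache$study <- list(acq = acq, cfg = cfg, truth = st$truth,
                       aif = st$aif, vfa = st$vfa, dyn = st$dyn,
                       mvd = st$mvd, t1set = t1set, conc = conc,
                       cand = cand, aifHat = aifHat, roi = roi)
  .cache$study
}

## default-protocol synthetic input function on the acquisition grid
defaultAIF <- function(peak = 5) {
  acq <- acquisitionParams()
  tg <- dynamicTimes(acq)
  aifCurve(bloodToPlasma(simulateBloodCurve(peak, tg), acq@hct), tg)
}

## brute-force signed-rank two-sided p by enumerating all sign vectors
enumSignedRankP <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  lower <- mean(vs <= v + 1e-9)
  upper <- mean(vs >= v - 1e-9)
  min(1, 2 * min(lower, upper))
}
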