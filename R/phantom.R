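## Digital phantom: ground-truth parameter maps over an ablated-tumor
## geometry (necrotic core, partial-necrotic ring, viable rim inside liver,
## plus a blood pool), a synthetic first-pass bolus, SPGR renderings of the
## VFA and dynamic acquisitions, and microvessel-density counts linked
## linearly to Ktrans. Every generator is reproducible under a fixed seed.

## run expr under a fixed seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## lognormal draws parameterized by arithmetic mean and coefficient of
## variation; cv = 0 degenerates to the exact mean
rlnormMean <- function(n, mean, cv) {
  if (mean <= 0) return(rep(0, n))
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Phantom configuration
#'
#' Geometry and ground-truth statistics of the digital phantom. The default
#' grid emulates a coronal 160 x 160 acquisition (0.75 mm in-plane, 2 mm
#' slices, 8 slices) containing one ablated tumor: a completely necrotic
#' core (CNA), a partial necrotic ring (PNA) and a viable rim (VTA) as
#' concentric discs on the central slices, embedded in liver, with a
#' cylindrical blood pool for input-function extraction. Region Ktrans
#' means default to the per-region column means of the bundled tumor table
#' (CNA 0.044, PNA 0.293, VTA 1.00 /min) so the synthetic curves stay in a
#' realistic dynamic range.
#'
#' @param dim grid size (x, y, z)
#' @param spacing voxel spacing, mm
#' @param tumorCenter in-plane center of the tumor, voxels
#' @param tumorSlices slice indices carrying the tumor
#' @param radiiMM outer radii of CNA, PNA, VTA discs, mm
#' @param liverCenter,liverSemiAxesMM in-plane liver ellipse
#' @param bloodCenter,bloodRadiusMM in-plane blood-pool cylinder
#' @param regionMeans list of per-region mean \code{ktrans} (/min),
#'   \code{ve} and \code{vp} (fractions), each named CNA/PNA/VTA;
#'   mean Ktrans must increase CNA < PNA < VTA
#' @param intraCV within-region coefficient of variation of the voxelwise
#'   parameter draws (0 gives uniform regions)
#' @param liverParams Ktrans/ve/vp of normal liver
#' @param t10 precontrast T1 by tissue class, seconds
#' @param s0 equilibrium signal of tissue
#' @param t0 bolus-arrival delay of tissue relative to the input
#'   function, seconds
#' @param aifPeak whole-blood peak concentration of the synthetic bolus, mM
#' @return a configuration list for \code{\link{makeGroundTruth}}
#' @export
phantomConfig <- function(dim = c(160L, 160L, 8L),
                          spacing = c(0.75, 0.75, 2),
                          tumorCenter = c(80, 88),
                          tumorSlices = 3:6,
                          radiiMM = c(cna = 3.75, pna = 6.75, vta = 9.75),
                          liverCenter = c(80, 90),
                          liverSemiAxesMM = c(45, 35),
                          bloodCenter = c(25, 25),
                          bloodRadiusMM = 2.25,
                          regionMeans = list(
                            ktrans = c(cna = 0.044, pna = 0.293, vta = 1.0),
                            ve = c(cna = 0.23, pna = 0.134, vta = 0.141),
                            vp = c(cna = 0.015, pna = 0.034, vta = 0.033)),
                          intraCV = 0.1,
                          liverParams = c(ktrans = 0.15, ve = 0.25,
                                          vp = 0.05),
                          t10 = c(tumor = 1.1, liver = 0.8, blood = 1.6,
                                  background = 1.0),
                          s0 = 1000,
                          t0 = 4.8,
                          aifPeak = 5) {
  cfg <- list(dim = as.integer(dim), spacing = spacing,
              tumorCenter = tumorCenter, tumorSlices = tumorSlices,
              radiiMM = radiiMM, liverCenter = liverCenter,
              liverSemiAxesMM = liverSemiAxesMM,
              bloodCenter = bloodCenter, bloodRadiusMM = bloodRadiusMM,
              regionMeans = regionMeans, intraCV = intraCV,
              liverParams = liverParams, t10 = t10, s0 = s0, t0 = t0,
              aifPeak = aifPeak)
  if (is.unsorted(regionMeans$ktrans, strictly = TRUE))
    stop("region mean Ktrans must increase CNA < PNA < VTA")
  ## ve + vp must stay below 1 even in the upper tail of the draws
  tail <- (regionMeans$ve + regionMeans$vp) * (1 + 5 * intraCV)
  if (any(tail >= 1) ||
      (liverParams["ve"] + liverParams["vp"]) * (1 + 5 * intraCV) >= 1)
    stop("configured ve + vp could exceed 1")
  cfg
}

#' Generate phantom ground truth
#'
#' Builds the label geometry of \code{\link{phantomConfig}} and draws
#' voxel-wise Ktrans/ve/vp from lognormal distributions with the configured
#' region means and within-region coefficient of variation (the lognormal
#' keeps rates positive; \code{intraCV = 0} gives exactly the region mean
#' at every voxel). T10 and S0 are assigned by tissue class. Background
#' voxels carry zero Ktrans and zero signal.
#'
#' @param config a \code{\link{phantomConfig}} list
#' @param seed integer seed; the result is reproducible voxel-for-voxel
#' @return a \code{\linkS4class{PhantomTruth}}
#' @examples
#' truth <- makeGroundTruth(phantomConfig(dim = c(40, 40, 3),
#'   tumorCenter = c(20, 20), tumorSlices = 2, liverCenter = c(20, 20),
#'   liverSemiAxesMM = c(13, 13), bloodCenter = c(6, 6)), seed = 1)
#' truth
#' @export
makeGroundTruth <- function(config = phantomConfig(), seed = 1L) {
  d <- config$dim
  sp <- config$spacing
  ix <- matrix(seq_len(d[1]), d[1], d[2])
  iy <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  distMM <- function(center)
    sqrt(((ix - center[1]) * sp[1])^2 + ((iy - center[2]) * sp[2])^2)
  liver2d <- (((ix - config$liverCenter[1]) * sp[1] /
                 config$liverSemiAxesMM[1])^2 +
              ((iy - config$liverCenter[2]) * sp[2] /
                 config$liverSemiAxesMM[2])^2) <= 1
  blood2d <- distMM(config$bloodCenter) <= config$bloodRadiusMM
  dTum <- distMM(config$tumorCenter)
  labels <- array(0L, d)
  for (z in seq_len(d[3])) {
    sl <- matrix(0L, d[1], d[2])
    sl[liver2d] <- 4L
    if (z %in% config$tumorSlices) {
      sl[dTum <= config$radiiMM["vta"]] <- 3L
      sl[dTum <= config$radiiMM["pna"]] <- 2L
      sl[dTum <= config$radiiMM["cna"]] <- 1L
    }
    sl[blood2d] <- 5L
    labels[, , z] <- sl
  }
  ktrans <- array(0, d); ve <- array(0, d); vp <- array(0, d)
  t10 <- array(config$t10["background"], d)
  s0 <- array(0, d)
  rm <- config$regionMeans
  withSeed(seed, {
    for (code in 1:3) {
      idx <- which(labels == code)
      if (!length(idx)) next
      n <- length(idx)
      ktrans[idx] <- rlnormMean(n, rm$ktrans[code], config$intraCV)
      ve[idx] <- rlnormMean(n, rm$ve[code], config$intraCV)
      vp[idx] <- rlnormMean(n, rm$vp[code], config$intraCV)
      t10[idx] <- config$t10["tumor"]
      s0[idx] <- config$s0
    }
    idx <- which(labels == 4L)
    n <- length(idx)
    ktrans[idx] <- rlnormMean(n, config$liverParams["ktrans"],
                              config$intraCV)
    ve[idx] <- rlnormMean(n, config$liverParams["ve"], config$intraCV)
    vp[idx] <- rlnormMean(n, config$liverParams["vp"], config$intraCV)
    t10[idx] <- config$t10["liver"]
    s0[idx] <- config$s0
  })
  idx <- which(labels == 5L)
  t10[idx] <- config$t10["blood"]
  s0[idx] <- config$s0
  ## guard the fractional-volume invariant in the extreme upper tail
  over <- ve + vp > 1
  if (any(over)) {
    sc <- 0.999 / (ve[over] + vp[over])
    ve[over] <- ve[over] * sc
    vp[over] <- vp[over] * sc
  }
  new("PhantomTruth", ktrans = ktrans, ve = ve, vp = vp, t10 = t10,
      s0 = s0, labels = labels, spacing = sp, config = config)
}

#' Synthetic first-pass bolus in whole blood
#'
#' Gamma-variate first pass plus a slow recirculation/washout shoulder:
#' \deqn{C_b(t) \propto u^{\alpha} e^{-u/\beta} + A_r (1 - e^{-u/\tau_{in}})
#' e^{-u/\tau_{out}}, \quad u = t - t_a,} normalized so the grid maximum
#' equals \code{peak}. The curve is zero before arrival, has a single
#' global maximum at the gamma-variate mode, and decays monotonically after
#' the recirculation shoulder.
#'
#' @param peak peak whole-blood concentration, mM (a pure scale factor)
#' @param times uniform time grid, seconds
#' @param shape list with arrival time \code{ta} (s), gamma-variate
#'   exponent \code{alpha} and time constant \code{beta} (s), recirculation
#'   amplitude \code{recircFrac} (fraction of the first-pass peak) and time
#'   constants \code{tauIn}, \code{tauOut} (s)
#' @return whole-blood concentration curve, mM
#' @examples
#' cb <- simulateBloodCurve(5, dynamicTimes(acquisitionParams()))
#' max(cb)  # 5
#' @export
simulateBloodCurve <- function(peak, times,
                               shape = list(ta = 12, alpha = 2,
                                            beta = 2.5, recircFrac = 0.15,
                                            tauIn = 15, tauOut = 80)) {
  stopifnot(peak >= 0, length(times) >= 2)
  dt <- diff(times)
  if (any(abs(dt - dt[1]) > 1e-9 * max(dt[1], 1)))
    stop("time grid must be uniform")
  if (peak == 0) return(numeric(length(times)))
  u <- pmax(times - shape$ta, 0)
  mode <- shape$alpha * shape$beta
  g <- (u / mode)^shape$alpha * exp((mode - u) / shape$beta)
  g[u == 0] <- 0
  w <- shape$recircFrac * (1 - exp(-u / shape$tauIn)) *
    exp(-u / shape$tauOut)
  w[u == 0] <- 0
  curve <- g + w
  peak * curve / max(curve)
}

#' Render the precontrast variable-flip-angle volumes
#'
#' Forward SPGR rendering of the phantom at each precontrast flip angle,
#' with optional additive Gaussian noise on the magnitude signal.
#'
#' @param truth a \code{\linkS4class{PhantomTruth}}
#' @param acq an \code{\linkS4class{AcquisitionParams}}
#' @param noiseSd Gaussian noise standard deviation, signal units
#' @param seed seed for the noise draw
#' @return named list of 3D signal arrays, one per flip angle
#' @export
renderVFAImages <- function(truth, acq, noiseSd = 0, seed = 1L) {
  out <- lapply(acq@flipAngles, function(a)
    spgrSignal(truth@s0, truth@t10, a, acq@tr))
  names(out) <- paste0("fa", acq@flipAngles)
  if (noiseSd > 0) {
    out <- withSeed(seed, lapply(out, function(v)
      v + array(stats::rnorm(length(v), 0, noiseSd), dim(v))))
  }
  out
}

#' Render the dynamic contrast-enhanced series
#'
#' Composes the extended Kety forward model (per tissue voxel, with the
#' phantom's ground-truth parameters and bolus delay), the relaxation-rate
#' increase \eqn{R_1(t) = 1/T_{10} + r_1 C(t)}, and the SPGR signal
#' equation at the dynamic flip angle. Blood-pool voxels carry the
#' whole-blood curve \eqn{C_b = C_p (1 - \mathrm{Hct})}. The first
#' \code{nBaseline} frames precede bolus arrival, so they are rendered at
#' zero concentration. Additive Gaussian noise on the magnitude signal is
#' optional.
#'
#' @param truth a \code{\linkS4class{PhantomTruth}}
#' @param aif ground-truth plasma input function on the acquisition grid
#' @param acq an \code{\linkS4class{AcquisitionParams}}
#' @param noiseSd Gaussian noise standard deviation, signal units
#' @param seed seed for the noise draw
#' @return a \code{\linkS4class{DynamicSeries}}
#' @export
renderDynamicSeries <- function(truth, aif, acq, noiseSd = 0, seed = 1L) {
  d <- dim(truth@ktrans)
  times <- dynamicTimes(acq)
  nt <- length(times)
  if (length(aif@cp) != nt ||
      max(abs(aif@times - times)) > 1e-9)
    stop("AIF is not defined on the acquisition time grid")
  dt <- acq@dt
  cpd <- delayCurve(aif@cp, times, truth@config$t0)
  conc <- matrix(0, prod(d), nt)
  tis <- which(truth@labels %in% 1:4)
  if (length(tis)) {
    kt <- truth@ktrans[tis]; vev <- truth@ve[tis]; vpv <- truth@vp[tis]
    kep <- ifelse(kt > 0, (kt / pmax(vev, 1e-12)) / 60, 0)
    E <- exp(-kep * dt)
    acc <- numeric(length(tis))
    conc[tis, 1] <- vpv * cpd[1]
    for (k in 2:nt) {
      acc <- acc * E + dt / 2 * (cpd[k] + cpd[k - 1] * E)
      conc[tis, k] <- vpv * cpd[k] + (kt / 60) * acc
    }
  }
  blood <- which(truth@labels == 5L)
  if (length(blood)) {
    cb <- aif@cp * (1 - acq@hct)
    conc[blood, ] <- matrix(cb, length(blood), nt, byrow = TRUE)
  }
  ## relaxation-rate increase, then SPGR signal at the dynamic flip angle
  r10 <- 1 / as.numeric(truth@t10)
  s0 <- as.numeric(truth@s0)
  a <- acq@dynamicFlip * pi / 180
  sig <- matrix(0, prod(d), nt)
  for (k in seq_len(nt)) {
    e1 <- exp(-(acq@tr / 1000) * (r10 + acq@r1 * conc[, k]))
    sig[, k] <- s0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
  }
  if (noiseSd > 0)
    sig <- withSeed(seed,
      sig + matrix(stats::rnorm(length(sig), 0, noiseSd), nrow(sig)))
  dynamicSeries(array(sig, c(d, nt)), acq, times)
}

#' Linear Ktrans-to-microvessel-density link
#'
#' Parameters of the synthetic association between a region's mean Ktrans
#' and its microvessel count per high-power field. Defaults are calibrated
#' to the bundled tumor table: a line through the PNA and VTA column means
#' (slope 13.9 vessels per (1/min), intercept 2.96 vessels), field-to-field
#' noise of 3 vessels, and a near-zero necrotic rate of 1.11 vessels.
#'
#' @param slope vessels per (1/min)
#' @param intercept vessels
#' @param noiseSd field-to-field standard deviation, vessels
#' @param cnaRate mean count in completely necrotic tissue, vessels
#' @return a link list for \code{\link{sampleMVD}}
#' @export
mvdLink <- function(slope = 13.9, intercept = 2.96, noiseSd = 3,
                    cnaRate = 1.11) {
  stopifnot(slope >= 0, noiseSd >= 0, cnaRate >= 0)
  list(slope = slope, intercept = intercept, noiseSd = noiseSd,
       cnaRate = cnaRate)
}

#' Sample microvessel-density counts for the phantom regions
#'
#' Emulates the histology protocol: for each subregion, \code{nFields}
#' high-power fields are counted and their mean is the reported value. In
#' the PNA and VTA the field counts are drawn around
#' \code{slope * meanKtrans + intercept}; in the avascular CNA they are
#' drawn around \code{cnaRate}. Negative draws are truncated at zero.
#'
#' @param truth a \code{\linkS4class{PhantomTruth}}
#' @param link an \code{\link{mvdLink}}
#' @param nFields number of counted fields per region
#' @param seed seed for the field draws
#' @return data.frame with columns \code{region}, \code{mean_ktrans}
#'   (/min), \code{mvd} (vessels per field)
#' @export
sampleMVD <- function(truth, link = mvdLink(), nFields = 5L, seed = 1L) {
  stopifnot(nFields >= 1)
  regions <- c("CNA", "PNA", "VTA")
  withSeed(seed, {
    rows <- lapply(1:3, function(code) {
      idx <- which(truth@labels == code)
      if (!length(idx)) return(NULL)
      mk <- mean(truth@ktrans[idx])
      mu <- if (code == 1L) link$cnaRate else
        link$slope * mk + link$intercept
      fields <- pmax(0, stats::rnorm(nFields, mu, link$noiseSd))
      data.frame(region = regions[code], mean_ktrans = mk,
                 mvd = mean(fields))
    })
    do.call(rbind, rows)
  })
}

#' Simulate a cohort of tumors at the summary level
#'
#' Draws per-tumor, per-region mean pharmacokinetic parameters from
#' lognormal inter-subject distributions and attaches microvessel counts
#' through \code{\link{sampleMVD}}'s field-sampling rule, without rendering
#' images. This is the statistical backbone of the phantom: it reproduces
#' the between-tumor variability structure that the correlation analyses
#' operate on, at negligible cost, and is the tool for Monte-Carlo checks
#' of calibration and power.
#'
#' Default means and coefficients of variation are the column statistics
#' of the bundled tumor table.
#'
#' @param nTumors number of tumors
#' @param link an \code{\link{mvdLink}}
#' @param means per-region mean \code{ktrans}, \code{ve}, \code{vp}
#' @param interCV per-region between-tumor coefficients of variation
#' @param nFields counted fields per region
#' @param seed integer seed
#' @return data.frame with columns \code{tumor_id}, \code{region},
#'   \code{ktrans}, \code{ve}, \code{vp}, \code{mvd}
#' @examples
#' head(simulateCohort(seed = 7))
#' @export
simulateCohort <- function(nTumors = 15L, link = mvdLink(),
                           means = list(
                             ktrans = c(cna = 0.044, pna = 0.293,
                                        vta = 1.0),
                             ve = c(cna = 0.23, pna = 0.134, vta = 0.141),
                             vp = c(cna = 0.015, pna = 0.034,
                                    vta = 0.033)),
                           interCV = list(
                             ktrans = c(cna = 1.55, pna = 1.35,
                                        vta = 1.02),
                             ve = c(cna = 0.92, pna = 0.62, vta = 0.53),
                             vp = c(cna = 1.32, pna = 0.98, vta = 0.84)),
                           nFields = 5L, seed = 1L) {
  regions <- c("CNA", "PNA", "VTA")
  withSeed(seed, {
    rows <- lapply(seq_len(nTumors), function(tid) {
      do.call(rbind, lapply(1:3, function(code) {
        kt <- rlnormMean(1, means$ktrans[code], interCV$ktrans[code])
        vev <- min(rlnormMean(1, means$ve[code], interCV$ve[code]), 0.9)
        vpv <- min(rlnormMean(1, means$vp[code], interCV$vp[code]),
                   0.999 - vev)
        mu <- if (code == 1L) link$cnaRate else
          link$slope * kt + link$intercept
        fields <- pmax(0, stats::rnorm(nFields, mu, link$noiseSd))
        data.frame(tumor_id = tid, region = regions[code], ktrans = kt,
                   ve = vev, vp = vpv, mvd = mean(fields))
      }))
    })
    do.call(rbind, rows)
  })
}

#' Simulate one full imaging study
#'
#' Convenience wrapper generating everything one study needs: the ground
#' truth, the ground-truth plasma input function, the VFA volumes, the
#' dynamic series and the microvessel counts, all from one seed.
#'
#' @param config a \code{\link{phantomConfig}}
#' @param acq an \code{\linkS4class{AcquisitionParams}}
#' @param noiseSd signal noise standard deviation
#' @param link an \code{\link{mvdLink}}
#' @param seed integer seed (sub-seeds are derived from it)
#' @return list with \code{truth}, \code{aif}, \code{vfa}, \code{dyn},
#'   \code{mvd}, \code{acq}
#' @export
simulatePhantomStudy <- function(config = phantomConfig(),
                                 acq = acquisitionParams(),
                                 noiseSd = 0, link = mvdLink(),
                                 seed = 1L) {
  seed <- as.integer(seed) %% 2000000000L
  truth <- makeGroundTruth(config, seed)
  times <- dynamicTimes(acq)
  cb <- simulateBloodCurve(config$aifPeak, times)
  aif <- aifCurve(bloodToPlasma(cb, acq@hct), times)
  vfa <- renderVFAImages(truth, acq, noiseSd, seed + 1L)
  dyn <- renderDynamicSeries(truth, aif, acq, noiseSd, seed + 2L)
  mvd <- sampleMVD(truth, link, seed = seed + 3L)
  list(truth = truth, aif = aif, vfa = vfa, dyn = dyn, mvd = mvd,
       acq = acq)
}
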