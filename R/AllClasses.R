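#' @import methods
NULL

#' Acquisition parameters for a spoiled gradient-echo DCE protocol
#'
#' Container for the sequence timing and contrast-agent constants that every
#' quantification stage needs: repetition/echo time, the precontrast
#' variable-flip-angle set, the dynamic flip angle, the dynamic sampling
#' interval and frame counts, the longitudinal relaxivity of the contrast
#' agent and the hematocrit used for the blood-to-plasma conversion.
#'
#' Defaults reproduce a coronal 3T liver protocol: TR/TE 2.3/4.5 ms,
#' precontrast flip angles 2/5/10/12 degrees, dynamic flip 12 degrees,
#' 2.4 s sampling, 120 dynamics of which the first 2 are baseline,
#' r1 = 4.39 /s/mM and Hct = 0.45.
#'
#' @slot tr repetition time, milliseconds
#' @slot te echo time, milliseconds (carried for provenance; not used by the
#'   T1-based conversion)
#' @slot flipAngles precontrast flip angles, degrees
#' @slot dynamicFlip flip angle of the dynamic series, degrees
#' @slot dt sampling interval of the dynamic series, seconds
#' @slot nDynamics number of dynamic frames
#' @slot nBaseline number of precontrast baseline frames
#' @slot r1 longitudinal relaxivity, per second per mM
#' @slot hct hematocrit fraction
#' @export
setClass("AcquisitionParams",
  representation(
    tr = "numeric", te = "numeric",
    flipAngles = "numeric", dynamicFlip = "numeric",
    dt = "numeric", nDynamics = "integer", nBaseline = "integer",
    r1 = "numeric", hct = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (object@tr <= 0) msg <- c(msg, "tr must be positive (ms)")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive (s)")
  if (object@nBaseline >= object@nDynamics)
    msg <- c(msg, "nBaseline must be smaller than nDynamics")
  if (any(object@flipAngles <= 0 | object@flipAngles > 90))
    msg <- c(msg, "flip angles must lie in (0, 90] degrees")
  if (object@dynamicFlip <= 0 || object@dynamicFlip > 90)
    msg <- c(msg, "dynamicFlip must lie in (0, 90] degrees")
  if (object@r1 <= 0) msg <- c(msg, "r1 must be positive")
  if (object@hct < 0 || object@hct >= 1)
    msg <- c(msg, "hct must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct acquisition parameters
#'
#' @param tr,te repetition and echo time in milliseconds
#' @param flipAngles precontrast flip angles in degrees
#' @param dynamicFlip dynamic-series flip angle in degrees
#' @param dt dynamic sampling interval in seconds
#' @param nDynamics,nBaseline total and baseline dynamic frame counts
#' @param r1 contrast-agent longitudinal relaxivity, /s/mM
#' @param hct hematocrit fraction
#' @return an \code{AcquisitionParams} object
#' @examples
#' acq <- acquisitionParams()
#' dynamicTimes(acq)[1:5]
#' @export
acquisitionParams <- function(tr = 2.3, te = 4.5,
                              flipAngles = c(2, 5, 10, 12),
                              dynamicFlip = 12,
                              dt = 2.4, nDynamics = 120L, nBaseline = 2L,
                              r1 = 4.39, hct = 0.45) {
  new("AcquisitionParams", tr = tr, te = te,
      flipAngles = as.numeric(flipAngles), dynamicFlip = dynamicFlip,
      dt = dt, nDynamics = as.integer(nDynamics),
      nBaseline = as.integer(nBaseline), r1 = r1, hct = hct)
}

#' @describeIn acquisitionParams time grid (seconds) of the dynamic series,
#'   starting at 0
#' @param acq an \code{AcquisitionParams} object
#' @export
dynamicTimes <- function(acq) {
  (seq_len(acq@nDynamics) - 1L) * acq@dt
}

#' 4D dynamic signal-intensity series
#'
#' The raw input to quantification: one signal volume per dynamic frame,
#' with the time grid and the acquisition parameters it was acquired under.
#'
#' @slot signal 4D numeric array (x, y, z, t), arbitrary signal units
#' @slot times frame times in seconds, length \code{dim(signal)[4]}
#' @slot acq the \code{AcquisitionParams} of the acquisition
#' @export
setClass("DynamicSeries",
  representation(signal = "array", times = "numeric",
                 acq = "AcquisitionParams"))

setValidity("DynamicSeries", function(object) {
  d <- dim(object@signal)
  if (length(d) != 4L)
    return("signal must be a 4D array (x, y, z, t)")
  if (length(object@times) != d[4])
    return(sprintf("time grid length (%d) does not match frame count (%d)",
                   length(object@times), d[4]))
  if (d[4] != object@acq@nDynamics)
    return(sprintf(
      "series has %d frames but acquisition declares nDynamics = %d",
      d[4], object@acq@nDynamics))
  TRUE
})

#' @rdname DynamicSeries-class
#' @param signal 4D array of signal intensities
#' @param acq an \code{AcquisitionParams}; its frame count must match
#' @param times optional explicit time grid (seconds)
#' @export
dynamicSeries <- function(signal, acq, times = NULL) {
  if (is.null(times)) times <- (seq_len(dim(signal)[4]) - 1L) * acq@dt
  new("DynamicSeries", signal = signal, times = times, acq = acq)
}

#' Precontrast relaxometry maps
#'
#' Per-voxel equilibrium signal S0 and precontrast longitudinal relaxation
#' time T10 estimated from the variable-flip-angle images, with a mask of
#' voxels where the fit succeeded.
#'
#' @slot t10 T10 map, seconds
#' @slot s0 equilibrium-signal map, signal units
#' @slot ok logical array, TRUE where the fit is valid
#' @export
setClass("T1MapSet",
  representation(t10 = "array", s0 = "array", ok = "array"))

setValidity("T1MapSet", function(object) {
  if (!identical(dim(object@t10), dim(object@s0)) ||
      !identical(dim(object@t10), dim(object@ok)))
    return("t10, s0 and ok must share dimensions")
  okv <- object@ok & !is.na(object@ok)
  if (any(object@t10[okv] <= 0, na.rm = TRUE))
    return("t10 must be positive where the fit mask is TRUE")
  if (any(object@s0[okv] <= 0, na.rm = TRUE))
    return("s0 must be positive where the fit mask is TRUE")
  TRUE
})

#' Contrast-agent concentration time series
#'
#' @slot conc 4D array (x, y, z, t) of tissue concentration, mM. Values may
#'   be slightly negative under noise; they are deliberately not clipped.
#' @slot times frame times, seconds (uniform grid)
#' @slot nBaseline number of precontrast frames
#' @export
setClass("ConcentrationSeries",
  representation(conc = "array", times = "numeric", nBaseline = "integer"))

setValidity("ConcentrationSeries", function(object) {
  d <- dim(object@conc)
  if (length(d) != 4L) return("conc must be a 4D array")
  if (length(object@times) != d[4])
    return("time grid length does not match frame count")
  if (length(object@times) > 1) {
    dt <- diff(object@times)
    if (any(abs(dt - dt[1]) > 1e-6 * dt[1]))
      return("time grid must be uniform")
  }
  if (object@nBaseline >= d[4])
    return("nBaseline must be smaller than the frame count")
  TRUE
})

concentrationSeriesObj <- function(conc, times, nBaseline) {
  new("ConcentrationSeries", conc = conc, times = times,
      nBaseline = as.integer(nBaseline))
}

#' Arterial input function
#'
#' Plasma concentration-time curve Cp(t) driving the kinetic model, with the
#' voxels it was averaged from and simple curve-shape quality metrics
#' (peak height, time to peak, full width at half maximum).
#'
#' @slot cp plasma concentration per frame, mM
#' @slot times frame times, seconds
#' @slot sourceVoxels linear voxel indices the curve was averaged from
#'   (empty for synthetic input functions)
#' @slot peak peak height, mM
#' @slot ttp time to peak, seconds
#' @slot fwhm full width at half maximum of the first pass, seconds
#' @export
setClass("AIF",
  representation(cp = "numeric", times = "numeric",
                 sourceVoxels = "integer",
                 peak = "numeric", ttp = "numeric", fwhm = "numeric"))

setValidity("AIF", function(object) {
  if (length(object@cp) != length(object@times))
    return("cp and times must have equal length")
  if (!all(is.finite(object@cp))) return("cp must be finite")
  if (length(object@cp) && max(object@cp) <= 0)
    return("peak plasma concentration must be positive")
  TRUE
})

#' @rdname AIF-class
#' @param cp plasma concentration curve, mM
#' @param times time grid, seconds
#' @param sourceVoxels linear indices of contributing voxels
#' @export
aifCurve <- function(cp, times, sourceVoxels = integer()) {
  m <- curveShapeMetrics(cp, times)
  new("AIF", cp = as.numeric(cp), times = as.numeric(times),
      sourceVoxels = as.integer(sourceVoxels),
      peak = m["peak"], ttp = m["ttp"], fwhm = m["fwhm"])
}

#' Digital phantom ground truth
#'
#' Voxel-wise ground-truth parameter maps plus the anatomy labels of the
#' synthetic acquisition: an ablated tumor (necrotic core CNA, partial
#' necrotic ring PNA, viable rim VTA) embedded in liver, with a blood-pool
#' structure for input-function extraction.
#'
#' Label codes: 0 background, 1 CNA, 2 PNA, 3 VTA, 4 liver, 5 blood pool.
#'
#' @slot ktrans Ktrans map, /min
#' @slot ve,vp fractional volumes per voxel
#' @slot t10 precontrast T1 map, seconds
#' @slot s0 equilibrium signal map
#' @slot labels integer label array
#' @slot spacing voxel spacing, mm (x, y, z)
#' @slot config the phantom configuration list used to build the object
#' @export
setClass("PhantomTruth",
  representation(ktrans = "array", ve = "array", vp = "array",
                 t10 = "array", s0 = "array", labels = "array",
                 spacing = "numeric", config = "list"))

setValidity("PhantomTruth", function(object) {
  d <- dim(object@ktrans)
  for (sl in c("ve", "vp", "t10", "s0", "labels"))
    if (!identical(dim(slot(object, sl)), d))
      return(sprintf("map '%s' does not match the grid", sl))
  if (any(object@ve < 0 | object@vp < 0 | object@ve + object@vp > 1))
    return("ve, vp must be nonnegative with ve + vp <= 1 at every voxel")
  if (any(object@ktrans < 0)) return("ktrans must be nonnegative")
  if (any(object@ktrans[object@labels == 0L] != 0))
    return("ktrans must be zero on background")
  if (!all(object@labels %in% 0:5)) return("labels must be in 0..5")
  TRUE
})

#' Voxel-wise pharmacokinetic parameter maps
#'
#' Output of map fitting over an ROI: Ktrans, ve, vp and bolus-arrival delay
#' t0 maps, the residual sum of squares and a convergence mask. Voxels
#' outside the ROI carry \code{NA}.
#'
#' @slot ktrans Ktrans map, /min
#' @slot ve,vp fractional-volume maps
#' @slot t0 delay map, seconds
#' @slot rss residual sum of squares, mM^2
#' @slot converged logical array
#' @slot mask the ROI that was fitted
#' @export
setClass("ParameterMaps",
  representation(ktrans = "array", ve = "array", vp = "array",
                 t0 = "array", rss = "array", converged = "array",
                 mask = "array"))

setValidity("ParameterMaps", function(object) {
  d <- dim(object@ktrans)
  for (sl in c("ve", "vp", "t0", "rss", "converged", "mask"))
    if (!identical(dim(slot(object, sl)), d))
      return(sprintf("map '%s' does not match the grid", sl))
  if (any(!is.na(object@ktrans[!object@mask])))
    return("voxels outside the ROI must carry NA")
  TRUE
})

## ---- accessors ----

#' @export
setGeneric("ktransMap", function(x) standardGeneric("ktransMap"))
#' @export
setGeneric("veMap", function(x) standardGeneric("veMap"))
#' @export
setGeneric("vpMap", function(x) standardGeneric("vpMap"))
#' @export
setGeneric("t10Map", function(x) standardGeneric("t10Map"))
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname PhantomTruth-class
#' @param x object with a Ktrans map
#' @aliases ktransMap,PhantomTruth-method
setMethod("ktransMap", "PhantomTruth", function(x) x@ktrans)
#' @rdname PhantomTruth-class
setMethod("veMap", "PhantomTruth", function(x) x@ve)
#' @rdname PhantomTruth-class
setMethod("vpMap", "PhantomTruth", function(x) x@vp)
#' @rdname PhantomTruth-class
setMethod("t10Map", "PhantomTruth", function(x) x@t10)
#' @rdname PhantomTruth-class
setMethod("labelMap", "PhantomTruth", function(x) x@labels)

#' @rdname ParameterMaps-class
#' @param x object with a Ktrans map
#' @aliases ktransMap,ParameterMaps-method
setMethod("ktransMap", "ParameterMaps", function(x) x@ktrans)
#' @rdname ParameterMaps-class
setMethod("veMap", "ParameterMaps", function(x) x@ve)
#' @rdname ParameterMaps-class
setMethod("vpMap", "ParameterMaps", function(x) x@vp)
#' @rdname ParameterMaps-class
setMethod("t10Map", "T1MapSet", function(x) x@t10)

#' @export
setGeneric("s0Map", function(x) standardGeneric("s0Map"))
#' @rdname T1MapSet-class
#' @param x a \code{T1MapSet} or \code{PhantomTruth}
#' @aliases s0Map,T1MapSet-method
setMethod("s0Map", "T1MapSet", function(x) x@s0)
#' @rdname PhantomTruth-class
setMethod("s0Map", "PhantomTruth", function(x) x@s0)

#' @export
setGeneric("fitMask", function(x) standardGeneric("fitMask"))
#' @rdname T1MapSet-class
#' @aliases fitMask,T1MapSet-method
setMethod("fitMask", "T1MapSet", function(x) x@ok)

#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))
#' @rdname DynamicSeries-class
#' @param x an object carrying a time grid
#' @aliases timeGrid,DynamicSeries-method
setMethod("timeGrid", "DynamicSeries", function(x) x@times)
#' @rdname ConcentrationSeries-class
setMethod("timeGrid", "ConcentrationSeries", function(x) x@times)
#' @rdname AIF-class
setMethod("timeGrid", "AIF", function(x) x@times)

#' @export
setGeneric("concArray", function(x) standardGeneric("concArray"))
#' @rdname ConcentrationSeries-class
#' @param x a \code{ConcentrationSeries}
#' @aliases concArray,ConcentrationSeries-method
setMethod("concArray", "ConcentrationSeries", function(x) x@conc)

#' @export
setGeneric("signalArray", function(x) standardGeneric("signalArray"))
#' @rdname DynamicSeries-class
#' @aliases signalArray,DynamicSeries-method
setMethod("signalArray", "DynamicSeries", function(x) x@signal)

#' @export
setGeneric("plasmaCurve", function(x) standardGeneric("plasmaCurve"))
#' @rdname AIF-class
#' @param x an \code{AIF}
#' @aliases plasmaCurve,AIF-method
setMethod("plasmaCurve", "AIF", function(x) x@cp)

#' @export
setGeneric("aifQuality", function(x) standardGeneric("aifQuality"))
#' @rdname AIF-class
#' @aliases aifQuality,AIF-method
setMethod("aifQuality", "AIF", function(x)
  c(peak = x@peak, ttp = x@ttp, fwhm = x@fwhm))

## ---- show methods ----

setMethod("show", "AcquisitionParams", function(object) {
  cat("AcquisitionParams\n")
  cat(sprintf("  TR/TE: %.2f/%.2f ms, dynamic flip %g deg\n",
              object@tr, object@te, object@dynamicFlip))
  cat(sprintf("  VFA angles: %s deg\n",
              paste(object@flipAngles, collapse = ", ")))
  cat(sprintf("  %d dynamics (%d baseline) at dt = %.2f s\n",
              object@nDynamics, object@nBaseline, object@dt))
  cat(sprintf("  r1 = %.2f /s/mM, Hct = %.2f\n", object@r1, object@hct))
})

setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@signal)
  cat(sprintf("DynamicSeries: %d x %d x %d voxels, %d frames (dt %.2f s)\n",
              d[1], d[2], d[3], d[4], object@acq@dt))
})

setMethod("show", "ConcentrationSeries", function(object) {
  d <- dim(object@conc)
  cat(sprintf(
    "ConcentrationSeries: %d x %d x %d voxels, %d frames, %d baseline\n",
    d[1], d[2], d[3], d[4], object@nBaseline))
})

setMethod("show", "AIF", function(object) {
  cat(sprintf(
    "AIF: %d frames; peak %.3g mM at %.1f s, FWHM %.1f s (%d source voxels)\n",
    length(object@cp), object@peak, object@ttp, object@fwhm,
    length(object@sourceVoxels)))
})

setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@ktrans)
  n <- tabulate(object@labels + 1L, nbins = 6L)
  cat(sprintf("PhantomTruth: %d x %d x %d grid (%.2g x %.2g x %.2g mm)\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  voxels: %d CNA, %d PNA, %d VTA, %d liver, %d blood\n",
              n[2], n[3], n[4], n[5], n[6]))
})

setMethod("show", "T1MapSet", function(object) {
  d <- dim(object@t10)
  cat(sprintf("T1MapSet: %d x %d x %d; %d voxels fit ok\n",
              d[1], d[2], d[3], sum(object@ok)))
})

setMethod("show", "ParameterMaps", function(object) {
  d <- dim(object@ktrans)
  nf <- sum(object@mask)
  cat(sprintf("ParameterMaps: %d x %d x %d; %d ROI voxels, %d converged\n",
              d[1], d[2], d[3], nf, sum(object@converged, na.rm = TRUE)))
  if (nf) {
    k <- object@ktrans[object@mask]
    cat(sprintf("  Ktrans [/min]: median %.3g (range %.3g-%.3g)\n",
                stats::median(k, na.rm = TRUE),
                min(k, na.rm = TRUE), max(k, na.rm = TRUE)))
  }
})
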