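## Arterial input function selection and extraction. Manual visual
## selection of blood-pool voxels ("high peak, narrow shape, quick wash-in
## and wash-out") is made operational as a deterministic curve-shape score;
## an explicit voxel list remains available as the operator-driven mode.

#' Curve-shape quality metrics
#'
#' Peak height, time to peak and full width at half maximum of a
#' concentration-time curve. The half-maximum crossings are located by
#' linear interpolation between frames, which matters when the sampling
#' interval is coarse relative to the bolus width. If the curve never falls
#' back below half maximum, the last time point is used as the right edge.
#'
#' @param curve concentration curve, mM
#' @param times time grid, seconds
#' @return named vector with \code{peak} (mM), \code{ttp} (s), \code{fwhm}
#'   (s)
#' @export
curveShapeMetrics <- function(curve, times) {
  ipk <- which.max(curve)
  peak <- curve[ipk]
  if (!is.finite(peak) || peak <= 0)
    return(c(peak = if (is.finite(peak)) peak else NA_real_,
             ttp = NA_real_, fwhm = NA_real_))
  half <- peak / 2
  crossLeft <- function() {
    if (ipk == 1L) return(times[1])
    for (i in seq(ipk - 1L, 1L)) {
      if (curve[i] <= half) {
        return(times[i] + (half - curve[i]) /
                 (curve[i + 1L] - curve[i]) * (times[i + 1L] - times[i]))
      }
    }
    times[1]
  }
  crossRight <- function() {
    n <- length(curve)
    if (ipk == n) return(times[n])
    for (i in seq(ipk + 1L, n)) {
      if (curve[i] <= half) {
        return(times[i - 1L] + (curve[i - 1L] - half) /
                 (curve[i - 1L] - curve[i]) * (times[i] - times[i - 1L]))
      }
    }
    times[n]
  }
  c(peak = peak, ttp = times[ipk], fwhm = crossRight() - crossLeft())
}

#' Rank candidate input-function voxels by curve shape
#'
#' Scores every voxel in the search mask by
#' \code{peak / (ttp * fwhm)}: a tall, early, narrow bolus scores high.
#' Candidates are returned in descending score order; exact ties are broken
#' by ascending linear voxel index, so the ranking is deterministic.
#' Voxels without a positive peak are dropped (an empty result raises a
#' warning).
#'
#' @param conc a \code{\linkS4class{ConcentrationSeries}}
#' @param searchMask logical array of voxels to consider
#' @return data.frame with columns \code{voxel} (linear index),
#'   \code{peak}, \code{ttp}, \code{fwhm}, \code{score}, ranked
#' @export
scoreAIFCandidates <- function(conc, searchMask) {
  d <- dim(conc@conc)[1:3]
  stopifnot(identical(dim(searchMask), d))
  idx <- which(searchMask)
  if (!length(idx)) stop("search mask is empty")
  nt <- dim(conc@conc)[4]
  sig <- matrix(conc@conc, prod(d), nt)
  rows <- lapply(idx, function(i) {
    cv <- sig[i, ]
    if (!all(is.finite(cv))) return(NULL)
    m <- curveShapeMetrics(cv, conc@times)
    if (!is.finite(m["peak"]) || m["peak"] <= 0) return(NULL)
    data.frame(voxel = i, peak = m[["peak"]], ttp = m[["ttp"]],
               fwhm = m[["fwhm"]])
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) {
    warning("no enhancing voxel in the search mask")
    return(data.frame(voxel = integer(), peak = numeric(),
                      ttp = numeric(), fwhm = numeric(),
                      score = numeric()))
  }
  denom <- rows$ttp * rows$fwhm
  rows$score <- ifelse(denom > 0, rows$peak / denom, -Inf)
  rows[order(-rows$score, rows$voxel), , drop = FALSE]
}

#' Extract an arterial input function from selected voxels
#'
#' Averages the whole-blood concentration curves of the selected voxels
#' (duplicates are collapsed first), applies the hematocrit correction via
#' \code{\link{bloodToPlasma}}, and recomputes the shape metrics on the
#' plasma curve.
#'
#' @param conc a \code{\linkS4class{ConcentrationSeries}}
#' @param voxels linear voxel indices (e.g. the top-k of
#'   \code{\link{scoreAIFCandidates}}), or an n x 3 index matrix
#' @param hct hematocrit fraction
#' @param convention hematocrit convention, see \code{\link{bloodToPlasma}}
#' @return an \code{\linkS4class{AIF}}
#' @export
extractAIF <- function(conc, voxels, hct = 0.45,
                       convention = c("divide", "multiply")) {
  convention <- match.arg(convention)
  d <- dim(conc@conc)[1:3]
  if (is.matrix(voxels)) {
    stopifnot(ncol(voxels) == 3)
    voxels <- voxels[, 1] + (voxels[, 2] - 1L) * d[1] +
      (voxels[, 3] - 1L) * d[1] * d[2]
  }
  voxels <- unique(as.integer(voxels))
  if (!length(voxels)) stop("at least one voxel is required")
  if (any(voxels < 1L | voxels > prod(d)))
    stop("voxel indices outside the volume")
  nt <- dim(conc@conc)[4]
  sig <- matrix(conc@conc, prod(d), nt)[voxels, , drop = FALSE]
  cb <- colMeans(sig)
  if (any(!is.finite(cb)))
    stop("selected voxels contain invalid concentration values")
  cp <- bloodToPlasma(cb, hct, convention)
  aifCurve(cp, conc@times, sourceVoxels = voxels)
}
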