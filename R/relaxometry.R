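## Variable flip angle relaxometry: the SPGR signal model, its linearized
## VFA inversion for (S0, T10), and the single-angle inversion used to turn
## the dynamic series into a T1 time series.

#' Spoiled gradient-echo signal model
#'
#' \eqn{S = S_0 \sin\alpha (1 - E_1) / (1 - E_1 \cos\alpha)} with
#' \eqn{E_1 = \exp(-TR/T_1)}. This is the forward model underlying both the
#' variable-flip-angle T10 fit and the dynamic signal-to-T1 inversion.
#'
#' @param s0 equilibrium signal (arbitrary units); absorbs proton density,
#'   coil sensitivity and receiver gain
#' @param t1 longitudinal relaxation time, seconds
#' @param alpha flip angle, degrees
#' @param tr repetition time, milliseconds
#' @return signal in the units of \code{s0}; vectorized over all arguments
#' @examples
#' spgrSignal(1000, 1.0, 12, 2.3)
#' @export
spgrSignal <- function(s0, t1, alpha, tr) {
  stopifnot(all(tr > 0), all(alpha >= 0), all(alpha <= 90))
  a <- alpha * pi / 180
  e1 <- exp(-(tr / 1000) / t1)
  s0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Variable flip angle fit of S0 and T10 for one voxel
#'
#' Linearizes the SPGR equation as \eqn{S/\sin\alpha = E_1 \, S/\tan\alpha +
#' S_0 (1 - E_1)} and solves by ordinary least squares. A physically valid
#' voxel yields a slope in (0, 1), giving \eqn{T_{10} = -TR/\log(\mathrm{slope})}.
#' Degenerate inputs (all-zero signals, slope outside (0, 1), nonpositive
#' intercept) are flagged rather than propagating NaN.
#'
#' @param signals signal at each flip angle
#' @param angles flip angles, degrees (>= 2 distinct values)
#' @param tr repetition time, milliseconds
#' @return list with \code{s0}, \code{t10} (seconds) and logical \code{ok}
#' @examples
#' s <- spgrSignal(1000, 0.9, c(2, 5, 10, 12), 2.3)
#' fitVFA(s, c(2, 5, 10, 12), 2.3)
#' @export
fitVFA <- function(signals, angles, tr) {
  stopifnot(length(signals) == length(angles),
            length(unique(angles)) >= 2, tr > 0)
  bad <- list(s0 = NA_real_, t10 = NA_real_, ok = FALSE)
  if (!all(is.finite(signals)) || all(signals == 0)) return(bad)
  a <- angles * pi / 180
  y <- signals / sin(a)
  x <- signals / tan(a)
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) return(bad)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  if (!is.finite(slope) || slope <= 0 || slope >= 1 || intercept <= 0)
    return(bad)
  t10 <- -(tr / 1000) / log(slope)
  s0 <- intercept / (1 - slope)
  list(s0 = s0, t10 = t10, ok = TRUE)
}

#' Variable flip angle fit over a volume
#'
#' Vectorized version of \code{\link{fitVFA}} applied independently to every
#' voxel of a set of per-angle volumes.
#'
#' @param vfa list of 3D arrays, one per flip angle, identical dimensions
#' @param angles flip angles, degrees, matching \code{vfa}
#' @param tr repetition time, milliseconds
#' @param mask optional logical array restricting the fit; voxels outside
#'   are flagged not-ok
#' @return a \code{\linkS4class{T1MapSet}}
#' @export
fitVFAMap <- function(vfa, angles, tr, mask = NULL) {
  stopifnot(is.list(vfa), length(vfa) == length(angles),
            length(unique(angles)) >= 2, tr > 0)
  d <- dim(vfa[[1]])
  for (v in vfa) stopifnot(identical(dim(v), d))
  nvox <- prod(d)
  S <- vapply(vfa, as.numeric, numeric(nvox))   # nvox x nAngles
  a <- matrix(angles * pi / 180, nvox, length(angles), byrow = TRUE)
  y <- S / sin(a)
  x <- S / tan(a)
  n <- length(angles)
  mx <- rowMeans(x); my <- rowMeans(y)
  sxx <- rowSums((x - mx)^2)
  sxy <- rowSums((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  ok <- is.finite(slope) & slope > 0 & slope < 1 & intercept > 0
  if (!is.null(mask)) ok <- ok & as.logical(mask)
  t10 <- rep(NA_real_, nvox); s0 <- rep(NA_real_, nvox)
  t10[ok] <- -(tr / 1000) / log(slope[ok])
  s0[ok] <- intercept[ok] / (1 - slope[ok])
  new("T1MapSet",
      t10 = array(t10, d), s0 = array(s0, d), ok = array(ok, d))
}

#' Invert the SPGR equation for T1 at a known S0
#'
#' Solves \eqn{S = S_0 \sin\alpha (1 - E_1)/(1 - E_1\cos\alpha)} for
#' \eqn{E_1} and returns \eqn{T_1 = -TR/\log E_1}. The attainable signal at
#' fixed \code{(s0, alpha)} is bounded above by \eqn{S_0 \sin\alpha}
#' (the \eqn{T_1 \to 0} limit); signals at or above that bound are clamped
#' to \code{t1Floor} and flagged, and nonpositive signals are clamped to
#' \code{t1Ceiling} and flagged, so a single out-of-domain voxel cannot
#' abort a map.
#'
#' @param signal observed signal
#' @param s0 equilibrium signal from the VFA fit
#' @param alpha flip angle, degrees
#' @param tr repetition time, milliseconds
#' @param t1Floor,t1Ceiling clamp values, seconds
#' @return list with \code{t1} (seconds) and logical \code{ok}; vectorized
#' @examples
#' s <- spgrSignal(1000, 1.0, 12, 2.3)
#' t1FromSignal(s, 1000, 12, 2.3)$t1   # 1.0
#' @export
t1FromSignal <- function(signal, s0, alpha, tr,
                         t1Floor = 1e-3, t1Ceiling = 20) {
  stopifnot(all(s0 > 0, na.rm = TRUE), tr > 0, alpha > 0, alpha <= 90)
  a <- alpha * pi / 180
  e1 <- (s0 * sin(a) - signal) / (s0 * sin(a) - signal * cos(a))
  e1safe <- ifelse(is.finite(e1) & e1 > 0 & e1 < 1, e1, NA_real_)
  t1 <- -(tr / 1000) / log(e1safe)
  ok <- is.finite(e1) & e1 > 0 & e1 < 1 & signal > 0
  t1[!ok] <- NA_real_
  ## signal >= SPGR ceiling -> T1 below any physical value: clamp low
  hi <- is.finite(e1) & e1 <= 0
  t1[hi] <- t1Floor
  ## nonpositive signal -> T1 unbounded: clamp high
  lo <- !is.na(signal) & signal <= 0
  t1[lo] <- t1Ceiling
  ok[hi | lo] <- FALSE
  list(t1 = t1, ok = ok)
}

#' T1 time series from a dynamic acquisition
#'
#' Applies \code{\link{t1FromSignal}} frame by frame to the dynamic series,
#' using the S0 map from the precontrast VFA fit and the dynamic flip angle.
#'
#' @param dyn a \code{\linkS4class{DynamicSeries}}
#' @param t1set a \code{\linkS4class{T1MapSet}} from \code{\link{fitVFAMap}}
#' @param mask optional logical array; voxels outside are skipped
#' @return list with \code{t1} (4D array, seconds) and \code{ok}
#'   (4D logical)
#' @export
dynamicT1Series <- function(dyn, t1set, mask = NULL) {
  d <- dim(dyn@signal)
  stopifnot(identical(dim(t1set@t10), d[1:3]))
  if (is.null(mask)) mask <- t1set@ok else mask <- mask & t1set@ok
  idx <- which(mask)
  nt <- d[4]
  t1 <- array(NA_real_, d)
  ok <- array(FALSE, d)
  sig <- matrix(dyn@signal, prod(d[1:3]), nt)[idx, , drop = FALSE]
  res <- t1FromSignal(sig, t1set@s0[idx], dyn@acq@dynamicFlip, dyn@acq@tr)
  nvol <- prod(d[1:3])
  for (k in seq_len(nt)) {
    t1[idx + (k - 1L) * nvol] <- res$t1[, k]
    ok[idx + (k - 1L) * nvol] <- res$ok[, k]
  }
  list(t1 = t1, ok = ok)
}
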