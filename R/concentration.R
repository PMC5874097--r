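## Signal-derived T1 to contrast-agent concentration, and the hematocrit
## correction from whole-blood to plasma concentration.

#' Concentration from longitudinal relaxation change
#'
#' \eqn{C(t) = (1/T_1(t) - 1/T_{10}) / r_1}: the contrast agent shortens T1
#' in proportion to its concentration. Values may be slightly negative under
#' noise; they are passed through unclipped so that least-squares fitting
#' stays unbiased (a symmetric noise model is assumed downstream).
#'
#' @param t1 T1 at each time point, seconds (voxel-by-frame matrix allowed)
#' @param t10 precontrast T1, seconds
#' @param r1 longitudinal relaxivity, per second per mM (the same value is
#'   applied to blood and tissue)
#' @return concentration in mM, same shape as \code{t1}; \code{NA} where T1
#'   is nonpositive or missing
#' @examples
#' concentrationFromT1(0.25, 1.0, 4.39)  # 3/4.39 mM
#' @export
concentrationFromT1 <- function(t1, t10, r1 = 4.39) {
  stopifnot(r1 > 0, all(t10 > 0, na.rm = TRUE))
  bad <- !is.na(t1) & t1 <= 0
  t1[bad] <- NA_real_
  (1 / t1 - 1 / t10) / r1
}

#' Whole-blood to plasma concentration
#'
#' The contrast agent distributes in plasma only, so a whole-blood
#' concentration measured in a vessel underestimates the plasma
#' concentration by the red-cell volume fraction: \eqn{C_p = C_b/(1 -
#' \mathrm{Hct})}. A \code{"multiply"} convention
#' (\eqn{C_p = C_b (1 - \mathrm{Hct})}) is retained as an option for
#' comparison with analyses that used the rescaled form; because the
#' conversion is a global scale factor on the input function it rescales
#' Ktrans and vp uniformly and leaves correlation analyses unchanged.
#'
#' @param cb whole-blood concentration, mM
#' @param hct hematocrit fraction in [0, 1)
#' @param convention \code{"divide"} (physical, default) or
#'   \code{"multiply"}
#' @return plasma concentration, mM
#' @examples
#' bloodToPlasma(1, 0.45)  # 1.818 mM
#' @export
bloodToPlasma <- function(cb, hct, convention = c("divide", "multiply")) {
  convention <- match.arg(convention)
  if (hct < 0 || hct >= 1) stop("hct must lie in [0, 1)")
  if (convention == "divide") cb / (1 - hct) else cb * (1 - hct)
}

#' Concentration time series from a dynamic acquisition
#'
#' Full signal-to-concentration conversion: per-frame SPGR inversion of the
#' dynamic series against the precontrast (S0, T10) maps, then the
#' relaxation-rate difference scaled by the relaxivity.
#'
#' @param dyn a \code{\linkS4class{DynamicSeries}}
#' @param t1set a \code{\linkS4class{T1MapSet}}
#' @param mask optional logical array restricting the conversion
#' @return a \code{\linkS4class{ConcentrationSeries}}; voxels outside the
#'   mask (or with failed relaxometry) are \code{NA}
#' @export
concentrationSeries <- function(dyn, t1set, mask = NULL) {
  ts <- dynamicT1Series(dyn, t1set, mask)
  d <- dim(dyn@signal)
  idx <- rep(TRUE, prod(d[1:3]))
  conc <- array(NA_real_, d)
  valid <- !is.na(ts$t1)
  t10rep <- array(rep(t1set@t10, d[4]), d)
  conc[valid] <- (1 / ts$t1[valid] - 1 / t10rep[valid]) / dyn@acq@r1
  concentrationSeriesObj(conc, dyn@times, dyn@acq@nBaseline)
}
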