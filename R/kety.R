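## Extended Kety (extended Tofts) two-compartment model: forward simulation
## of the tissue concentration curve and bounded nonlinear least-squares
## fitting of (Ktrans, ve, vp, t0), voxel-wise over an ROI.

#' Parameter tuple for the extended Kety model
#'
#' @param ktrans volume transfer constant, /min
#' @param ve fractional extravascular extracellular space (0..1)
#' @param vp fractional plasma volume (0..1)
#' @param t0 bolus-arrival delay between the arterial input and the tissue
#'   curve, seconds
#' @return a named list with class \code{"KetyParams"}
#' @export
ketyParams <- function(ktrans, ve, vp, t0 = 0) {
  stopifnot(ktrans >= 0, ve >= 0, ve <= 1, vp >= 0, vp <= 1, t0 >= 0)
  if (ktrans > 0 && ve <= 0)
    stop("ktrans > 0 with ve = 0: the efflux rate constant is undefined")
  structure(list(ktrans = ktrans, ve = ve, vp = vp, t0 = t0),
            class = "KetyParams")
}

## Causal convolution of cp with exp(-kep * t) by trapezoidal quadrature,
## computed by the exact O(n) recursion for an exponential kernel:
##   I[k] = I[k-1] e^{-kep dt} + dt/2 (cp[k] + cp[k-1] e^{-kep dt})
## which reproduces the trapezoid rule applied to the convolution integral.
expConvolve <- function(cp, dt, kep) {
  n <- length(cp)
  out <- numeric(n)
  if (n < 2) return(out)
  e <- exp(-kep * dt)
  acc <- 0
  for (k in 2:n) {
    acc <- acc * e + dt / 2 * (cp[k] + cp[k - 1] * e)
    out[k] <- acc
  }
  out
}

## Delay a curve by t0 seconds via linear interpolation on its own grid;
## zero before the grid start (causal input, Cp(0) = 0).
delayCurve <- function(cp, times, t0) {
  if (t0 == 0) return(cp)
  stats::approx(times, cp, xout = times - t0, yleft = 0,
                rule = 2)$y
}

#' Forward extended Kety model
#'
#' \eqn{C_t(t) = v_p C_p(t - t_0) + K^{trans} \int_0^t C_p(\tau - t_0)
#' e^{-(K^{trans}/v_e)(t - \tau)} d\tau}. The delay is applied by linear
#' interpolation of the input function (sub-frame delays allowed) and the
#' convolution is evaluated by trapezoidal quadrature on the uniform
#' acquisition grid. Rate constants are in /min; the time grid is in
#' seconds.
#'
#' @param params a \code{\link{ketyParams}} tuple (or a named list with
#'   \code{ktrans}, \code{ve}, \code{vp}, \code{t0})
#' @param aif an \code{\linkS4class{AIF}} on a uniform time grid
#' @return tissue concentration on the AIF grid, mM
#' @examples
#' acq <- acquisitionParams()
#' tg <- dynamicTimes(acq)
#' aif <- aifCurve(simulateBloodCurve(5, tg) / (1 - 0.45), tg)
#' ct <- ketyForward(ketyParams(0.45, 0.084, 0.0237, 4.8), aif)
#' @export
ketyForward <- function(params, aif) {
  times <- aif@times
  dt <- times[2] - times[1]
  if (params$ktrans > 0 && params$ve <= 0)
    stop("ktrans > 0 with ve = 0: the efflux rate constant is undefined")
  cpd <- delayCurve(aif@cp, times, params$t0)
  ct <- params$vp * cpd
  if (params$ktrans > 0) {
    kep <- (params$ktrans / params$ve) / 60    # /s
    ct <- ct + (params$ktrans / 60) * expConvolve(cpd, dt, kep)
  }
  ct
}

## crude bolus-delay estimate: difference between the first times the
## tissue curve and the input function exceed 10% of their own maxima;
## used only to seed the optimizer with a plausible t0
estimateBolusDelay <- function(ct, aif) {
  arrival <- function(x) {
    thr <- 0.1 * max(x)
    if (thr <= 0) return(NA_real_)
    aif@times[which(x > thr)[1]]
  }
  d <- arrival(ct) - arrival(aif@cp)
  if (!is.finite(d)) 0 else min(max(d, 0), 30)
}

## residuals for the least-squares fit; theta = (ktrans, ve, vp, t0)
ketyResiduals <- function(theta, ct, aif) {
  p <- list(ktrans = theta[1], ve = max(theta[2], 1e-8),
            vp = theta[3], t0 = theta[4])
  ct - ketyForward(p, aif)
}

#' Fit the extended Kety model to one voxel
#'
#' Bounded Levenberg-Marquardt least squares on (Ktrans, ve, vp, t0). The
#' fit is deterministic given the data and the initial value. An all-zero
#' curve converges to Ktrans = 0, vp = 0 and is not an error. When the
#' fitted Ktrans lies on the zero bound, ve is unidentifiable; it is
#' reported as \code{NA} with \code{veIdentifiable = FALSE} (common in
#' fully necrotic tissue).
#'
#' @param ct tissue concentration curve, mM, on the AIF time grid
#' @param aif an \code{\linkS4class{AIF}}
#' @param init initial parameter tuple
#' @param lower,upper parameter bounds in the order
#'   (ktrans, ve, vp, t0); defaults bracket the physiological range:
#'   Ktrans in [0, 10] /min, ve in [1e-6, 1], vp in [0, 1], t0 in [0, 30] s
#' @param multistart if \code{TRUE}, additionally restart from Ktrans =
#'   0.05, 0.5 and 2 /min with a data-driven bolus-delay seed and keep
#'   the lowest residual sum of squares (recommended for map fitting,
#'   where single-start fits can stall in a delay/vp local minimum at
#'   high Ktrans)
#' @return list with \code{params} (a \code{KetyParams}), \code{rss},
#'   \code{nIter}, \code{converged}, \code{veIdentifiable}
#' @examples
#' acq <- acquisitionParams()
#' tg <- dynamicTimes(acq)
#' aif <- aifCurve(simulateBloodCurve(5, tg) / 0.55, tg)
#' ct <- ketyForward(ketyParams(0.45, 0.084, 0.0237, 4.8), aif)
#' fitKetyVoxel(ct, aif)$params
#' @export
fitKetyVoxel <- function(ct, aif,
                         init = ketyParams(0.1, 0.2, 0.02, 0),
                         lower = c(0, 1e-6, 0, 0),
                         upper = c(10, 1, 1, 30),
                         multistart = FALSE) {
  if (length(ct) != length(aif@cp))
    stop("tissue curve and AIF must share the time grid")
  if (!all(is.finite(ct)))
    return(list(params = NULL, rss = NA_real_, nIter = 0L,
                converged = FALSE, veIdentifiable = FALSE))
  if (all(ct == 0)) {
    p <- structure(list(ktrans = 0, ve = NA_real_, vp = 0, t0 = init$t0),
                   class = "KetyParams")
    return(list(params = p, rss = 0, nIter = 0L, converged = TRUE,
                veIdentifiable = FALSE))
  }
  starts <- list(c(init$ktrans, init$ve, init$vp, init$t0))
  if (multistart) {
    t0hat <- estimateBolusDelay(ct, aif)
    starts <- c(starts, lapply(c(init$ktrans, 0.05, 0.5, 2), function(k)
      c(k, init$ve, init$vp, t0hat)))
  }
  best <- NULL
  for (th0 in starts) {
    fit <- minpack.lm::nls.lm(
      par = pmin(pmax(th0, lower), upper),
      lower = lower, upper = upper,
      fn = ketyResiduals, ct = ct, aif = aif,
      control = minpack.lm::nls.lm.control(
        maxiter = 200, ftol = 1e-12, ptol = 1e-12))
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  th <- best$par
  veId <- th[1] > lower[1] + 1e-12
  p <- list(ktrans = th[1], ve = if (veId) th[2] else NA_real_,
            vp = th[3], t0 = th[4])
  class(p) <- "KetyParams"
  list(params = p, rss = best$deviance, nIter = best$niter,
       converged = best$info %in% 1:4, veIdentifiable = veId)
}

#' Voxel-wise extended Kety map fitting
#'
#' Applies \code{\link{fitKetyVoxel}} independently to every voxel of the
#' ROI. Voxel fits do not interact, so the result is independent of
#' processing order. Voxels outside the ROI carry \code{NA}.
#'
#' @param conc a \code{\linkS4class{ConcentrationSeries}}
#' @param aif an \code{\linkS4class{AIF}} on the same time grid
#' @param mask logical ROI array over the volume
#' @param init,lower,upper,multistart passed to \code{\link{fitKetyVoxel}}
#' @param verbose if \code{TRUE}, report the convergence rate
#' @return a \code{\linkS4class{ParameterMaps}} object
#' @export
fitKetyMap <- function(conc, aif, mask,
                       init = ketyParams(0.1, 0.2, 0.02, 0),
                       lower = c(0, 1e-6, 0, 0),
                       upper = c(10, 1, 1, 30),
                       multistart = FALSE, verbose = FALSE) {
  d <- dim(conc@conc)[1:3]
  stopifnot(identical(dim(mask), d))
  if (max(abs(conc@times - aif@times)) > 1e-9)
    stop("concentration series and AIF time grids differ")
  idx <- which(mask)
  if (!length(idx)) warning("empty ROI mask: returning empty maps")
  mk <- function() array(NA_real_, d)
  maps <- list(ktrans = mk(), ve = mk(), vp = mk(), t0 = mk(), rss = mk())
  conv <- array(FALSE, d)
  nt <- dim(conc@conc)[4]
  sig <- matrix(conc@conc, prod(d), nt)
  for (i in idx) {
    f <- fitKetyVoxel(sig[i, ], aif, init, lower, upper, multistart)
    if (is.null(f$params)) next
    maps$ktrans[i] <- f$params$ktrans
    maps$ve[i] <- f$params$ve
    maps$vp[i] <- f$params$vp
    maps$t0[i] <- f$params$t0
    maps$rss[i] <- f$rss
    conv[i] <- f$converged
  }
  if (verbose && length(idx))
    message(sprintf("fitKetyMap: %d/%d voxels converged (%.1f%%)",
                    sum(conv), length(idx), 100 * mean(conv[idx])))
  new("ParameterMaps", ktrans = maps$ktrans, ve = maps$ve, vp = maps$vp,
      t0 = maps$t0, rss = maps$rss, converged = conv,
      mask = array(as.logical(mask), d))
}
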