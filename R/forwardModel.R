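#' Construct DcmParameters
#'
#' @param a,bLow,bHigh n x n coupling matrices (Hz); the diagonal of \code{a}
#'   must be zero (self-decay is fixed inside the integrator).
#' @param c n x 2 driving matrix (Hz).
#' @param selfDecay positive self-decay magnitude (Hz, default 0.5); the
#'   effective intrinsic matrix is \code{a - selfDecay * I}.
#' @return A \linkS4class{DcmParameters}.
#' @export
dcmParameters <- function(a, bLow = 0 * a, bHigh = 0 * a,
                          c = matrix(0, nrow(a), 2L), selfDecay = 0.5) {
  new("DcmParameters", a = a, bLow = bLow, bHigh = bHigh, c = c,
      selfDecay = selfDecay)
}

#' Apply a mask to parameters
#'
#' Zeroes every entry outside the governing \linkS4class{MaskSet}.
#'
#' @param params a \linkS4class{DcmParameters}.
#' @param mask a \linkS4class{MaskSet}.
#' @return Masked \linkS4class{DcmParameters}.
#' @export
maskParameters <- function(params, mask) {
  new("DcmParameters",
      a = params@a * mask@aMask, bLow = params@bLow * mask@bMaskLow,
      bHigh = params@bHigh * mask@bMaskHigh, c = params@c * mask@cMask,
      selfDecay = params@selfDecay)
}

#' Default balloon-Windkessel constants
#'
#' Canonical values: signal decay kappa = 0.64 Hz, flow feedback gamma = 0.32
#' Hz, transit time tau = 2 s, stiffness alpha = 0.32, resting oxygen
#' extraction e0 = 0.4, resting blood volume v0 = 0.04, neuronal efficacy
#' epsilon = 1. Held fixed during estimation; epsilon may be a per-region
#' vector.
#'
#' @param kappa,gamma,tau,alpha,e0,v0,epsilon scalars (or per-region vectors).
#' @return Named list of hemodynamic constants.
#' @export
defaultHemoParams <- function(kappa = 0.64, gamma = 0.32, tau = 2.0,
                              alpha = 0.32, e0 = 0.4, v0 = 0.04,
                              epsilon = 1.0) {
  stopifnot(all(kappa > 0), all(gamma > 0), all(tau > 0),
            all(alpha > 0 & alpha < 1), all(e0 > 0 & e0 < 1), all(v0 > 0))
  list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha, e0 = e0,
       v0 = v0, epsilon = epsilon)
}

.hemoVectors <- function(hemo, n) {
  lapply(hemo, function(v) rep_len(as.numeric(v), n))
}

#' Integrate the bilinear neural state equation
#'
#' Advances dx/dt = (A - selfDecay*I + u1*Blow + u2*Bhigh) x + C u with
#' classical fixed-step RK4 at dt = TR / microtimeBins, inputs piecewise
#' constant over each microtime bin, from x(0) = \code{x0} (zero by default).
#'
#' @param params a \linkS4class{DcmParameters} (mask already applied, or pass
#'   \code{mask}).
#' @param design a \linkS4class{TaskDesign}.
#' @param mask optional \linkS4class{MaskSet} applied to \code{params} first.
#' @param x0 initial state (default zeros).
#' @return n x T matrix of neuronal activity on the microtime grid.
#' @export
integrateNeural <- function(params, design, mask = NULL, x0 = NULL) {
  if (!is.null(mask)) params <- maskParameters(params, mask)
  n <- nrow(params@a)
  if (is.null(x0)) x0 <- numeric(n)
  dt <- design@tr / design@microtimeBins
  aEff <- params@a - diag(params@selfDecay, n)
  .integrate_neural_cpp(aEff, params@bLow, params@bHigh, params@c,
                        design@u, dt, x0)
}

#' Balloon-Windkessel hemodynamics
#'
#' Per region integrates the vasodilatory signal s, blood inflow f, volume v
#' and deoxyhemoglobin content q:
#' ds/dt = eps*x - kappa*s - gamma*(f-1); df/dt = s;
#' tau dv/dt = f - v^(1/alpha);
#' tau dq/dt = f*E(f,e0)/e0 - v^(1/alpha) q/v, E(f,e0) = 1-(1-e0)^(1/f),
#' from the resting state s=0, f=v=q=1, and maps to percent BOLD signal
#' y = 100 v0 (k1(1-q) + k2(1-q/v) + k3(1-v)) with k1 = 7 e0, k2 = 2,
#' k3 = 2 e0 - 0.2. RK4 at the same microtime step.
#'
#' @param neural n x T neural trajectory (from \code{\link{integrateNeural}}).
#' @param hemo hemodynamic constants (\code{\link{defaultHemoParams}}).
#' @param dt microtime step (s).
#' @return n x T matrix of BOLD (percent signal change) on the microtime grid.
#' @export
hemodynamics <- function(neural, hemo = defaultHemoParams(), dt) {
  stopifnot(all(is.finite(neural)))
  h <- .hemoVectors(hemo, nrow(neural))
  .hemodynamics_cpp(neural, dt, h$kappa, h$gamma, h$tau, h$alpha, h$e0,
                    h$v0, h$epsilon)
}

#' Simulate a BOLD time series
#'
#' Integrates the neural and hemodynamic states jointly (one classical RK4
#' pass over the combined state, preserving 4th-order accuracy), samples one
#' value per TR at each volume onset, and optionally adds i.i.d. Gaussian
#' scan noise.
#'
#' @inheritParams integrateNeural
#' @param hemo hemodynamic constants.
#' @param noiseSd scan-noise SD in percent signal (0 = deterministic
#'   prediction).
#' @param seed RNG seed used when \code{noiseSd > 0}.
#' @return A \linkS4class{BoldTimeSeries}.
#' @export
simulateBold <- function(params, design, mask = NULL,
                         hemo = defaultHemoParams(), noiseSd = 0,
                         seed = NULL) {
  stopifnot(noiseSd >= 0)
  if (!is.null(mask)) params <- maskParameters(params, mask)
  n <- nrow(params@a)
  hv <- .hemoVectors(hemo, n)
  aEff <- params@a - diag(params@selfDecay, n)
  # joint neural + hemodynamic RK4 (4th order); acquisition at volume onsets
  ys <- .simulate_bold_cpp(aEff, params@bLow, params@bHigh, params@c,
                           design@u, design@tr / design@microtimeBins,
                           design@microtimeBins, design@nScans, hv$kappa,
                           hv$gamma, hv$tau, hv$alpha, hv$e0, hv$v0,
                           hv$epsilon)
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    ys <- ys + matrix(rnorm(length(ys), 0, noiseSd), nrow(ys), ncol(ys))
  }
  regions <- if (nrow(ys) == length(.REGIONS)) .REGIONS else
    paste0("R", seq_len(nrow(ys)))
  rownames(ys) <- regions
  new("BoldTimeSeries", y = ys, tr = design@tr, regions = regions)
}

# Fast masked prediction used by the inverter: theta -> 6 x nScans BOLD.
.predict <- function(theta, ix, selfDecay, design, hemoVec) {
  .dcm_predict_cpp(theta, ix$iA, ix$iB, ix$iC, selfDecay, design@u,
                   design@tr / design@microtimeBins, design@microtimeBins,
                   design@nScans, length(hemoVec$kappa), hemoVec$kappa,
                   hemoVec$gamma, hemoVec$tau, hemoVec$alpha, hemoVec$e0,
                   hemoVec$v0, hemoVec$epsilon)
}

.predictJac <- function(theta, ix, selfDecay, design, hemoVec, h) {
  .dcm_predict_jac_cpp(theta, ix$iA, ix$iB, ix$iC, selfDecay, design@u,
                       design@tr / design@microtimeBins, design@microtimeBins,
                       design@nScans, length(hemoVec$kappa), hemoVec$kappa,
                       hemoVec$gamma, hemoVec$tau, hemoVec$alpha, hemoVec$e0,
                       hemoVec$v0, hemoVec$epsilon, h)
}
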