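#' @include AllClasses.R
NULL

#' Two-parameter monoexponential decay
#'
#' `S(t) = S0 * exp(-t / T)`. This is the fitting model for MESE T2,
#' CW T1rho, adiabatic T1rho and adiabatic T2rho; for pulse-train
#' acquisitions the time axis is the train duration `n * tau_p`.
#'
#' @param t time in seconds (vectorized, `t >= 0`).
#' @param amplitude signal amplitude S0.
#' @param relaxationTime time constant T in seconds (> 0).
#' @return numeric signal.
#' @examples
#' monoexpDecay(0.05, 100, 0.05)  # one time constant: 100 / e
#' @export
monoexpDecay <- function(t, amplitude, relaxationTime) {
  .checkRelaxationTime(relaxationTime)
  stopifnot(all(t >= 0))
  amplitude * exp(-t / relaxationTime)
}

#' Magnitude inversion-recovery signal
#'
#' `S(TI) = |S0 * (1 - 2 * exp(-TI / T1))|`, the two-parameter magnitude
#' inversion-recovery model under a full-recovery assumption (TR much longer
#' than T1; here TR = 7 s against tissue T1 of order 1.5 s). The signal
#' nulls at `TI = T1 * ln 2`.
#'
#' @param ti inversion time in seconds (vectorized, `ti >= 0`).
#' @param amplitude equilibrium amplitude S0.
#' @param t1 longitudinal relaxation time in seconds (> 0).
#' @return numeric magnitude signal.
#' @examples
#' irMagnitude(1.4 * log(2), 50, 1.4)  # null point: 0
#' @export
irMagnitude <- function(ti, amplitude, t1) {
  .checkRelaxationTime(t1)
  stopifnot(all(ti >= 0))
  abs(amplitude * (1 - 2 * exp(-ti / t1)))
}

#' RAFF signal with steady state
#'
#' RAFF decays toward a nonzero steady state:
#' `S(t) = Sss + (S0 - Sss) * exp(-t / T)` without inversion preparation and
#' `S(t) = Sss + (S0inv - Sss) * exp(-t / T)` with it. The two curves share
#' the relaxation time and the steady state; the returned value is signed
#' (the inverted curve starts negative for `S0inv < 0`), take `abs()` to
#' compare against magnitude images.
#'
#' @param t train duration in seconds (vectorized, `t >= 0`).
#' @param amplitude S0 of the non-inverted curve.
#' @param relaxationTime T_RAFF in seconds (> 0).
#' @param steadyState shared steady-state signal Sss.
#' @param invertedAmplitude S0inv of the inversion-prepared curve
#'   (required when `inverted = TRUE`).
#' @param inverted logical, evaluate the inversion-prepared curve.
#' @return numeric signed signal.
#' @examples
#' raffSignal(0.05, 100, 0.05, 40)  # 40 + 60/e
#' @export
raffSignal <- function(t, amplitude, relaxationTime, steadyState,
                       invertedAmplitude = NA_real_, inverted = FALSE) {
  .checkRelaxationTime(relaxationTime)
  stopifnot(all(t >= 0))
  if (any(!is.finite(steadyState)))
    stop("raffSignal: steadyState is required (RAFF decays to Sss)")
  s0 <- if (inverted) {
    if (any(!is.finite(invertedAmplitude)))
      stop("raffSignal: invertedAmplitude is required when inverted = TRUE")
    invertedAmplitude
  } else amplitude
  steadyState + (s0 - steadyState) * exp(-t / relaxationTime)
}

#' Pulse-train duration
#'
#' Converts adiabatic/RAFF pulse counts to a time axis, `t = n * tau_p`.
#'
#' @param nPulses non-negative pulse counts (vectorized).
#' @param tauP pulse duration in seconds (> 0).
#' @return durations in seconds.
#' @export
trainDuration <- function(nPulses, tauP) {
  if (any(nPulses < 0)) stop("trainDuration: pulse counts must be >= 0")
  if (!is.finite(tauP) || tauP <= 0)
    stop("trainDuration: tauP must be positive")
  nPulses * tauP
}

.checkRelaxationTime <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("relaxation time must be positive and finite", call. = FALSE)
  invisible(TRUE)
}
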