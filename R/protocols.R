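#' @include AllClasses.R
NULL

#' Construct a SequenceProtocol
#'
#' For pulse-train kinds (`AD_T1RHO`, `AD_T2RHO`, `RAFF2/3/4`) the timing
#' axis may be omitted and is then computed as
#' [trainDuration()]`(pulseCounts, pulseDuration)`.
#'
#' @param kind sequence kind, see [SequenceProtocol-class].
#' @param repetitionTime TR in seconds.
#' @param timingAxis echo/inversion/spin-lock times in seconds.
#' @param spinLockHz spin-lock amplitude in Hz (`CW_T1RHO` only).
#' @param pulseDuration adiabatic/RAFF pulse duration tau_p in seconds.
#' @param pulseCounts pulse counts per timing-axis entry.
#' @param inversionPrepared logical, RAFF inversion preparation.
#' @return A validated [SequenceProtocol-class].
#' @examples
#' sequenceProtocol("MESE_T2", 3, timingAxis = seq(0.01, 0.1, by = 0.01))
#' sequenceProtocol("AD_T1RHO", 5, pulseDuration = 0.0045,
#'                  pulseCounts = c(0, 4, 8, 12, 24, 36))
#' @export
sequenceProtocol <- function(kind, repetitionTime, timingAxis = NULL,
                             spinLockHz = NA_real_, pulseDuration = NA_real_,
                             pulseCounts = numeric(0),
                             inversionPrepared = FALSE) {
  if (is.null(timingAxis)) {
    if (!kind %in% .TRAIN_KINDS || !length(pulseCounts))
      stop("timingAxis can only be omitted for pulse-train kinds ",
           "with pulseCounts given")
    timingAxis <- trainDuration(pulseCounts, pulseDuration)
  }
  new("SequenceProtocol", kind = kind,
      repetitionTime = as.numeric(repetitionTime),
      timingAxis = as.numeric(timingAxis),
      spinLockHz = as.numeric(spinLockHz),
      pulseDuration = as.numeric(pulseDuration),
      pulseCounts = as.numeric(pulseCounts),
      inversionPrepared = isTRUE(inversionPrepared))
}

#' The study's acquisition protocols
#'
#' The full multi-parameter relaxometry protocol set: inversion-recovery T1,
#' multi-echo spin-echo T2, continuous-wave T1rho at four spin-lock
#' amplitudes (200, 500, 1000, 5000 Hz), adiabatic T1rho and T2rho (HS1
#' pulse trains, tau_p = 4.5 ms), and RAFF2/3/4 (tau_p = 4.5 ms, trains of
#' 0-64 pulses; the returned protocols are the non-inverted member of each
#' RAFF pair, see [withInversion()]).
#'
#' @return A named list of [SequenceProtocol-class] objects; names are the
#'   quantity labels used throughout the package (e.g. `CW_T1RHO_200HZ`).
#' @examples
#' names(paperProtocols())
#' @export
paperProtocols <- function() {
  tau <- 0.0045
  cw <- function(hz)
    sequenceProtocol("CW_T1RHO", 5,
                     timingAxis = c(0, 8, 16, 32, 64, 128) / 1000,
                     spinLockHz = hz)
  raff <- function(kind)
    sequenceProtocol(kind, 5, pulseDuration = tau,
                     pulseCounts = c(0, 2, 4, 8, 16, 32, 64))
  p <- list(
    IR_T1 = sequenceProtocol("IR_T1", 7,
                             timingAxis = c(0.2, 0.5, 0.8, 1.1, 1.4, 3)),
    MESE_T2 = sequenceProtocol("MESE_T2", 3,
      timingAxis = c(7.4, 14.7, 22.1, 29.4, 36.8, 44.1,
                     51.5, 58.8, 66.2, 73.6) / 1000),
    CW_T1RHO_200HZ = cw(200), CW_T1RHO_500HZ = cw(500),
    CW_T1RHO_1000HZ = cw(1000), CW_T1RHO_5000HZ = cw(5000),
    AD_T1RHO = sequenceProtocol("AD_T1RHO", 5, pulseDuration = tau,
                                pulseCounts = c(0, 4, 8, 12, 24, 36)),
    AD_T2RHO = sequenceProtocol("AD_T2RHO", 5, pulseDuration = tau,
                                pulseCounts = c(0, 4, 8, 12, 24)),
    RAFF2 = raff("RAFF2"), RAFF3 = raff("RAFF3"), RAFF4 = raff("RAFF4"))
  p
}

#' Quantity label of a protocol
#'
#' A short label identifying the relaxation quantity a protocol measures,
#' used as list names, in sidecars and in reports. CW spin-lock amplitudes
#' are folded into the label (`CW_T1RHO_200HZ`); the RAFF inversion flag is
#' not (both members of a pair measure the same quantity).
#'
#' @param protocol a [SequenceProtocol-class].
#' @return character scalar.
#' @export
quantityLabel <- function(protocol) {
  stopifnot(is(protocol, "SequenceProtocol"))
  if (protocol@kind == "CW_T1RHO")
    sprintf("CW_T1RHO_%dHZ", as.integer(round(protocol@spinLockHz)))
  else protocol@kind
}

#' Inversion-prepared companion of a RAFF protocol
#'
#' @param protocol a RAFF [SequenceProtocol-class].
#' @return The same protocol with `inversionPrepared = TRUE`.
#' @export
withInversion <- function(protocol) {
  stopifnot(is(protocol, "SequenceProtocol"))
  if (!protocol@kind %in% .RAFF_KINDS)
    stop("inversion preparation applies to RAFF kinds only")
  protocol@inversionPrepared <- TRUE
  validObject(protocol)
  protocol
}

#' Evaluate a protocol's forward signal model
#'
#' Dispatches to [monoexpDecay()], [irMagnitude()] or [raffSignal()]
#' according to the protocol kind. RAFF signals are returned as magnitudes,
#' consistent with the magnitude image data the fitter consumes.
#'
#' @param protocol a [SequenceProtocol-class].
#' @param t times in seconds (defaults to the protocol timing axis).
#' @param params a [ModelParameters-class].
#' @return numeric vector of model signals.
#' @export
predictSignal <- function(protocol, t = timingAxis(protocol), params) {
  kind <- protocol@kind
  if (kind == "IR_T1")
    return(irMagnitude(t, params@amplitude, params@relaxationTime))
  if (kind %in% .RAFF_KINDS)
    return(abs(raffSignal(t, params@amplitude, params@relaxationTime,
                          params@steadyState, params@invertedAmplitude,
                          inverted = protocol@inversionPrepared)))
  monoexpDecay(t, params@amplitude, params@relaxationTime)
}

## ---- JSON sidecar (de)serialization -------------------------------------

#' Serialize a protocol to sidecar fields
#'
#' The sidecar schema uses keys `kind`, `tr_s`, `times_s`, `spin_lock_hz`,
#' `tau_p_s`, `pulse_counts`, `inversion_prepared`, `orientation_deg`
#' (the latter supplied by the series writer). Optional fields are omitted
#' when not applicable.
#'
#' @param protocol a [SequenceProtocol-class].
#' @return a named list ready for [jsonlite::write_json()].
#' @export
protocolToSidecar <- function(protocol) {
  out <- list(kind = protocol@kind,
              tr_s = protocol@repetitionTime,
              times_s = protocol@timingAxis)
  if (protocol@kind == "CW_T1RHO") out$spin_lock_hz <- protocol@spinLockHz
  if (protocol@kind %in% .TRAIN_KINDS) {
    out$tau_p_s <- protocol@pulseDuration
    out$pulse_counts <- protocol@pulseCounts
  }
  out$inversion_prepared <- protocol@inversionPrepared
  out
}

#' @rdname protocolToSidecar
#' @param fields a named list parsed from a JSON sidecar.
#' @export
protocolFromSidecar <- function(fields) {
  sequenceProtocol(kind = fields$kind,
                   repetitionTime = fields$tr_s,
                   timingAxis = unlist(fields$times_s),
                   spinLockHz = if (is.null(fields$spin_lock_hz))
                     NA_real_ else fields$spin_lock_hz,
                   pulseDuration = if (is.null(fields$tau_p_s))
                     NA_real_ else fields$tau_p_s,
                   pulseCounts = if (is.null(fields$pulse_counts))
                     numeric(0) else unlist(fields$pulse_counts),
                   inversionPrepared = isTRUE(fields$inversion_prepared))
}
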