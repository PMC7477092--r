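#' Chlorophyll-fluorescence derived quantities
#'
#' Standard quenching analysis for pulse-amplitude-modulated fluorescence:
#' dark-adapted maximum quantum yield Fv/Fm, PSII operating efficiency
#' (PhiPSII), non-photochemical quenching (NPQ), the Oxborough-Baker estimate
#' of minimal fluorescence in the light (Fo'), the photochemical quenching
#' coefficient (qP), the efficiency of open PSII traps (Fv'/Fm'), and the
#' conversion of PhiPSII to linear electron transport J. All fluorescence
#' inputs are arbitrary counts; every derived quantity is invariant under a
#' common rescaling of all counts, and the definitional identity
#' `PhiPSII = qP * Fv'/Fm'` holds exactly.
#'
#' @param Fo,Fm dark-adapted minimal and maximal fluorescence (Fm > Fo > 0).
#' @param F_,Fm_prime light-adapted steady and maximal fluorescence
#'   (Fm' >= F > 0).
#' @param Fo_prime estimated minimal fluorescence in the light, see
#'   [fo_prime()].
#' @name quenching
NULL

check_fluor <- function(ok, msg) {
  if (!all(ok))
    stop_photoinduct(msg, "photoinduct_fluorescence_error")
}

#' @describeIn quenching dark-adapted `(Fm - Fo)/Fm`, in (0, 1).
#' @export
fvfm <- function(Fo, Fm) {
  check_fluor(Fm > Fo & Fo > 0, "requires Fm > Fo > 0")
  (Fm - Fo) / Fm
}

#' @describeIn quenching PSII operating efficiency `(Fm' - F)/Fm'`, in [0, 1).
#' @export
phi_psii <- function(F_, Fm_prime) {
  check_fluor(Fm_prime >= F_ & F_ > 0, "requires Fm' >= F > 0")
  (Fm_prime - F_) / Fm_prime
}

#' @describeIn quenching non-photochemical quenching `(Fm - Fm')/Fm'` (>= 0).
#' @export
npq <- function(Fm, Fm_prime) {
  check_fluor(Fm >= Fm_prime & Fm_prime > 0, "requires Fm >= Fm' > 0")
  (Fm - Fm_prime) / Fm_prime
}

#' @describeIn quenching Oxborough-Baker estimator
#'   `Fo' = Fo / (Fv/Fm + Fo/Fm')`; reduces to `Fo` in the dark limit
#'   `Fm' = Fm` and decreases monotonically with `Fm'`.
#' @export
fo_prime <- function(Fo, Fm, Fm_prime) {
  check_fluor(Fm > Fo & Fo > 0 & Fm_prime > 0,
              "requires Fm > Fo > 0 and Fm' > 0")
  den <- fvfm(Fo, Fm) + Fo / Fm_prime
  check_fluor(den > 0, "Fo' denominator must be positive")
  Fo / den
}

#' @describeIn quenching photochemical quenching coefficient
#'   `qP = (Fm' - F)/(Fm' - Fo')`, in [0, 1].
#' @export
qp <- function(F_, Fm_prime, Fo_prime) {
  check_fluor(Fm_prime > Fo_prime, "requires Fm' > Fo'")
  check_fluor(F_ >= Fo_prime & F_ <= Fm_prime, "requires Fo' <= F <= Fm'")
  (Fm_prime - F_) / (Fm_prime - Fo_prime)
}

#' @describeIn quenching efficiency of open PSII traps
#'   `Fv'/Fm' = (Fm' - Fo')/Fm'`, in (0, 1).
#' @export
fvfm_prime <- function(Fm_prime, Fo_prime) {
  check_fluor(Fm_prime > Fo_prime & Fo_prime > 0, "requires Fm' > Fo' > 0")
  (Fm_prime - Fo_prime) / Fm_prime
}

#' Electron transport rate from PSII operating efficiency
#'
#' `J = s * PAR * PhiPSII`, where `s` is the lumped calibration factor
#' (absorptance x PSII partitioning x any alternative-sink correction)
#' estimated by [fit_rd_s()].
#'
#' @param PAR irradiance, umol m-2 s-1 (>= 0).
#' @param phi_psii PSII operating efficiency.
#' @param s lumped conversion factor, dimensionless (> 0).
#' @return J, umol electrons m-2 s-1; linear in each argument.
#' @export
electron_transport <- function(PAR, phi_psii, s) {
  stopifnot(all(s > 0), all(PAR >= 0))
  s * PAR * phi_psii
}

#' Quenching analysis of a trace's fluorescence records
#'
#' Applies the full partitioning to every sample of a trace that carries
#' fluorescence (`F`, `Fm_prime`) together with dark reference `Fo`, `Fm`.
#'
#' @param trace an [induction_trace] (or data frame) with fluorescence columns.
#' @param s optional conversion factor; when given, `J` is appended.
#' @return Data frame with `time_s`, `phi_psii`, `npq`, `qp`, `fvfm_prime`,
#'   `fo_prime` (and `J` if `s` supplied), one row per fluorescence record.
#' @export
quenching_analysis <- function(trace, s = NULL) {
  need <- c("F", "Fm_prime", "Fo", "Fm")
  if (!all(need %in% names(trace)))
    stop_photoinduct("trace lacks fluorescence columns",
                     "photoinduct_format_error")
  has <- stats::complete.cases(trace[, need])
  d <- as.data.frame(trace)[has, , drop = FALSE]
  fo_p <- fo_prime(d$Fo, d$Fm, d$Fm_prime)
  out <- data.frame(
    time_s     = d$time_s,
    phi_psii   = phi_psii(d$F, d$Fm_prime),
    npq        = npq(d$Fm, d$Fm_prime),
    qp         = qp(d$F, d$Fm_prime, fo_p),
    fvfm_prime = fvfm_prime(d$Fm_prime, fo_p),
    fo_prime   = fo_p)
  if (!is.null(s)) out$J <- electron_transport(d$PAR, out$phi_psii, s)
  out
}
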