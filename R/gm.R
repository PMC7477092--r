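#' Variable-J estimate of mesophyll conductance
#'
#' Inverts the RuBP-regeneration-limited FvCB model with a
#' fluorescence-derived electron transport rate (the Harley-type "variable J"
#' method):
#' `gm = A / (Ci - G* (J + 8 (A + Rd)) / (J - 4 (A + Rd)))`, and
#' `Cc = Ci - A / gm`. The formula amplifies errors as `J` approaches the
#' electron requirement `4 (A + Rd)`; estimates within 5% of that singularity
#' are flagged unreliable. Results with `Cc` outside `(G*, Ci)` or
#' non-positive `gm` are flagged invalid rather than raised as errors.
#'
#' @param A net photosynthesis, umol m-2 s-1 (> 0); vectorized.
#' @param Ci substomatal CO2 partial pressure, ubar (> gamma_star).
#' @param J electron transport rate, umol m-2 s-1 (> `4 (A + Rd)`).
#' @param Rd day respiration, umol m-2 s-1.
#' @param gamma_star CO2 photocompensation point, ubar (chloroplastic basis).
#' @param singularity_margin flag estimates with
#'   `J < (1 + margin) * 4 (A + Rd)` as unreliable (default 5%).
#' @return Data frame of class `mesophyll_result`: `gm`, `Cc`, inputs echoed,
#'   `valid`, `reliable`.
#' @export
gm_variable_j <- function(A, Ci, J, Rd, gamma_star,
                          singularity_margin = 0.05) {
  n <- max(length(A), length(Ci), length(J))
  A <- rep_len(A, n); Ci <- rep_len(Ci, n); J <- rep_len(J, n)
  if (any(A <= 0))
    stop_photoinduct("A must be positive", "photoinduct_domain_error")
  if (any(Ci <= gamma_star))
    stop_photoinduct("Ci must exceed gamma_star", "photoinduct_domain_error")
  req <- 4 * (A + Rd)                    # electron requirement
  if (any(J <= req))
    stop_photoinduct(
      "J <= 4 (A + Rd): fluorescence inconsistent with photorespiratory model",
      "photoinduct_photorespiration_error")
  cc_term <- gamma_star * (J + 8 * (A + Rd)) / (J - req)
  gm <- A / (Ci - cc_term)
  Cc <- Ci - A / gm
  valid <- is.finite(gm) & gm > 0 & Cc > gamma_star & Cc < Ci
  reliable <- valid & J >= (1 + singularity_margin) * req
  out <- data.frame(gm = gm, Cc = Cc, A = A, Ci = Ci, J = J,
                    Rd = Rd, gamma_star = gamma_star,
                    valid = valid, reliable = reliable)
  class(out) <- c("mesophyll_result", "data.frame")
  out
}

#' Variable-J mesophyll conductance for a set of samples
#'
#' Computes per-sample `J` from fluorescence via [electron_transport()] with
#' the calibrated `s`, then applies [gm_variable_j()] with the calibrated
#' `Rd` and `Gamma*`. Samples without fluorescence, or failing the method's
#' preconditions, are kept in the output with `valid = FALSE` and a `reason`,
#' never dropped silently.
#'
#' @param samples data frame (trace or curve) with `A`, `Ci`, `PAR` and
#'   fluorescence columns `F`, `Fm_prime`.
#' @param calib a `calibration_params` object (or list with `Rd`,
#'   `gamma_star`, `s`).
#' @return A `mesophyll_result` data frame, one row per input sample, with a
#'   `reason` column for skipped/invalid rows.
#' @export
batch_gm <- function(samples, calib) {
  d <- as.data.frame(samples)
  n <- nrow(d)
  out <- data.frame(gm = rep(NA_real_, n), Cc = NA_real_, A = d$A, Ci = d$Ci,
                    J = NA_real_, Rd = calib$Rd, gamma_star = calib$gamma_star,
                    valid = FALSE, reliable = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  has_fluor <- all(c("F", "Fm_prime") %in% names(d))
  fl_ok <- if (has_fluor)
    !is.na(d$F) & !is.na(d$Fm_prime) & d$F > 0 & d$Fm_prime >= d$F
  else rep(FALSE, n)
  if (has_fluor) {
    present <- !is.na(d$F) & !is.na(d$Fm_prime)
    out$reason[!fl_ok & present]  <- "invalid fluorescence"
    out$reason[!fl_ok & !present] <- "missing fluorescence"
  } else out$reason <- "missing fluorescence"
  for (i in which(fl_ok)) {
    J_i <- electron_transport(d$PAR[i], phi_psii(d$F[i], d$Fm_prime[i]),
                              calib$s)
    res <- tryCatch(
      gm_variable_j(d$A[i], d$Ci[i], J_i, calib$Rd, calib$gamma_star),
      photoinduct_error = function(e) e)
    if (inherits(res, "error")) {
      out$J[i] <- J_i
      out$reason[i] <- conditionMessage(res)
    } else {
      out[i, c("gm", "Cc", "J", "valid", "reliable")] <-
        res[, c("gm", "Cc", "J", "valid", "reliable")]
      if (!res$valid) out$reason[i] <- "Cc outside (gamma_star, Ci)"
      else if (!res$reliable) out$reason[i] <- "near variable-J singularity"
    }
  }
  class(out) <- c("mesophyll_result", "data.frame")
  out
}
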