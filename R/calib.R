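#' Estimate Rd and the fluorescence-to-J factor s
#'
#' Under non-photorespiratory conditions (2% oxygen, saturating CO2) the
#' electron requirement of assimilation reduces to `J = 4 (A + Rd)`, so a
#' plot of `A` against `x = PAR * PhiPSII / 4` across low irradiances is a
#' straight line with slope `s` (the lumped factor converting
#' `PAR * PhiPSII` to `J`) and intercept `-Rd`. This fits that line by
#' ordinary least squares.
#'
#' @param curve a [response_curve] of mode `"APAR"` measured at low oxygen
#'   and high Ca, with fluorescence columns (`F`, `Fm_prime`).
#' @param par_max use only points with `PAR <= par_max` (umol m-2 s-1), where
#'   electron transport is strictly light-limited.
#' @return List of class `rd_s_fit`: `Rd`, `s`, `r_squared`, `n`.
#' @export
fit_rd_s <- function(curve, par_max = 200) {
  d <- as.data.frame(curve)
  if (!all(c("F", "Fm_prime") %in% names(d)))
    stop_photoinduct("curve lacks fluorescence columns",
                     "photoinduct_format_error")
  d <- d[d$PAR <= par_max & stats::complete.cases(d[, c("F", "Fm_prime")]), ]
  if (nrow(d) < 4L)
    stop_photoinduct("need >= 4 low-irradiance points with fluorescence",
                     "photoinduct_fit_error")
  x <- d$PAR * phi_psii(d$F, d$Fm_prime) / 4
  if (max(x) / max(min(x), .Machine$double.eps) < 2)
    stop_photoinduct("degenerate x-range (max/min < 2): ill-conditioned",
                     "photoinduct_fit_error")
  fit <- stats::lm(d$A ~ x)
  structure(list(Rd = -unname(stats::coef(fit)[1]),
                 s = unname(stats::coef(fit)[2]),
                 r_squared = summary(fit)$r.squared,
                 n = nrow(d)),
            class = "rd_s_fit")
}

#' Estimate the CO2 photocompensation point Gamma*
#'
#' Fits the RuBP-regeneration-limited model
#' `A = J (C - G*) / (4 C + 8 G*) - Rd`, with per-point
#' `J = s * PAR * PhiPSII`, to the low-Ci portion of a 21%-oxygen A/Ci curve,
#' minimizing the sum of squared A residuals over `G*` on a bounded interval.
#' With the default `gm = NULL` the fit runs on Ci and returns the
#' *apparent* (Ci-based) Gamma*; supplying a mesophyll conductance converts
#' to `Cc = Ci - A/gm` and yields the chloroplastic value.
#'
#' @param curve a [response_curve] of mode `"ACI"` at 21% O2 with
#'   fluorescence columns.
#' @param Rd day respiration, umol m-2 s-1 (from [fit_rd_s()]).
#' @param s fluorescence-to-J conversion factor (from [fit_rd_s()]).
#' @param gm optional mesophyll conductance for a Cc-based fit.
#' @param ci_max use only points with `Ci <= ci_max` (ubar), below the
#'   RuBP/TPU transitions.
#' @param interval search bounds for Gamma*, ubar.
#' @return List of class `gamma_star_fit`: `gamma_star`, `sse`, `n`,
#'   `at_boundary` (logical; optimum within 0.5 ubar of a search bound, with
#'   a warning).
#' @export
fit_gamma_star <- function(curve, Rd, s, gm = NULL, ci_max = 200,
                           interval = c(10, 100)) {
  d <- as.data.frame(curve)
  if (!all(c("F", "Fm_prime") %in% names(d)))
    stop_photoinduct("curve lacks fluorescence columns",
                     "photoinduct_format_error")
  d <- d[d$Ci <= ci_max & stats::complete.cases(d[, c("F", "Fm_prime")]), ]
  if (nrow(d) < 3L)
    stop_photoinduct("need >= 3 points with Ci <= ci_max and fluorescence",
                     "photoinduct_fit_error")
  J <- electron_transport(d$PAR, phi_psii(d$F, d$Fm_prime), s)
  C <- if (is.null(gm)) d$Ci else d$Ci - d$A / gm
  sse <- function(g) sum((d$A - (J * (C - g) / (4 * C + 8 * g) - Rd))^2)
  opt <- stats::optimize(sse, interval = interval, tol = 1e-8)
  at_bound <- min(opt$minimum - interval[1], interval[2] - opt$minimum) < 0.5
  if (at_bound)
    warning("Gamma* optimum at search boundary; estimate unreliable",
            call. = FALSE)
  structure(list(gamma_star = opt$minimum, sse = opt$objective, n = nrow(d),
                 at_boundary = at_bound),
            class = "gamma_star_fit")
}

#' Calibrate Rd, Gamma* and s for one leaf
#'
#' Runs the two-step calibration: [fit_rd_s()] on the non-photorespiratory
#' (2% O2, high Ca) A/PAR curve, then [fit_gamma_star()] on the low-Ci part
#' of the 21% O2 A/Ci curve. By default Gamma* is the apparent, Ci-based
#' value. With `refine_gm = TRUE` the calibration alternates a Cc-based
#' Gamma* fit with a variable-J mesophyll-conductance estimate at the sample
#' closest to `gm_ca`, iterating to the self-consistent (Gamma*, gm) pair;
#' the iteration is a contraction on well-behaved curves and stops when
#' Gamma* changes by < 0.01 ubar.
#'
#' @param apar_low_o2 [response_curve] `"APAR"` at 2% O2.
#' @param aci [response_curve] `"ACI"` at 21% O2 with fluorescence.
#' @param refine_gm iterate to a Cc-based Gamma*, gm and corrected s/Rd
#'   (see Details)?
#' @param gm_ca chamber CO2 (ubar) of the sample used for the gm step.
#' @param ... passed to [fit_rd_s()] / [fit_gamma_star()].
#' @return List of class `calibration_params`: `Rd`, `gamma_star`, `s`,
#'   `r_squared`, `n_rd_s`, `n_gamma`, `gamma_star_basis` ("Ci" or "Cc"),
#'   `gm` (NA unless refined), `iterations`.
#' @export
calibrate_leaf <- function(apar_low_o2, aci, refine_gm = FALSE, gm_ca = 400,
                           ...) {
  rs <- fit_rd_s(apar_low_o2)
  gf <- fit_gamma_star(aci, Rd = rs$Rd, s = rs$s, ...)
  gamma <- gf$gamma_star
  s_est <- rs$s
  rd_est <- rs$Rd
  gm_est <- NA_real_
  iters <- 0L
  if (refine_gm) {
    d <- as.data.frame(aci)
    i <- which.min(abs(d$Ca - gm_ca))
    phi_pt <- phi_psii(d$F[i], d$Fm_prime[i])
    dl <- as.data.frame(apar_low_o2)
    dl <- dl[dl$PAR <= 200 & stats::complete.cases(dl[, c("F", "Fm_prime")]), ]
    o2_low <- attr(apar_low_o2, "O2") %||% 2
    x_low <- dl$PAR * phi_psii(dl$F, dl$Fm_prime) / 4
    for (iters in seq_len(40L)) {
      J_pt <- electron_transport(d$PAR[i], phi_pt, s_est)
      mg <- gm_variable_j(d$A[i], d$Ci[i], J_pt, rd_est, gamma)
      if (!mg$valid)
        stop_photoinduct("gm refinement produced an invalid estimate",
                         "photoinduct_fit_error")
      gm_est <- mg$gm
      gf <- fit_gamma_star(aci, Rd = rd_est, s = s_est, gm = gm_est, ...)
      # re-regress the low-O2 curve with the residual-photorespiration
      # factor predicted by the current Gamma*/gm, removing the small bias
      # of the fully non-photorespiratory approximation of s
      g_low <- gf$gamma_star * (o2_low / 21)
      cc_low <- dl$Ci - dl$A / gm_est
      fac <- (cc_low - g_low) / (cc_low + 2 * g_low)
      fit_corr <- stats::lm(dl$A ~ I(x_low * fac))
      s_new <- unname(stats::coef(fit_corr)[2])
      rd_new <- -unname(stats::coef(fit_corr)[1])
      done <- abs(gf$gamma_star - gamma) < 0.005 &&
        abs(s_new / s_est - 1) < 1e-5
      gamma <- gf$gamma_star
      s_est <- s_new
      rd_est <- rd_new
      if (done) break
    }
  }
  structure(list(Rd = rd_est, gamma_star = gamma, s = s_est,
                 r_squared = rs$r_squared, n_rd_s = rs$n, n_gamma = gf$n,
                 gamma_star_basis = if (refine_gm) "Cc" else "Ci",
                 gm = gm_est, iterations = iters),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat(sprintf(
    "Calibration: Rd = %.3f, Gamma* = %.2f ubar (%s-based), s = %.4f (R2 = %.4f)\n",
    x$Rd, x$gamma_star, x$gamma_star_basis, x$s, x$r_squared))
  invisible(x)
}
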