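#' Reference steady-state gas-exchange endpoints for the genotype presets
#'
#' Published steady-state means at 50 and 1500 umol m-2 s-1 PAR for the
#' wildtype and the ABA-deficient, high-conductance flacca mutant of tomato
#' under three environments (control: 400 ubar CO2 / 7 mbar VPD; low CO2:
#' 200 ubar; high VPD: 15 mbar). These endpoints define the simulator
#' presets: [preset_scenario()] pins its stomatal endpoints to `gs50` /
#' `gs1500` and numerically calibrates the demand side so the simulated
#' steady states reproduce `A50` and `A1500`.
#'
#' @return Data frame with one row per genotype x treatment.
#' @export
steady_state_targets <- function() {
  data.frame(
    genotype  = rep(c("WT", "flacca"), 3),
    treatment = rep(c("control", "low_co2", "high_vpd"), each = 2),
    Ca  = rep(c(400, 200, 400), each = 2),
    vpd = rep(c(7, 7, 15), each = 2),
    A50    = c(2.0, 1.9, 1.7, 1.7, 1.9, 1.8),
    gs50   = c(0.22, 0.62, 0.34, 0.58, 0.14, 0.58),
    Ci50   = c(379, 390, 192, 194, 369, 385),
    A1500  = c(26.0, 28.4, 14.8, 16.7, 24.4, 26.6),
    gs1500 = c(0.60, 1.03, 0.71, 1.09, 0.41, 0.88),
    Ci1500 = c(311, 336, 159, 165, 281, 329),
    stringsAsFactors = FALSE)
}

# non-rectangular hyperbola for potential electron transport vs PAR
nrh_j <- function(PAR, alpha, Jmax, theta = 0.7) {
  q <- alpha * PAR + Jmax
  (q - sqrt(pmax(q^2 - 4 * theta * alpha * PAR * Jmax, 0))) / (2 * theta)
}

# Jmax such that the hyperbola passes through (par_ref, J_ref)
jmax_for <- function(J_ref, alpha, theta = 0.7, par_ref = 1500) {
  aI <- alpha * par_ref
  if (aI <= J_ref)
    stop_photoinduct("alpha too small for requested J at reference PAR",
                     "photoinduct_scenario_error")
  J_ref * (aI - theta * J_ref) / (aI - J_ref)
}

# kinetic constants at a given oxygen mole percentage; gamma* scales with O2
eff_params <- function(p, O2) {
  p$O <- O2 * 10                      # % -> mbar
  p$gamma_star <- p$gamma_star * (O2 / 21)
  p
}

#' Construct a simulation scenario
#'
#' Bundles every knob of the ground-truth generator: stomatal kinetics
#' (exponential opening from `gs_i` to `gs_f` with lag `lag_s` and time
#' constant `tau_gs_s`), biochemical activation (Rubisco capacity and the
#' RuBP-regeneration capacity relax exponentially from initial activation
#' fractions `act_R0` / `act_J0` to the final [fvcb_params] with time
#' constants `tau_R_s` / `tau_J_s`), the light response of potential electron
#' transport (initial slope `alpha`, curvature `theta`, anchored so that
#' J(1500) equals `fvcb$J1500`), diffusion (`gm`, boundary layer `gb`),
#' fluorescence generation (`s`, dark `Fm`/`Fo`, a phenomenological NPQ
#' trajectory), optional transient TPU depression (`dip`), per-channel
#' measurement noise, and the RNG seed. A fixed seed makes the simulated
#' output bitwise reproducible.
#'
#' @param genotype,treatment labels carried onto outputs.
#' @param gs_i,gs_f initial and final stomatal conductance, mol m-2 s-1
#'   (`gs_f >= gs_i > 0`).
#' @param lag_s,tau_gs_s stomatal lag and time constant, s.
#' @param fvcb final (fully activated) [fvcb_params].
#' @param tau_R_s,tau_J_s Rubisco / RuBP-regeneration activation time
#'   constants, s.
#' @param act_R0,act_J0 initial activation fractions in (0, 1].
#' @param gm mesophyll conductance, mol m-2 s-1.
#' @param gb boundary-layer conductance to water vapour, mol m-2 s-1.
#' @param s fluorescence-to-J conversion factor.
#' @param alpha initial slope of J vs PAR (umol e- per umol photons);
#'   bounded above by `0.82 * s` (PhiPSII cannot exceed dark Fv/Fm).
#' @param theta curvature of the J light response.
#' @param Ca chamber CO2, ubar. @param vpd leaf-to-air VPD, mbar.
#' @param O2 oxygen, %.
#' @param par_low,par_high irradiance before/after the step, umol m-2 s-1.
#' @param fm_dark,fo_dark dark-adapted fluorescence levels (counts).
#' @param npq list of NPQ-trajectory parameters (`low`, `amp_fast`,
#'   `tau_fast`, `amp_relax`, `tau_relax`, `relax_delay`, `amp_slow`,
#'   `tau_slow`).
#' @param noise list of noise scales: `A`, `gs`, `Ci` (additive SD in trace
#'   units) and `fluor_rel` (relative SD on fluorescence counts).
#' @param dip optional transient TPU depression,
#'   `list(frac, t_center_s, width_s)`; `NULL` disables it.
#' @param pre_s,duration_s,dt_s pre-step baseline, post-step duration and
#'   logging cadence, s.
#' @param seed integer RNG seed, or `NULL` for noise-free determinism only.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(genotype = "WT", treatment = "control",
                         gs_i = 0.22, gs_f = 0.60,
                         lag_s = 60, tau_gs_s = 840,
                         fvcb = fvcb_params(Vcmax = 134, J1500 = 207,
                                            TPU = 14, Rd = 1.0),
                         tau_R_s = 120, tau_J_s = 90,
                         act_R0 = 0.3, act_J0 = 0.5,
                         gm = 0.3, gb = 1.42, s = 0.425,
                         alpha = 0.82 * s, theta = 0.7,
                         Ca = 400, vpd = 7, O2 = 21,
                         par_low = 50, par_high = 1500,
                         fm_dark = 4800, fo_dark = 864,
                         npq = list(low = 0.10, amp_fast = 1.68,
                                    tau_fast = 60, amp_relax = 0.35,
                                    tau_relax = 360, relax_delay = 180,
                                    amp_slow = 0.30, tau_slow = 1500),
                         noise = list(A = 0.3, gs = 0.01, Ci = 2,
                                      fluor_rel = 0.005),
                         dip = NULL,
                         pre_s = 300, duration_s = 3600, dt_s = 2,
                         seed = NULL) {
  stopifnot(gs_f >= gs_i, gs_i > 0, tau_gs_s > 0, tau_R_s > 0, tau_J_s > 0,
            act_R0 > 0, act_R0 <= 1, act_J0 > 0, act_J0 <= 1,
            gm > 0, s > 0, alpha <= 0.82 * s + 1e-12)
  sc <- list(genotype = genotype, treatment = treatment,
             gs_i = gs_i, gs_f = gs_f, lag_s = lag_s, tau_gs_s = tau_gs_s,
             fvcb = fvcb, tau_R_s = tau_R_s, tau_J_s = tau_J_s,
             act_R0 = act_R0, act_J0 = act_J0, gm = gm, gb = gb, s = s,
             alpha = alpha, theta = theta, Ca = Ca, vpd = vpd, O2 = O2,
             par_low = par_low, par_high = par_high,
             fm_dark = fm_dark, fo_dark = fo_dark, npq = npq, noise = noise,
             dip = dip, pre_s = pre_s, duration_s = duration_s, dt_s = dt_s,
             seed = seed)
  class(sc) <- "sim_scenario"
  sc
}

# steady state of a scenario at given drivers and activation state
sim_steady <- function(sc, PAR, gs, Ca = sc$Ca, O2 = sc$O2,
                       act_R = 1, act_J = 1) {
  p <- eff_params(sc$fvcb, O2)
  Jmax <- jmax_for(sc$fvcb$J1500, sc$alpha, sc$theta)
  J <- nrh_j(PAR, sc$alpha, Jmax * act_J, sc$theta)
  out <- aci_with_supply(p, gs = gs, Ca = Ca, gm = sc$gm, J = J,
                         Vcmax = p$Vcmax * act_R, gb = sc$gb)
  out$J <- J
  out
}

#' Genotype x treatment preset scenarios
#'
#' Returns a [sim_scenario] whose steady-state endpoints reproduce the
#' corresponding row of [steady_state_targets()]: the stomatal endpoints are
#' taken directly from the table (flacca's initial gs barely reacts to the
#' environment, unlike the wildtype's), a scale factor applied jointly to
#' `Vcmax`, `J1500` and `TPU` is solved so the simulated steady state at high
#' PAR matches the tabulated final A, and the light-response slope `alpha`
#' is solved (within its physical cap `0.82 s`) so the low-PAR steady state
#' matches the tabulated initial A. Day respiration is 1.0 (WT) / 1.4
#' (flacca) umol m-2 s-1, below the genotypes' dark effluxes of 1.2 / 1.9.
#'
#' @param genotype `"WT"` or `"flacca"`.
#' @param treatment `"control"`, `"low_co2"` or `"high_vpd"`.
#' @param seed optional RNG seed stored in the scenario.
#' @param ... overrides passed on to [sim_scenario()] after calibration
#'   (e.g. `noise`, `dip`, `duration_s`).
#' @return A calibrated [sim_scenario].
#' @export
preset_scenario <- function(genotype = c("WT", "flacca"),
                            treatment = c("control", "low_co2", "high_vpd"),
                            seed = NULL, ...) {
  genotype <- match.arg(genotype)
  treatment <- match.arg(treatment)
  tg <- steady_state_targets()
  row <- tg[tg$genotype == genotype & tg$treatment == treatment, ]
  base <- list(
    WT     = list(Vcmax = 110, J1500 = 138, TPU = 9.8, Rd = 1.0, gm = 0.30,
                  npq = list(low = 0.10, amp_fast = 1.68, tau_fast = 60,
                             amp_relax = 0.35, tau_relax = 360,
                             relax_delay = 180, amp_slow = 0.30,
                             tau_slow = 1500)),
    flacca = list(Vcmax = 110, J1500 = 138, TPU = 9.8, Rd = 1.4, gm = 0.35,
                  npq = list(low = 0.10, amp_fast = 1.48, tau_fast = 60,
                             amp_relax = 0.22, tau_relax = 360,
                             relax_delay = 180, amp_slow = 0.25,
                             tau_slow = 1500)))[[genotype]]
  mk <- function(sigma, alpha) {
    sim_scenario(
      genotype = genotype, treatment = treatment,
      gs_i = row$gs50, gs_f = row$gs1500,
      fvcb = fvcb_params(Vcmax = base$Vcmax * sigma,
                         J1500 = base$J1500 * sigma,
                         TPU = base$TPU * sigma, Rd = base$Rd),
      gm = base$gm, alpha = alpha, Ca = row$Ca, vpd = row$vpd,
      npq = base$npq, seed = seed, ...)
  }
  alpha_cap <- 0.82 * 0.425
  # capacity scale: final steady A at high PAR matches the tabulated value
  f_sigma <- function(sg)
    sim_steady(mk(sg, alpha_cap), PAR = 1500, gs = row$gs1500)$A - row$A1500
  # J1500 must stay below the light-limited ceiling alpha * PAR
  sigma_max <- 0.95 * alpha_cap * 1500 / base$J1500
  sigma <- stats::uniroot(f_sigma, c(0.2, sigma_max), tol = 1e-9)$root
  # light-response slope: pre-step steady A (partially activated) matches
  f_alpha <- function(al)
    sim_steady(mk(sigma, al), PAR = 50, gs = row$gs50,
               act_R = 0.3, act_J = 0.5)$A - row$A50
  alpha_min <- 1.06 * base$J1500 * sigma / 1500
  alpha <- if (f_alpha(alpha_cap) <= 0 || alpha_min >= alpha_cap) alpha_cap
  else stats::uniroot(f_alpha, c(alpha_min, alpha_cap), tol = 1e-10)$root
  mk(sigma, alpha)
}

# phenomenological NPQ trajectory: fast rise, partial relaxation, slow rise
npq_trajectory <- function(t, np) {
  ifelse(t < 0, np$low,
         np$low +
           np$amp_fast * (1 - exp(-t / np$tau_fast)) -
           np$amp_relax * (1 - exp(-pmax(0, t - np$relax_delay) / np$tau_relax)) +
           np$amp_slow * (1 - exp(-t / np$tau_slow)))
}

#' Simulate a photosynthetic induction transient
#'
#' Generates a 2-s-cadence gas-exchange + fluorescence trace of a step from
#' low to high irradiance. At each timestep stomatal conductance opens
#' exponentially (with lag), Rubisco capacity and the RuBP-regeneration
#' capacity relax exponentially from their initial activation fractions, and
#' (A, Ci, Cc) is obtained from the supply-demand intersection
#' ([aci_with_supply()]). Fluorescence is generated by inverting the demand
#' model — `J_true = 4 (A + Rd)(Cc + 2 G*)/(Cc - G*)`,
#' `PhiPSII = J_true / (s PAR)` — and combining it with a phenomenological
#' NPQ trajectory under fixed dark Fo/Fm, so every fluorescence-based
#' analysis stage can be validated against known truth. Gaussian noise is
#' added per channel; fluorescence records are attached at the instrument
#' cadence (one pre-step, every minute for 10 min, then every 2 min).
#'
#' @param sc a [sim_scenario].
#' @return List: `trace` (an [induction_trace], noisy if the scenario has
#'   noise), `truth` (list with the noise-free `trace`, the scenario, and
#'   `metrics` = [induction_metrics()] of the noise-free trace, including the
#'   true t50/t90).
#' @export
simulate_induction <- function(sc) {
  p <- eff_params(sc$fvcb, sc$O2)
  t <- seq(-sc$pre_s, sc$duration_s, by = sc$dt_s)
  post <- t >= 0
  PAR <- ifelse(post, sc$par_high, sc$par_low)
  gs <- ifelse(post,
               sc$gs_i + (sc$gs_f - sc$gs_i) *
                 (1 - exp(-pmax(0, t - sc$lag_s) / sc$tau_gs_s)),
               sc$gs_i)
  act_R <- ifelse(post, 1 - (1 - sc$act_R0) * exp(-t / sc$tau_R_s), sc$act_R0)
  act_J <- ifelse(post, 1 - (1 - sc$act_J0) * exp(-t / sc$tau_J_s), sc$act_J0)
  Jmax <- jmax_for(sc$fvcb$J1500, sc$alpha, sc$theta)
  J <- nrh_j(PAR, sc$alpha, Jmax * act_J, sc$theta)
  TPU <- rep_len(p$TPU, length(t))
  if (!is.null(sc$dip))
    TPU <- TPU * (1 - sc$dip$frac *
                    exp(-((t - sc$dip$t_center_s) / sc$dip$width_s)^2))
  st <- aci_with_supply(p, gs = gs, Ca = sc$Ca, gm = sc$gm, J = J,
                        Vcmax = p$Vcmax * act_R, TPU = TPU, gb = sc$gb)
  # fluorescence consistent with the realized fluxes
  j_true <- 4 * (st$A + p$Rd) * (st$Cc + 2 * p$gamma_star) /
    (st$Cc - p$gamma_star)
  phi <- pmin(j_true / (sc$s * PAR), 0.82)
  npq_t <- npq_trajectory(t, sc$npq)
  fmp <- sc$fm_dark / (1 + npq_t)
  f_op <- fmp * (1 - phi)
  fluor_at <- c(-60, seq(60, min(600, sc$duration_s), by = 60),
                if (sc$duration_s > 600) seq(720, sc$duration_s, by = 120))
  keep <- t %in% fluor_at
  clean <- data.frame(time_s = t, A = st$A, gs = gs, Ci = st$Ci, Ca = sc$Ca,
                      PAR = PAR, VPD = sc$vpd, O2 = sc$O2,
                      F = ifelse(keep, f_op, NA_real_),
                      Fm_prime = ifelse(keep, fmp, NA_real_),
                      Fo = ifelse(keep, sc$fo_dark, NA_real_),
                      Fm = ifelse(keep, sc$fm_dark, NA_real_))
  clean_trace <- induction_trace(clean, sc$genotype, sc$treatment,
                                 validate = FALSE)
  truth <- list(scenario = sc, trace = clean_trace,
                metrics = induction_metrics(clean_trace))
  noisy <- clean
  nz <- sc$noise
  if (!is.null(nz) && (nz$A > 0 || nz$gs > 0 || nz$Ci > 0 ||
                       nz$fluor_rel > 0)) {
    n <- nrow(clean)
    noisy <- with_seed(sc$seed, {
      out <- clean
      out$A  <- out$A + stats::rnorm(n, 0, nz$A)
      out$gs <- pmax(out$gs + stats::rnorm(n, 0, nz$gs), 1e-4)
      out$Ci <- out$Ci + stats::rnorm(n, 0, nz$Ci)
      out$F <- out$F * (1 + stats::rnorm(n, 0, nz$fluor_rel))
      out$Fm_prime <- pmax(out$Fm_prime * (1 + stats::rnorm(n, 0, nz$fluor_rel)),
                           out$F)
      out
    })
  }
  list(trace = induction_trace(noisy, sc$genotype, sc$treatment,
                               validate = FALSE),
       truth = truth)
}

#' Simulate a steady-state response curve
#'
#' Steady-state samples at fully activated biochemistry: an A/Ci curve steps
#' chamber CO2 at fixed high PAR, an A/PAR curve steps irradiance at fixed
#' Ca. Low-oxygen modes suppress photorespiration by scaling the oxygen
#' partial pressure and Gamma* proportionally with O2. Fluorescence is
#' generated by the same demand-model inversion as [simulate_induction()],
#' so calibration and fitting stages round-trip on noise-free output. With
#' `noise = TRUE` the scenario's per-channel noise is applied, scaled by
#' `1/sqrt(6)` to reflect the 30-s / 5-s steady-state logging average.
#'
#' @param sc a [sim_scenario].
#' @param mode `"ACI"` or `"APAR"`.
#' @param levels Ca steps (ubar) for `"ACI"`; PAR steps for `"APAR"`.
#' @param O2 oxygen mole percentage of the measurement.
#' @param Ca chamber CO2 for `"APAR"` mode (protocol default 2000 ubar).
#' @param noise apply (averaged) measurement noise?
#' @return A [response_curve] with fluorescence columns.
#' @export
simulate_response_curve <- function(sc, mode = c("ACI", "APAR"),
                                    levels = NULL, O2 = 21, Ca = 2000,
                                    noise = FALSE) {
  mode <- match.arg(mode)
  p <- eff_params(sc$fvcb, O2)
  if (is.null(levels))
    levels <- if (mode == "ACI")
      c(50, 70, 100, 130, 200, 300, 400, 600, 750, 900, 1100, 1400, 1700, 2000)
    else c(200, 150, 100, 70, 50, 30)
  if (mode == "ACI") { Ca_v <- levels; PAR_v <- rep_len(sc$par_high, length(levels)) }
  else { Ca_v <- rep_len(Ca, length(levels)); PAR_v <- levels }
  Jmax <- jmax_for(sc$fvcb$J1500, sc$alpha, sc$theta)
  J <- nrh_j(PAR_v, sc$alpha, Jmax, sc$theta)
  st <- aci_with_supply(p, gs = sc$gs_f, Ca = Ca_v, gm = sc$gm, J = J,
                        gb = sc$gb)
  j_true <- 4 * (st$A + p$Rd) * (st$Cc + 2 * p$gamma_star) /
    (st$Cc - p$gamma_star)
  phi <- pmin(j_true / (sc$s * PAR_v), 0.82)
  npq_ss <- ifelse(PAR_v >= 1000, 1.5, 0.2)
  fmp <- sc$fm_dark / (1 + npq_ss)
  d <- data.frame(time_s = seq_along(levels), A = st$A, gs = sc$gs_f,
                  Ci = st$Ci, Ca = Ca_v, PAR = PAR_v, VPD = sc$vpd, O2 = O2,
                  F = fmp * (1 - phi), Fm_prime = fmp,
                  Fo = sc$fo_dark, Fm = sc$fm_dark)
  if (noise) {
    nz <- sc$noise
    k <- sqrt(6)                    # steady-state logging average
    d <- with_seed(sc$seed, {
      n <- nrow(d)
      d$A <- d$A + stats::rnorm(n, 0, nz$A / k)
      d$Ci <- d$Ci + stats::rnorm(n, 0, nz$Ci / k)
      d$F <- d$F * (1 + stats::rnorm(n, 0, nz$fluor_rel / k))
      d$Fm_prime <- pmax(d$Fm_prime * (1 + stats::rnorm(n, 0, nz$fluor_rel / k)),
                         d$F)
      d
    })
  }
  response_curve(d, mode = mode, O2 = O2, validate = FALSE)
}
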