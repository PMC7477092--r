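#' FvCB demand-model parameter set
#'
#' Parameters of the steady-state Farquhar-von Caemmerer-Berry model of C3
#' photosynthesis at 25 degC. `Vcmax` is the maximum carboxylation rate,
#' `J1500` the linear electron transport rate at the 1500 umol m-2 s-1
#' measuring irradiance, `TPU` the triose-phosphate utilization capacity and
#' `Rd` day (mitochondrial) respiration, all umol m-2 s-1. Kinetic constants
#' default to the standard 25 degC set used by A/Ci fitting tools:
#' `Kc` = 404.9 ubar, `Ko` = 278.4 mbar, `gamma_star` = 42.75 ubar, oxygen
#' partial pressure `O` = 210 mbar (21%); no temperature response is applied.
#'
#' @param Vcmax,J1500,TPU,Rd demand-side rates, umol m-2 s-1 (`Rd` is the
#'   magnitude of respiration in the light, >= 0).
#' @param gamma_star CO2 photocompensation point without Rd, ubar.
#' @param Kc,Ko Michaelis constants for CO2 (ubar) and O2 (mbar).
#' @param O oxygen partial pressure, mbar.
#' @return List of class `fvcb_params`.
#' @export
fvcb_params <- function(Vcmax = 100, J1500 = 160, TPU = 10, Rd = 1,
                        gamma_star = 42.75, Kc = 404.9, Ko = 278.4, O = 210) {
  stopifnot(Vcmax > 0, J1500 > 0, TPU > 0, Rd >= 0,
            gamma_star > 0, Kc > 0, Ko > 0, O >= 0)
  structure(list(Vcmax = Vcmax, J1500 = J1500, TPU = TPU, Rd = Rd,
                 gamma_star = gamma_star, Kc = Kc, Ko = Ko, O = O),
            class = "fvcb_params")
}

# gross limitation hypotheses at chloroplastic CO2 Cc (vectorized)
fvcb_gross <- function(Cc, p, J = p$J1500) {
  Km <- p$Kc * (1 + p$O / p$Ko)
  Ac <- p$Vcmax * (Cc - p$gamma_star) / (Cc + Km)
  Aj <- J * (Cc - p$gamma_star) / (4 * Cc + 8 * p$gamma_star)
  Ap <- rep_len(3 * p$TPU, length(Cc))
  cbind(Rubisco = Ac, RuBP = Aj, TPU = Ap)
}

#' Net assimilation predicted by the FvCB demand model
#'
#' `A = min(Ac, Aj, Ap) - Rd` with
#' `Ac = Vcmax (Cc - G*) / (Cc + Kc (1 + O/Ko))`,
#' `Aj = J (Cc - G*) / (4 Cc + 8 G*)`, and `Ap = 3 TPU`. Ties between
#' hypotheses are labelled in the order Rubisco, RuBP, TPU.
#'
#' @param Cc chloroplastic CO2 partial pressure, ubar (> 0); vectorized.
#' @param p an [fvcb_params] object.
#' @param J electron transport rate to use for the RuBP-limited hypothesis
#'   (defaults to `p$J1500`).
#' @param regime also return the limiting regime per point?
#' @return Net A (umol m-2 s-1), or a data frame with columns `A`, `regime`.
#' @export
demand_a <- function(Cc, p, J = p$J1500, regime = FALSE) {
  if (any(!is.finite(Cc)) || any(Cc <= 0))
    stop_photoinduct("Cc must be positive", "photoinduct_domain_error")
  g <- fvcb_gross(Cc, p, J)
  A <- unname(pmin(g[, 1L], g[, 2L], g[, 3L])) - p$Rd
  if (!regime) return(A)
  lab <- colnames(g)[max.col(-g, ties.method = "first")]
  data.frame(A = A, regime = lab)
}

#' Steady-state supply-demand intersection
#'
#' Solves the coupled system `A = (Ca - Ci) / (1.6/gs + 1.37/gb)`,
#' `Cc = Ci - A/gm`, `A = demand_a(Cc)` for the unique fixed point. The
#' default `gb = Inf` gives the pure stomatal supply `A = (gs/1.6)(Ca - Ci)`;
#' a finite leaf boundary-layer conductance `gb` (mol m-2 s-1, to water
#' vapour) adds the series term used by clamp-on chambers. The solver
#' bisects on A over `[-Rd, (Ca - G*) / r_total]`, across which the residual
#' `demand - A` changes sign exactly once (supply is decreasing and demand
#' non-decreasing in Cc); fully vectorized over samples.
#'
#' @param p an [fvcb_params] object.
#' @param gs stomatal conductance to water vapour, mol m-2 s-1 (> 0).
#' @param Ca chamber CO2 partial pressure, ubar (> gamma_star).
#' @param gm mesophyll conductance, mol m-2 s-1 (> 0; `Inf` for Cc = Ci).
#' @param J electron transport rate (vectorized, defaults to `p$J1500`).
#' @param Vcmax optional override of `p$Vcmax` (vectorized; used by the
#'   simulator's activation dynamics).
#' @param TPU optional override of `p$TPU` (vectorized).
#' @param gb boundary-layer conductance to water vapour, mol m-2 s-1.
#' @param tol absolute tolerance on A, umol m-2 s-1.
#' @return Data frame with columns `A`, `Ci`, `Cc`.
#' @export
aci_with_supply <- function(p, gs, Ca, gm = Inf, J = p$J1500,
                            Vcmax = p$Vcmax, TPU = p$TPU, gb = Inf,
                            tol = 1e-10) {
  stopifnot(all(gs > 0), all(gm > 0))
  if (any(Ca <= p$gamma_star))
    stop_photoinduct("Ca must exceed gamma_star", "photoinduct_domain_error")
  n <- max(length(gs), length(Ca), length(J), length(Vcmax), length(TPU))
  gs <- rep_len(gs, n); Ca <- rep_len(Ca, n); J <- rep_len(J, n)
  Vcmax <- rep_len(Vcmax, n); TPU <- rep_len(TPU, n)
  r  <- 1.6 / gs + 1.37 / gb     # CO2 transfer resistance, m2 s mol-1
  rm_ <- 1 / gm
  Km <- p$Kc * (1 + p$O / p$Ko)
  g  <- p$gamma_star
  demand <- function(Cc) {
    pmin(Vcmax * (Cc - g) / (Cc + Km),
         J * (Cc - g) / (4 * Cc + 8 * g),
         3 * TPU) - p$Rd
  }
  lo <- rep_len(-p$Rd, n)                 # Cc >= Ca here => demand >= A
  hi <- (Ca - g) / (r + rm_)              # Cc = gamma_star => demand < A
  # residual demand(Cc(A)) - A is strictly decreasing in A on [lo, hi]
  for (i in seq_len(80L)) {
    mid <- (lo + hi) / 2
    f <- demand(Ca - mid * (r + rm_)) - mid
    up <- f > 0
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
    if (max(hi - lo) < tol) break
  }
  A <- (lo + hi) / 2
  data.frame(A = A, Ci = Ca - A * r, Cc = Ca - A * (r + rm_))
}

#' Fit the FvCB demand model to an A/Ci curve
#'
#' Least-squares estimation of `Vcmax`, `J1500`, `TPU` (and optionally `Rd`)
#' from a steady-state A/Ci response. The fit is the deterministic
#' regime-switching linear least-squares scheme: from each point of a 3x3x3
#' multi-start grid, points are assigned to their limiting regime under the
#' current parameters (ties toward Rubisco), each rate is then updated by its
#' closed-form per-regime least-squares solution (a single linear regression
#' when `Rd` is free), and assignment and update alternate until the
#' assignment is stable. The best (lowest SSE) start is returned. Rates whose
#' regime captures no points are unidentifiable from the curve; they are
#' returned at their search bound with a warning and flagged.
#'
#' @param curve a [response_curve] of mode `"ACI"` (or a data frame with
#'   `A` and `Ci` columns).
#' @param cc_source `"Ci"` (default; fit on the instrument's Ci) or `"Cc"`
#'   (convert to chloroplastic CO2 with the fixed `gm` supplied).
#' @param gm mesophyll conductance used when `cc_source = "Cc"`.
#' @param fit_rd estimate `Rd` as a free intercept? If `FALSE`, `Rd` is fixed
#'   at `constants$Rd`.
#' @param constants an [fvcb_params] holding `Rd` and the kinetic constants.
#' @param starts list of numeric grids for the multi-start (defaults span the
#'   plausible crop-leaf range).
#' @param bounds named list of `c(lower, upper)` per rate.
#' @return List of class `fvcb_fit`: `params` ([fvcb_params]), `regime`
#'   (factor per point), `SSE`, `converged`, `identifiable` (named logical),
#'   `n`, `fitted`.
#' @export
fit_aci <- function(curve, cc_source = c("Ci", "Cc"), gm = NULL,
                    fit_rd = FALSE, constants = fvcb_params(),
                    starts = list(Vcmax = c(40, 90, 150),
                                  J1500 = c(80, 160, 250),
                                  TPU = c(5, 10, 15)),
                    bounds = list(Vcmax = c(1, 600), J1500 = c(1, 1200),
                                  TPU = c(0.1, 120), Rd = c(0, 10))) {
  cc_source <- match.arg(cc_source)
  d <- as.data.frame(curve)
  if (nrow(d) < 4L + fit_rd)
    stop_photoinduct("under-determined: need more points than free parameters",
                     "photoinduct_fit_error")
  Cc <- if (cc_source == "Cc") {
    if (is.null(gm)) stop_photoinduct("cc_source = 'Cc' requires gm",
                                      "photoinduct_fit_error")
    d$Ci - d$A / gm
  } else d$Ci
  if (any(Cc <= 0))
    stop_photoinduct("non-positive Cc in curve", "photoinduct_domain_error")
  A <- d$A
  g <- constants$gamma_star
  Km <- constants$Kc * (1 + constants$O / constants$Ko)
  # per-point basis functions: gross rate = theta_r * phi_r in each regime
  phi <- cbind(Rubisco = (Cc - g) / (Cc + Km),
               RuBP    = (Cc - g) / (4 * Cc + 8 * g),
               TPU     = rep_len(3, length(Cc)))

  rate_names <- c("Vcmax", "J1500", "TPU")   # parameter behind each regime
  assign_regime <- function(th) {
    gross <- sweep(phi, 2L, c(th["Vcmax"], th["J1500"], th["TPU"]), `*`)
    max.col(-gross, ties.method = "first")
  }
  clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])
  refit <- function(reg, th) {
    rd <- th["Rd"]
    if (fit_rd) {
      pres <- sort(unique(reg))
      X <- sapply(pres, function(k) ifelse(reg == k, phi[, k], 0))
      X <- cbind(matrix(X, ncol = length(pres)), Rd = -1)
      cf <- tryCatch(stats::lsfit(X, A, intercept = FALSE)$coefficients,
                     error = function(e) NULL)
      if (!is.null(cf)) {
        th[rate_names[pres]] <- cf[seq_along(pres)]
        th["Rd"] <- cf[length(cf)]
      }
    } else {
      for (k in 1:3) {
        sel <- reg == k
        if (any(sel))
          th[rate_names[k]] <-
            sum(phi[sel, k] * (A[sel] + rd)) / sum(phi[sel, k]^2)
      }
    }
    th["Vcmax"] <- clamp(th["Vcmax"], bounds$Vcmax)
    th["J1500"] <- clamp(th["J1500"], bounds$J1500)
    th["TPU"]   <- clamp(th["TPU"], bounds$TPU)
    th["Rd"]    <- clamp(th["Rd"], bounds$Rd)
    th
  }
  sse_of <- function(th) {
    gross <- sweep(phi, 2L, c(th["Vcmax"], th["J1500"], th["TPU"]), `*`)
    sum((A - (pmin(gross[, 1], gross[, 2], gross[, 3]) - th["Rd"]))^2)
  }

  grid <- expand.grid(Vcmax = starts$Vcmax, J1500 = starts$J1500,
                      TPU = starts$TPU)
  start_list <- lapply(seq_len(nrow(grid)), function(i)
    c(Vcmax = grid$Vcmax[i], J1500 = grid$J1500[i], TPU = grid$TPU[i],
      Rd = constants$Rd))
  # regimes are ordered along Cc (Rubisco -> RuBP -> TPU), so candidate
  # solutions can be enumerated from all monotone two-cut partitions of the
  # Cc-sorted points; each yields closed-form per-segment rates
  ord <- order(Cc)
  nn <- length(A)
  for (i_cut in 0:nn) for (j_cut in i_cut:nn) {
    th <- c(Vcmax = mean(starts$Vcmax), J1500 = mean(starts$J1500),
            TPU = mean(starts$TPU), Rd = constants$Rd)
    seg <- rep(3L, nn)
    if (i_cut > 0) seg[ord[1:i_cut]] <- 1L
    if (j_cut > i_cut) seg[ord[(i_cut + 1):j_cut]] <- 2L
    for (k in 1:3) {
      sel <- seg == k
      if (any(sel))
        th[rate_names[k]] <- pmin(pmax(
          sum(phi[sel, k] * (A[sel] + th["Rd"])) / sum(phi[sel, k]^2),
          bounds[[rate_names[k]]][1]), bounds[[rate_names[k]]][2])
    }
    start_list[[length(start_list) + 1L]] <- th
  }
  best <- NULL
  for (i in seq_along(start_list)) {
    th <- start_list[[i]]
    reg <- assign_regime(th)
    stable <- FALSE
    for (it in seq_len(60L)) {
      th <- refit(reg, th)
      reg2 <- assign_regime(th)
      if (identical(reg2, reg)) { stable <- TRUE; break }
      reg <- reg2
    }
    s <- sse_of(th)
    if (is.null(best) || s < best$SSE - 1e-12)
      best <- list(theta = th, regime = reg, SSE = s, stable = stable)
  }

  reg <- best$regime
  th <- best$theta
  # a rate is identifiable only if excluding its regime costs fit quality:
  # refit with the hypothesis banned and compare SSEs
  sse_without <- function(ban) {
    th_b <- th
    reg_b <- NULL
    keep <- setdiff(1:3, ban)
    for (it in seq_len(60L)) {
      gross <- sweep(phi[, keep, drop = FALSE], 2L,
                     c(th_b["Vcmax"], th_b["J1500"], th_b["TPU"])[keep], `*`)
      reg_new <- keep[max.col(-gross, ties.method = "first")]
      if (identical(reg_new, reg_b)) break
      reg_b <- reg_new
      th_b <- refit(reg_b, th_b)
    }
    gross <- sweep(phi[, keep, drop = FALSE], 2L,
                   c(th_b["Vcmax"], th_b["J1500"], th_b["TPU"])[keep], `*`)
    sum((A - (do.call(pmin, as.data.frame(gross)) - th_b["Rd"]))^2)
  }
  identifiable <- c(Vcmax = TRUE, J1500 = TRUE, TPU = TRUE)
  for (k in 1:3)
    identifiable[k] <- any(reg == k) &&
      sse_without(k) > best$SSE + max(1e-7, 1e-3 * best$SSE)
  if (!identifiable["TPU"]) th["TPU"] <- bounds$TPU[2]
  if (!identifiable["J1500"]) th["J1500"] <- bounds$J1500[2]
  if (!identifiable["Vcmax"]) th["Vcmax"] <- bounds$Vcmax[2]
  if (!all(identifiable))
    warning("unidentifiable parameter(s) returned at bounds: ",
            paste(names(identifiable)[!identifiable], collapse = ", "),
            call. = FALSE)
  # converged only if the assignment is stable and no small parameter step
  # decreases the SSE (a descent test; the objective is kinked at regime
  # boundaries, so a gradient is not defined there)
  grad_ok <- TRUE
  sse_here <- sse_of(th)
  for (nm in names(th)[c(identifiable, fit_rd)]) {
    h <- 1e-5 * max(1, abs(th[nm]))
    for (sgn in c(-1, 1)) {
      thp <- th; thp[nm] <- th[nm] + sgn * h
      if (sse_of(thp) < sse_here - 1e-7 * max(1, sse_here)) grad_ok <- FALSE
    }
  }
  params <- fvcb_params(Vcmax = th[["Vcmax"]], J1500 = th[["J1500"]],
                        TPU = th[["TPU"]], Rd = th[["Rd"]],
                        gamma_star = g, Kc = constants$Kc, Ko = constants$Ko,
                        O = constants$O)
  gross <- sweep(phi, 2L, c(th["Vcmax"], th["J1500"], th["TPU"]), `*`)
  structure(list(params = params,
                 regime = factor(colnames(phi)[reg], levels = colnames(phi)),
                 SSE = best$SSE,
                 converged = best$stable && grad_ok,
                 identifiable = identifiable,
                 n = length(A),
                 fitted = pmin(gross[, 1], gross[, 2], gross[, 3]) - th["Rd"]),
            class = "fvcb_fit")
}

#' @export
print.fvcb_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "FvCB fit (n = %d): Vcmax = %.2f, J1500 = %.2f, TPU = %.2f, Rd = %.2f\n",
    x$n, p$Vcmax, p$J1500, p$TPU, p$Rd))
  cat(sprintf("SSE = %.4g; converged: %s; regimes: %s\n", x$SSE, x$converged,
              paste(sprintf("%s=%d", levels(x$regime), table(x$regime)),
                    collapse = " ")))
  invisible(x)
}
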