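test_that("demand model evaluates the three limitations correctly", {
  p <- fvcb_params(Vcmax = 100, J1500 = 160, TPU = 10, Rd = 1,
                   gamma_star = 40, Kc = 405, Ko = 278, O = 210)
  # at the photocompensation point the gross terms vanish: A = -Rd
  expect_equal(demand_a(p$gamma_star, p), -1)
  # Rubisco-limited branch, evaluated by hand
  ac <- 100 * (200 - 40) / (200 + 405 * (1 + 210 / 278))
  expect_equal(demand_a(200, p), ac - 1)
  # RuBP-limited asymptote: A -> J/4 - Rd as Cc -> Inf with TPU huge
  p2 <- fvcb_params(Vcmax = 1e5, J1500 = 160, TPU = 1e5, Rd = 1)
  expect_equal(demand_a(1e7, p2), 160 / 4 - 1, tolerance = 1e-4)
  # TPU plateau
  p3 <- fvcb_params(Vcmax = 1e4, J1500 = 1e4, TPU = 10, Rd = 1)
  expect_equal(demand_a(2000, p3), 29)
  expect_error(demand_a(-5, p), class = "photoinduct_domain_error")
})

test_that("demand is non-decreasing in Cc and regimes are ordered", {
  p <- fvcb_params(Vcmax = 120, J1500 = 180, TPU = 9, Rd = 1.2)
  cc <- seq(50, 2500, by = 10)
  d <- demand_a(cc, p, regime = TRUE)
  expect_true(all(diff(d$A) >= -1e-12))
  # Rubisco -> RuBP -> TPU in that order as Cc rises
  ord <- as.integer(factor(d$regime, levels = c("Rubisco", "RuBP", "TPU")))
  expect_true(all(diff(ord) >= 0))
})

test_that("supply-demand intersection satisfies its defining identities", {
  p <- fvcb_params(Vcmax = 120, J1500 = 180, TPU = 12, Rd = 1)
  out <- aci_with_supply(p, gs = 0.4, Ca = 400, gm = 0.3)
  # supply identity to high precision
  expect_equal(out$A, (0.4 / 1.6) * (400 - out$Ci), tolerance = 1e-8)
  # fixed-point residual: demand at Cc equals A
  expect_equal(demand_a(out$Cc, p), out$A, tolerance = 1e-8)
  # no diffusion limitation: Ci = Cc = Ca
  free <- aci_with_supply(p, gs = 1e8, Ca = 400, gm = 1e8)
  expect_equal(free$Ci, 400, tolerance = 1e-4)
  expect_equal(free$A, demand_a(400, p), tolerance = 1e-6)
  # halving gs strictly lowers Ci and A on the rising part of the curve
  half <- aci_with_supply(p, gs = 0.2, Ca = 400, gm = 0.3)
  expect_lt(half$Ci, out$Ci)
  expect_lt(half$A, out$A)
  expect_error(aci_with_supply(p, gs = 0.4, Ca = 30, gm = 0.3),
               class = "photoinduct_domain_error")
})

test_that("supply-demand solver agrees with a brute-force grid solve", {
  p <- fvcb_params(Vcmax = 140, J1500 = 200, TPU = 11, Rd = 1.3)
  for (gs in c(0.1, 0.35, 0.9)) {
    out <- aci_with_supply(p, gs = gs, Ca = 400, gm = 0.25)
    ci_grid <- seq(p$gamma_star + 1, 400, by = 0.001)
    resid <- (gs / 1.6) * (400 - ci_grid) -
      demand_a(pmax(ci_grid - (gs / 1.6) * (400 - ci_grid) / 0.25, 1), p)
    ci_bf <- ci_grid[which.min(abs(resid))]
    expect_equal(out$Ci, ci_bf, tolerance = 1e-3)
  }
})

test_that("noise-free A/Ci curves return the generating parameters", {
  ci <- c(50, 80, 120, 170, 230, 300, 400, 600, 800, 1100, 1500, 2000)
  # parameter sets whose regimes all claim parts of this Ci grid
  cases <- list(c(100, 160, 12), c(70, 130, 10), c(120, 190, 13))
  for (cs in cases) {
    p <- fvcb_params(Vcmax = cs[1], J1500 = cs[2], TPU = cs[3], Rd = 1.1)
    d <- data.frame(time_s = seq_along(ci), A = demand_a(ci, p), gs = 0.5,
                    Ci = ci, Ca = ci, PAR = 1500, VPD = 7, O2 = 21)
    fit <- suppressWarnings(
      fit_aci(response_curve(d, "ACI", validate = FALSE), constants = p))
    for (k in 1:3)
      if (fit$identifiable[[k]])
        expect_lt(abs(fit$params[[c("Vcmax", "J1500", "TPU")[k]]] / cs[k] - 1),
                  1e-3)
    expect_true(all(fit$identifiable))   # these grids inform every rate
    expect_lt(fit$SSE, 1e-10)
    expect_true(fit$converged)
  }
})

test_that("fitting with free Rd recovers the intercept as well", {
  ci <- c(50, 80, 120, 170, 230, 300, 400, 600, 800, 1100, 1500, 2000)
  p <- fvcb_params(Vcmax = 110, J1500 = 160, TPU = 12, Rd = 1.7)
  d <- data.frame(time_s = seq_along(ci), A = demand_a(ci, p), gs = 0.5,
                  Ci = ci, Ca = ci, PAR = 1500, VPD = 7, O2 = 21)
  fit <- fit_aci(response_curve(d, "ACI", validate = FALSE), fit_rd = TRUE,
                 constants = fvcb_params(Rd = 0.5))
  expect_equal(fit$params$Rd, 1.7, tolerance = 1e-6)
  expect_equal(fit$params$Vcmax, 110, tolerance = 1e-4)
})

test_that("curves that never leave the Rubisco regime flag the other rates", {
  p <- fvcb_params(Vcmax = 80, J1500 = 250, TPU = 20, Rd = 1)
  ci <- seq(50, 250, by = 40)                 # all below the Ac/Aj transition
  d <- data.frame(time_s = seq_along(ci), A = demand_a(ci, p), gs = 0.5,
                  Ci = ci, Ca = ci, PAR = 1500, VPD = 7, O2 = 21)
  expect_warning(
    fit <- fit_aci(response_curve(d, "ACI", validate = FALSE), constants = p),
    "unidentifiable")
  expect_false(fit$identifiable[["TPU"]])
  expect_true(fit$identifiable[["Vcmax"]])
  expect_lt(abs(fit$params$Vcmax / 80 - 1), 1e-3)
})

test_that("fit objective never regresses below any multi-start seed", {
  sc <- quiet_scenario()
  cur <- simulate_response_curve(sc, "ACI")
  d <- as.data.frame(cur)
  set.seed(7)
  d$A <- d$A + rnorm(nrow(d), 0, 0.5)
  fit <- fit_aci(response_curve(d, "ACI", validate = FALSE),
                 cc_source = "Cc", gm = sc$gm, constants = sc$fvcb)
  # SSE at the optimum is no worse than at any start of the 3x3x3 grid
  g <- sc$fvcb$gamma_star
  Km <- sc$fvcb$Kc * (1 + sc$fvcb$O / sc$fvcb$Ko)
  cc <- d$Ci - d$A / sc$gm
  for (v in c(40, 90, 150)) for (j in c(80, 160, 250)) for (tp in c(5, 10, 15)) {
    pred <- pmin(v * (cc - g) / (cc + Km),
                 j * (cc - g) / (4 * cc + 8 * g), 3 * tp) - sc$fvcb$Rd
    expect_lte(fit$SSE, sum((d$A - pred)^2) + 1e-9)
  }
})
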