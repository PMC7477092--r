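test_that("fixed seeds make simulated output bitwise reproducible", {
  sc <- preset_scenario("WT", "control", seed = 42)
  a <- simulate_induction(sc)
  b <- simulate_induction(sc)
  expect_identical(a$trace, b$trace)
  expect_identical(a$truth$metrics, b$truth$metrics)
  # different seed, different noise
  sc2 <- preset_scenario("WT", "control", seed = 43)
  expect_false(identical(simulate_induction(sc2)$trace, a$trace))
})

test_that("ground truth equals metrics recomputed on the noise-free trace", {
  sim <- simulate_induction(preset_scenario("flacca", "high_vpd", seed = 5))
  expect_identical(sim$truth$metrics, induction_metrics(sim$truth$trace))
})

test_that("a scenario without dynamics is flat after the step", {
  sc <- quiet_scenario()
  sc$gs_f <- sc$gs_i
  sc$act_R0 <- 1; sc$act_J0 <- 1
  tr <- simulate_induction(sc)$trace
  post <- tr$A[tr$time_s >= 0]
  expect_lt(diff(range(post)), 1e-6)
})

test_that("preset steady-state endpoints reproduce the reference table", {
  # wildtype control: all six endpoints pinned within 5%
  m <- simulate_induction(quiet_scenario("WT", "control"))$truth
  tr <- m$trace
  expect_equal(m$metrics$Ai, 2.0, tolerance = 0.05 * 2.0)
  expect_equal(m$metrics$Af, 26.0, tolerance = 0.05 * 26)
  expect_equal(m$metrics$gs_initial, 0.22, tolerance = 0.05 * 0.22)
  expect_equal(m$metrics$gs_final, 0.60, tolerance = 0.05 * 0.60)
  expect_equal(steady_window_mean(tr, c(-300, -1), "Ci"), 379,
               tolerance = 0.05 * 379)
  expect_equal(steady_window_mean(tr, c(3300, 3600), "Ci"), 311,
               tolerance = 0.05 * 311)
  # flacca control: conductance endpoints pinned within 5%
  mf <- simulate_induction(quiet_scenario("flacca", "control"))$truth$metrics
  expect_equal(mf$gs_initial, 0.62, tolerance = 0.05 * 0.62)
  expect_equal(mf$gs_final, 1.03, tolerance = 0.05 * 1.03)
  # initial conductances across environments
  expect_equal(preset_scenario("WT", "high_vpd")$gs_i, 0.14, tolerance = 1e-9)
  expect_equal(preset_scenario("WT", "low_co2")$gs_i, 0.34, tolerance = 1e-9)
  expect_equal(preset_scenario("flacca", "high_vpd")$gs_i, 0.58,
               tolerance = 1e-9)
})

test_that("simulated A/Ci curves round-trip through the FvCB fit", {
  sc <- quiet_scenario()
  cur <- simulate_response_curve(sc, "ACI")
  expect_true(all(diff(cur$Ca) > 0))
  fit <- fit_aci(cur, cc_source = "Cc", gm = sc$gm, constants = sc$fvcb)
  expect_lt(abs(fit$params$Vcmax / sc$fvcb$Vcmax - 1), 1e-3)
  expect_lt(abs(fit$params$J1500 / sc$fvcb$J1500 - 1), 1e-3)
  expect_lt(abs(fit$params$TPU / sc$fvcb$TPU - 1), 1e-3)
  # A non-decreasing in Ca below the TPU region
  reg <- demand_a(cur$Ci - cur$A / sc$gm, sc$fvcb, regime = TRUE)$regime
  below <- reg != "TPU"
  expect_true(all(diff(cur$A[below]) > -1e-9))
})

test_that("simulated low-oxygen A/PAR curves round-trip through fit_rd_s", {
  sc <- quiet_scenario()
  apar <- simulate_response_curve(sc, "APAR", O2 = 2)
  fit <- fit_rd_s(apar)
  expect_lt(abs(fit$s / sc$s - 1), 0.02)
  expect_lt(abs(fit$Rd / sc$fvcb$Rd - 1), 0.05)
  expect_gt(fit$r_squared, 0.9999)
})

test_that("t90 falls with initial conductance and flattens above 0.4", {
  gsi <- c(0.1, 0.15, 0.2, 0.3, 0.4, 0.5, 0.6, 0.8)
  t90 <- vapply(gsi, function(g) {
    sc <- quiet_scenario()
    sc$gs_i <- g
    sc$gs_f <- 0.85
    simulate_induction(sc)$truth$metrics$t90
  }, numeric(1))
  expect_true(all(diff(t90) < 0.05))      # non-increasing (one-sample slack)
  slope_low <- (t90[1] - t90[5]) / (0.4 - 0.1)
  slope_high <- (t90[5] - t90[8]) / (0.8 - 0.4)
  expect_lt(slope_high, 0.4 * slope_low)  # plateau beyond 0.4 mol m-2 s-1
})

test_that("genotype orderings hold across noisy replicates", {
  n_rep <- 30
  t90_of <- function(genotype, treatment, seeds, gs_i = NULL) {
    vapply(seeds, function(sd) {
      sc <- preset_scenario(genotype, treatment, seed = sd)
      if (!is.null(gs_i)) sc$gs_i <- gs_i
      induction_metrics(simulate_induction(sc)$trace)$t90
    }, numeric(1))
  }
  seeds <- seq_len(n_rep)
  wt_c <- t90_of("WT", "control", seeds)
  flc_c <- t90_of("flacca", "control", seeds + 1000)
  wt_v <- t90_of("WT", "high_vpd", seeds + 2000)
  flc_v <- t90_of("flacca", "high_vpd", seeds + 3000)
  # flacca induces faster under control and high VPD, replicate by replicate
  expect_gt(mean(wt_c), mean(flc_c))
  expect_gt(mean(wt_v), mean(flc_v))
  expect_gt(mean(wt_c > flc_c), 0.95)
  expect_gt(mean(wt_v > flc_v), 0.95)
  # low CO2 narrows the gap, and only because wildtype initial gs rises
  wt_l <- t90_of("WT", "low_co2", seeds + 4000)
  flc_l <- t90_of("flacca", "low_co2", seeds + 5000)
  gap_control <- mean(wt_c) - mean(flc_c)
  gap_low <- mean(wt_l) - mean(flc_l)
  expect_lt(gap_low, 0.65 * gap_control)
  wt_l_fixed <- t90_of("WT", "low_co2", seeds + 6000, gs_i = 0.22)
  expect_gt(mean(wt_l_fixed) - mean(flc_l), gap_low)
})

test_that("flacca runs wetter but assimilates more early on", {
  wt <- simulate_induction(quiet_scenario("WT"))$trace
  flc <- simulate_induction(quiet_scenario("flacca"))$trace
  # WUEi lower in flacca at every timepoint
  expect_true(all(wue_i(flc$A, flc$gs) < wue_i(wt$A, wt$gs)))
  expect_gt(integrate_window(flc, "A"), integrate_window(wt, "A"))
  expect_gt(integrate_window(flc, "Ci"), integrate_window(wt, "Ci"))
})
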