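test_that("induction fraction hits its endpoints and is affine-invariant", {
  tr <- make_exp_trace(tau_min = 4, Ai = 2, dA = 24)
  ps <- induction_fraction(tr)
  expect_equal(ps$PI[1], 0, tolerance = 0.5)          # A ~ Ai at t = 0
  expect_equal(ps$PI[nrow(ps)], 100, tolerance = 0.5) # A ~ Af at the end
  # the Table-1-style arithmetic: halfway between Ai = 2 and Af = 26 is 50%
  expect_equal((14 - 2) / (26 - 2) * 100, 50)
  # adding a constant to every A leaves PI unchanged
  shifted <- as.data.frame(tr); shifted$A <- shifted$A + 5
  ps2 <- induction_fraction(induction_trace(shifted, validate = FALSE))
  expect_equal(ps2$PI, ps$PI, tolerance = 1e-10)
  # a flat trace has no induction
  flat <- make_exp_trace(dA = 0)
  expect_error(induction_fraction(flat),
               class = "photoinduct_no_induction_error")
})

test_that("crossing times match the exponential closed form", {
  tr <- make_exp_trace(tau_min = 4)
  # analytic endpoints, so the window-mean Af bias does not enter
  ps <- data.frame(time_s = tr$time_s[tr$time_s >= 0])
  ps$PI <- 100 * (1 - exp(-ps$time_s / 240))
  t50 <- time_to_fraction(ps, 50)
  t90 <- time_to_fraction(ps, 90)
  expect_equal(t50, 4 * log(2), tolerance = 0.04)     # 2.773 min
  expect_equal(t90, 4 * log(10), tolerance = 0.04)    # 9.210 min
  expect_equal(t90 / t50, log(10) / log(2), tolerance = 0.02)
  expect_lt(t50, t90)
  expect_error(time_to_fraction(ps, 101),
               class = "photoinduct_undefined_metric_error")
})

test_that("a step crossing is interpolated inside its bracketing interval", {
  ps <- data.frame(time_s = c(0, 2, 4, 6), PI = c(0, 20, 80, 100))
  t50 <- time_to_fraction(ps, 50, smooth_k = 1)
  expect_gt(t50 * 60, 2)
  expect_lt(t50 * 60, 4)
  expect_equal(t50 * 60, 3, tolerance = 1e-10)        # linear interpolation
})

test_that("crossing detection agrees with a brute-force fine-grid scan", {
  sc <- quiet_scenario()
  tr <- simulate_induction(sc)$trace
  ps <- induction_fraction(tr)
  for (target in c(50, 90)) {
    t_pkg <- time_to_fraction(ps, target)
    # brute force on a 10x finer linearly interpolated grid, no smoothing
    fine_t <- seq(0, max(ps$time_s), by = 0.2)
    fine <- approx(ps$time_s, ps$PI, xout = fine_t)$y
    t_bf <- fine_t[which(fine >= target)[1]] / 60
    expect_lt(abs(t_pkg - t_bf), 2 / 60)   # within one sampling interval
  }
})

test_that("WUEi quotients match the steady-state trait arithmetic", {
  expect_equal(wue_i(26.0, 0.60), 43.3, tolerance = 0.01)
  expect_equal(wue_i(28.4, 1.03), 27.6, tolerance = 0.01)
  # wildtype/flacca ratio ~1.6 at these endpoints
  expect_equal(wue_i(26.0, 0.60) / wue_i(28.4, 1.03), 1.57, tolerance = 0.01)
  expect_equal(wue_i(0, 0.3), 0)
  expect_error(wue_i(10, 0), class = "photoinduct_domain_error")
})

test_that("window integrals reproduce textbook areas", {
  t <- seq(-60, 360, by = 2)
  con <- induction_trace(make_samples(length(t), time_s = t, A = 10),
                         validate = FALSE)
  expect_equal(integrate_window(con, "A"), 50)        # 10 umol x 5 min
  ramp <- make_samples(length(t), time_s = t, A = pmax(t, 0) / 30)
  expect_equal(integrate_window(induction_trace(ramp, validate = FALSE), "A"),
               25)                                    # triangle to 10 over 5 min
  short <- induction_trace(make_samples(50, time_s = seq(0, 98, 2)),
                           validate = FALSE)
  expect_error(integrate_window(short, "A"),
               class = "photoinduct_empty_window_error")
  gap <- make_samples(100, time_s = c(seq(0, 58, 2), seq(120, 258, 2)))
  expect_warning(integrate_window(induction_trace(gap, validate = FALSE), "A",
                                  window = c(0, 250)),
                 "gap")
})

test_that("stomatal opening is the difference of the window means", {
  tr <- make_exp_trace()
  so <- stomatal_opening(tr)
  expect_equal(so$delta_gs, 0)                        # constant gs
  sc <- quiet_scenario("WT", "control")
  so_wt <- stomatal_opening(simulate_induction(sc)$trace)
  expect_equal(so_wt$gs_initial, 0.22, tolerance = 1e-6)
  expect_equal(so_wt$delta_gs, 0.38, tolerance = 0.02)
  so_flc <- stomatal_opening(simulate_induction(quiet_scenario("flacca"))$trace)
  expect_equal(so_flc$delta_gs, 0.41, tolerance = 0.02)
})

test_that("Ag vs J curvature recovers polynomial coefficients", {
  J <- seq(20, 180, by = 10)
  lin <- data.frame(A = 0.25 * J - 1, J = J)
  f1 <- suppressWarnings(gross_vs_j(lin, Rd = 1))
  expect_equal(f1$curvature, 0, tolerance = 1e-10)
  expect_equal(f1$linear_r_squared, 1, tolerance = 1e-10)
  quad <- data.frame(A = 0.1 * J + 0.001 * J^2 - 1, J = J)
  f2 <- suppressWarnings(gross_vs_j(quad, Rd = 1))
  expect_equal(f2$curvature, 0.001, tolerance = 1e-10)
  expect_true(f2$upward)
  expect_error(gross_vs_j(data.frame(A = 1:20, J = rep(5, 20)), Rd = 1),
               class = "photoinduct_fit_error")
})

test_that("wildtype transients bend Ag-vs-J upward more than flacca", {
  qj <- function(genotype) {
    tr <- simulate_induction(quiet_scenario(genotype))$trace
    q <- quenching_analysis(tr, s = 0.425)
    d <- merge(as.data.frame(tr)[, c("time_s", "A")], q[, c("time_s", "J")])
    gross_vs_j(d[d$time_s >= 0, ], Rd = 1)
  }
  wt <- qj("WT"); flc <- qj("flacca")
  expect_gt(abs(wt$curvature), abs(flc$curvature))
  expect_gt(flc$linear_r_squared, 0.97)   # flacca stays near-linear
})

test_that("the transient dip is found when present and only then", {
  # monotone trace: absent
  expect_false(detect_dip(make_exp_trace())$present)
  # injected 1 umol m-2 s-1 notch at 1.8 min, on a settled transient (the
  # notch depth is only observable once the underlying rise has levelled)
  tr <- make_exp_trace(tau_min = 0.2)
  d <- as.data.frame(tr)
  notch <- exp(-((d$time_s - 108) / 15)^2)
  d$A <- d$A - 1 * notch
  dip <- detect_dip(induction_trace(d, validate = FALSE))
  expect_true(dip$present)
  expect_equal(dip$time_min, 1.8, tolerance = 0.25)
  expect_equal(dip$depth, 1, tolerance = 0.3)
  # below-threshold notch: absent
  d2 <- as.data.frame(tr); d2$A <- d2$A - 0.3 * notch
  expect_false(detect_dip(induction_trace(d2, validate = FALSE))$present)
  # simulator's TPU-depression mechanism produces a detectable dip
  sc <- quiet_scenario("flacca")
  sc$dip <- list(frac = 0.6, t_center_s = 105, width_s = 30)
  dip_sim <- detect_dip(simulate_induction(sc)$trace)
  expect_true(dip_sim$present)
  expect_gt(dip_sim$time_min, 1)
  expect_lt(dip_sim$time_min, 3)
})
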