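# shared fixtures, all generated in code

# minimal well-formed sample table
make_samples <- function(n = 3, time_s = seq_len(n) - 1, A = 10, gs = 0.3,
                         Ci = 300, Ca = 400, PAR = 1500, VPD = 7, O2 = 21) {
  data.frame(time_s = time_s, A = A, gs = gs, Ci = Ci, Ca = Ca,
             PAR = PAR, VPD = VPD, O2 = O2)
}

# trace following A(t) = Ai + dA * (1 - exp(-t / tau)) after the step
make_exp_trace <- function(tau_min = 4, Ai = 2, dA = 24, dt = 2,
                           pre_s = 300, dur_s = 3600, gs = 0.3) {
  t <- seq(-pre_s, dur_s, by = dt)
  A <- ifelse(t < 0, Ai, Ai + dA * (1 - exp(-t / (tau_min * 60))))
  induction_trace(
    data.frame(time_s = t, A = A, gs = gs, Ci = 300, Ca = 400,
               PAR = ifelse(t < 0, 50, 1500), VPD = 7, O2 = 21),
    validate = FALSE)
}

# noise-free WT-control-like scenario, cheap to rerun
quiet_scenario <- function(genotype = "WT", treatment = "control", ...) {
  sc <- preset_scenario(genotype, treatment, ...)
  sc$noise <- NULL
  sc
}

# forward variable-J model: pick Cc, derive all observables consistently
forward_gm_point <- function(gm, Cc, p = fvcb_params()) {
  A <- demand_a(Cc, p)
  Ci <- Cc + A / gm
  J <- 4 * (A + p$Rd) * (Cc + 2 * p$gamma_star) / (Cc - p$gamma_star)
  list(A = A, Ci = Ci, J = J, Rd = p$Rd, gamma_star = p$gamma_star)
}
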