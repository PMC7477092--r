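#' Photosynthetic induction as percentage of the total change
#'
#' `PI(t) = (A(t) - Ai) / (Af - Ai) * 100` for `t >= 0`, where the initial
#' steady rate `Ai` is the pre-step window mean and the final steady rate
#' `Af` the final-window mean. PI is invariant to adding a constant to all
#' of `A`, `Ai` and `Af`.
#'
#' @param trace an [induction_trace].
#' @param pre_window seconds, window for `Ai` (default the last 5 pre-step
#'   minutes, `c(-300, 0)`; the step sample itself is excluded).
#' @param final_window seconds, window for `Af` (default minutes 55-60).
#' @return Data frame with `time_s`, `PI` (%), and attributes `Ai`, `Af`.
#' @export
induction_fraction <- function(trace, pre_window = c(-300, -1e-9),
                               final_window = c(3300, 3600)) {
  Ai <- steady_window_mean(trace, pre_window, "A")
  Af <- steady_window_mean(trace, final_window, "A")
  if (Af <= Ai)
    stop_photoinduct("Af <= Ai: no induction in trace",
                     "photoinduct_no_induction_error")
  sel <- trace$time_s >= 0
  structure(data.frame(time_s = trace$time_s[sel],
                       PI = (trace$A[sel] - Ai) / (Af - Ai) * 100),
            Ai = Ai, Af = Af)
}

#' Time to reach a target induction fraction
#'
#' Time of the *first* upward crossing of the target PI, with linear
#' interpolation between the bracketing samples. A rolling median (odd
#' width, default 5 samples ~ 10 s at 2-s cadence) is applied before
#' crossing detection so measurement noise cannot trigger spuriously early
#' crossings; the same smoothing is used for every target so t50 and t90
#' are directly comparable, and first-crossing semantics mean a post-peak
#' transient dip cannot inflate the metric.
#'
#' @param pi_series data frame from [induction_fraction()] (columns
#'   `time_s`, `PI`).
#' @param target percent, e.g. 50 or 90.
#' @param smooth_k odd rolling-median width in samples; 1 disables smoothing.
#' @return Time in minutes.
#' @export
time_to_fraction <- function(pi_series, target, smooth_k = 5) {
  t <- pi_series$time_s
  y <- pi_series$PI
  if (smooth_k > 1) y <- stats::runmed(y, smooth_k, endrule = "keep")
  above <- y >= target
  if (!any(above))
    stop_photoinduct(sprintf("PI never reaches %g%%", target),
                     "photoinduct_undefined_metric_error")
  i <- which(above)[1]
  if (i == 1L) return(t[1] / 60)
  # linear interpolation on the bracketing pair
  frac <- (target - y[i - 1]) / (y[i] - y[i - 1])
  (t[i - 1] + frac * (t[i] - t[i - 1])) / 60
}

#' Intrinsic water-use efficiency
#'
#' `WUEi = A / gs`, umol CO2 per mol H2O.
#'
#' @param A net photosynthesis, umol m-2 s-1.
#' @param gs stomatal conductance to water vapour, mol m-2 s-1 (> 0).
#' @return WUEi; vectorized.
#' @export
wue_i <- function(A, gs) {
  if (any(gs <= 0))
    stop_photoinduct("gs must be positive", "photoinduct_domain_error")
  A / gs
}

#' Trapezoidal integral of a field over the early transient
#'
#' Integrates a logged field (typically `A` or `Ci`) over a post-step window,
#' by default the first five minutes, and reports the integral in
#' field-units x minutes. Sampling gaps larger than `max_gap` seconds
#' trigger a warning but the integral is still returned.
#'
#' @param trace an [induction_trace].
#' @param field column to integrate.
#' @param window seconds, default `c(0, 300)`.
#' @param max_gap largest tolerated sampling gap, seconds.
#' @return Integral in field-units x min.
#' @export
integrate_window <- function(trace, field = "A", window = c(0, 300),
                             max_gap = 10) {
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2]
  t <- trace$time_s[sel]
  if (length(t) < 2L ||
      t[1] > window[1] + max_gap || t[length(t)] < window[2] - max_gap)
    stop_photoinduct("samples do not cover the integration window",
                     "photoinduct_empty_window_error")
  if (max(diff(t)) > max_gap)
    warning(sprintf("sampling gap > %g s inside integration window", max_gap),
            call. = FALSE)
  trapz_(t, trace[[field]][sel]) / 60
}

#' Initial and final stomatal conductance and stomatal opening
#'
#' Window means of `gs` before the step and at the end of the transient;
#' stomatal opening is their difference.
#'
#' @inheritParams induction_fraction
#' @return List: `gs_initial`, `gs_final`, `delta_gs` (mol m-2 s-1).
#' @export
stomatal_opening <- function(trace, pre_window = c(-300, -1e-9),
                             final_window = c(3300, 3600)) {
  gi <- steady_window_mean(trace, pre_window, "gs")
  gf <- steady_window_mean(trace, final_window, "gs")
  list(gs_initial = gi, gs_final = gf, delta_gs = gf - gi)
}

#' Curvature of gross photosynthesis against electron transport
#'
#' Gross photosynthesis `Ag = A + Rd` plotted against fluorescence-derived
#' `J` is linear when the carboxylation:oxygenation ratio is constant; a
#' rising chloroplastic CO2 during induction bends the relation upwards.
#' Fits `Ag = a + b J + c J^2` by least squares and reports the curvature
#' `c` with its confidence interval, plus the R^2 of the purely linear fit.
#'
#' @param samples data frame with paired `Ag` predictors: either columns
#'   `A` and `J`, or precomputed via [quenching_analysis()].
#' @param Rd day respiration added to A to form Ag.
#' @param level confidence level for the curvature interval.
#' @return List of class `ag_j_fit`: `curvature`, `ci` (length-2),
#'   `significant` (CI excludes 0), `linear_r_squared`, `n`.
#' @export
gross_vs_j <- function(samples, Rd, level = 0.95) {
  d <- as.data.frame(samples)
  d <- d[stats::complete.cases(d[, c("A", "J")]), ]
  if (nrow(d) < 10L)
    stop_photoinduct("need >= 10 paired (Ag, J) points",
                     "photoinduct_fit_error")
  Ag <- d$A + Rd
  J <- d$J
  if (stats::sd(J) == 0)
    stop_photoinduct("rank-deficient design: J has no spread",
                     "photoinduct_fit_error")
  quad <- stats::lm(Ag ~ J + I(J^2))
  lin <- stats::lm(Ag ~ J)
  ci <- tryCatch(stats::confint(quad, "I(J^2)", level = level),
                 error = function(e) c(NA_real_, NA_real_))
  curv <- unname(stats::coef(quad)["I(J^2)"])
  structure(list(curvature = curv, ci = as.numeric(ci),
                 significant = is.finite(ci[1]) && (ci[1] > 0 || ci[2] < 0),
                 upward = isTRUE(is.finite(ci[1]) && ci[1] > 0),
                 linear_r_squared = summary(lin)$r.squared,
                 n = nrow(d)),
            class = "ag_j_fit")
}

#' Detect the transient assimilation dip
#'
#' Some induction transients show a brief decrease of A (a local maximum
#' followed by a local minimum) one to a few minutes after the step,
#' attributed to a transient mismatch between Calvin-cycle CO2 fixation and
#' downstream sucrose metabolism. On the rolling-median smoothed A this
#' detects, within `window` minutes, a local maximum followed by a local
#' minimum with drop of at least `threshold`; absence is a valid result, not
#' an error.
#'
#' @param trace an [induction_trace].
#' @param window minutes after the step to search, default `c(0.5, 4)`.
#' @param threshold minimum drop, umol m-2 s-1 (default 0.5).
#' @param smooth_k odd rolling-median width in samples.
#' @return List: `present`, `time_min` (of the local minimum, NA if absent),
#'   `depth` (umol m-2 s-1, NA if absent).
#' @export
detect_dip <- function(trace, window = c(0.5, 4), threshold = 0.5,
                       smooth_k = 5) {
  sel <- trace$time_s >= window[1] * 60 & trace$time_s <= window[2] * 60
  t <- trace$time_s[sel]
  y <- trace$A[sel]
  if (length(y) < smooth_k + 2L)
    stop_photoinduct("trace does not cover the dip-search window",
                     "photoinduct_empty_window_error")
  if (smooth_k > 1) y <- stats::runmed(y, smooth_k, endrule = "keep")
  absent <- list(present = FALSE, time_min = NA_real_, depth = NA_real_)
  best <- absent
  run_max <- cummax(y)
  drop <- run_max - y                      # drawdown from running maximum
  if (max(drop) < threshold) return(absent)
  i_min <- which.max(drop)
  # require recovery after the minimum, i.e. it is a genuine local minimum
  if (i_min == length(y) || max(y[i_min:length(y)]) <= y[i_min])
    return(absent)
  best <- list(present = TRUE, time_min = t[i_min] / 60,
               depth = drop[i_min])
  best
}

#' All induction metrics for one trace
#'
#' Convenience wrapper computing the full metric set of a low-to-high
#' irradiance transient: `Ai`, `Af`, `t50`, `t90` (min), stomatal opening,
#' initial/final WUEi, the five-minute integrals of `A` and `Ci`, and the
#' transient-dip descriptor.
#'
#' @inheritParams induction_fraction
#' @param smooth_k rolling-median width for crossing detection.
#' @param dip_threshold minimum dip depth, umol m-2 s-1.
#' @return One-row data frame.
#' @export
induction_metrics <- function(trace, pre_window = c(-300, -1e-9),
                              final_window = c(3300, 3600), smooth_k = 5,
                              dip_threshold = 0.5) {
  pi_s <- induction_fraction(trace, pre_window, final_window)
  so <- stomatal_opening(trace, pre_window, final_window)
  dip <- detect_dip(trace, threshold = dip_threshold, smooth_k = smooth_k)
  Ai <- attr(pi_s, "Ai"); Af <- attr(pi_s, "Af")
  data.frame(
    genotype = attr(trace, "genotype") %||% NA_character_,
    treatment = attr(trace, "treatment") %||% NA_character_,
    Ai = Ai, Af = Af,
    t50 = time_to_fraction(pi_s, 50, smooth_k),
    t90 = time_to_fraction(pi_s, 90, smooth_k),
    gs_initial = so$gs_initial, gs_final = so$gs_final,
    delta_gs = so$delta_gs,
    wuei_initial = wue_i(Ai, so$gs_initial),
    wuei_final = wue_i(Af, so$gs_final),
    intA_5min = integrate_window(trace, "A"),
    intCi_5min = integrate_window(trace, "Ci"),
    dip_present = dip$present, dip_time_min = dip$time_min,
    dip_depth = dip$depth,
    stringsAsFactors = FALSE)
}

#' Time series of WUEi for a trace
#'
#' @param trace an [induction_trace].
#' @return Data frame `time_s`, `wuei`.
#' @export
wue_i_series <- function(trace) {
  data.frame(time_s = trace$time_s, wuei = wue_i(trace$A, trace$gs))
}
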