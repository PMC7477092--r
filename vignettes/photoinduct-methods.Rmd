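---
title: "Models and methods behind photoinduct"
author: "photoinduct maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photoinduct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoinduct)
```

photoinduct analyses photosynthetic induction — the recovery of net CO2
assimilation *A* after a step from low to high irradiance — from combined
gas-exchange and chlorophyll-fluorescence records, and ships a ground-truth
simulator so that every analysis stage can be validated against known
parameters. This vignette documents the models, the tunable parameters and
their defaults, the numerical choices, and what the simulator does and does
not emulate.

## The steady-state demand model

The biochemical (FvCB) demand model gives net assimilation at chloroplastic
CO2 partial pressure $C_c$ (µbar) as the minimum of three limitations minus
day respiration $R_d$:

$$A = \min\left(
  \underbrace{\frac{V_{cmax}\,(C_c - \Gamma^*)}{C_c + K_c(1 + O/K_o)}}_{\text{Rubisco}},\;
  \underbrace{\frac{J\,(C_c - \Gamma^*)}{4 C_c + 8\Gamma^*}}_{\text{RuBP regeneration}},\;
  \underbrace{3\,TPU}_{\text{triose-phosphate use}}
\right) - R_d$$

Kinetic constants default to the standard 25 °C set used by A/Ci fitting
tools ($K_c$ = 404.9 µbar, $K_o$ = 278.4 mbar, $\Gamma^*$ = 42.75 µbar,
$O$ = 210 mbar) and are overridable via `fvcb_params()`. No temperature
response is implemented: the package targets single-temperature (25 °C)
measurements. At reduced oxygen, both $O$ and $\Gamma^*$ are scaled
proportionally with the oxygen mole fraction.

`aci_with_supply()` intersects this demand with the diffusive supply

$$A = \frac{C_a - C_i}{1.6/g_s + 1.37/g_b}, \qquad C_c = C_i - A/g_m,$$

where $g_s$ is stomatal conductance to water vapour (1.6 converts to CO2),
$g_b$ an optional boundary-layer conductance (default `Inf`, i.e. the pure
stomatal form; the simulator uses 1.42 mol m⁻² s⁻¹, typical of a clamp-on
fluorescence chamber) and $g_m$ mesophyll conductance. The residual
(demand − supply) is strictly decreasing in $A$ between $A = -R_d$ and the
value at which $C_c = \Gamma^*$, so the solver bisects on $A$ — fully
vectorised over timesteps, deterministic, with fixed 80 iterations
(residuals ≪ 10⁻⁸).

## Fitting the A/Ci curve

`fit_aci()` estimates $V_{cmax}$, $J_{1500}$, $TPU$ (and optionally $R_d$)
by least squares. Conditional on an assignment of points to limitation
regimes, the model is linear in the rates, so the optimiser alternates
regime assignment (minimum-of-hypotheses, ties resolved toward Rubisco) with
closed-form per-regime least squares. Starts come from a deterministic 3×3×3
grid *and* from every monotone two-cut partition of the Cc-sorted points —
regimes are ordered along $C_c$, so these partitions enumerate all candidate
global solutions. The fit is reported `converged` only when the assignment
is stable and no small parameter step decreases the SSE (the objective is
kinked at regime boundaries, so a gradient test would be ill-defined there).

A rate can be structurally unidentifiable: if the curve never enters a
regime, any sufficiently large value of its rate explains the data equally
well. After fitting, each rate is re-checked by refitting with its
hypothesis banned; if the banned fit matches the full fit's SSE (within
`1e-7 + 0.1%`), the rate is flagged unidentifiable and returned at its
search bound with a warning. Parts of the plausible parameter box
($V_{cmax} \in [50,150]$, $J \in [100,250]$, $TPU \in [5,15]$) are
unidentifiable on any practical Ca grid — e.g. $J = 100$ with $TPU = 15$
never reaches TPU limitation — and recovery tests are therefore conditional
on the flags.

By default the fit runs on the instrument's $C_i$ (`cc_source = "Ci"`);
passing a fixed $g_m$ converts to $C_c$ first.

## Fluorescence quantities and calibration

The quenching partitioning uses the standard definitions
($F_v/F_m$, $\Phi_{PSII} = (F_m' - F)/F_m'$, $NPQ = (F_m - F_m')/F_m'$,
$qP$, $F_v'/F_m'$) with the Oxborough–Baker estimator
$F_o' = F_o / (F_v/F_m + F_o/F_m')$; no measured-$F_o'$ pathway is provided
because the target workflow computes it. The identity
$\Phi_{PSII} = qP \cdot F_v'/F_m'$ is algebraically exact and tested at
10⁻⁹ (pure arithmetic); all quantities are invariant under a common
rescaling of the fluorescence counts.

Electron transport is $J = s \cdot PAR \cdot \Phi_{PSII}$, with $s$ a lumped
leaf-specific factor (absorptance × photosystem partitioning × any
alternative-sink correction — $s$ absorbs these by construction). `calibrate_leaf()`
estimates, per leaf:

1. **$R_d$ and $s$** by ordinary least squares of $A$ on
   $x = PAR\,\Phi_{PSII}/4$ over the low-irradiance points (default
   PAR ≤ 200 µmol m⁻² s⁻¹) of an A/PAR curve at 2% O2 and high Ca, where
   $J \approx 4(A + R_d)$: slope $= s$, intercept $= -R_d$.
2. **$\Gamma^*$** by a bounded 1-D least-squares inversion of the
   RuBP-limited model over the low-$C_i$ points (default $C_i \le 200$ µbar,
   below the regime transitions) of the 21% O2 A/Ci curve, with per-point
   $J$ from fluorescence. The search interval is [10, 100] µbar; an optimum
   within 0.5 µbar of a bound raises a boundary warning. On noise-free
   synthetic data the objective is unimodal. By default this is the
   *apparent*, Ci-based $\Gamma^*$ (the instrument reports $C_i$), which
   with finite $g_m$ overestimates the chloroplastic value by several µbar;
   the bias is measured in the test suite and matters downstream (next
   section).

## Variable-J mesophyll conductance

`gm_variable_j()` inverts the RuBP-limited model with fluorescence-derived
$J$:

$$g_m = \frac{A}{C_i - \Gamma^*\,\dfrac{J + 8(A + R_d)}{J - 4(A + R_d)}}$$

The inversion is exact (machine precision) on forward-simulated data. The
denominator difference $J - 4(A+R_d)$ amplifies errors near the
non-photorespiratory limit; estimates with $J$ within 5% of $4(A+R_d)$ are
flagged unreliable, and computed $C_c$ outside $(\Gamma^*, C_i)$ flags the
estimate invalid (not an error). `batch_gm()` applies this per sample,
keeping skipped/invalid samples in the output with a reason. A leaf-level
$g_m$ is conventionally the mean of valid mid-$C_i$ estimates.

Because the formula subtracts $\Gamma^*$-scaled flux ratios from $C_i$, a
few-µbar bias in $\Gamma^*$ propagates to tens of percent in $g_m$
regardless of the true $g_m$ — the apparent (Ci-based) $\Gamma^*$ is not fit
for this purpose. `calibrate_leaf(refine_gm = TRUE)` therefore iterates to a
self-consistent solution: estimate $g_m$ at the sample nearest
$C_a$ = 400 µbar, refit $\Gamma^*$ on $C_c = C_i - A/g_m$, and re-regress
$s$/$R_d$ with the residual-photorespiration factor
$(C_c - \Gamma^*_{low})/(C_c + 2\Gamma^*_{low})$ predicted at the low-O2
conditions (the plain non-photorespiratory slope biases $s$ low by ~0.6%,
which the variable-J denominator amplifies). The alternation is a
contraction on well-behaved curves (typically ~12 iterations to
Δ$\Gamma^*$ < 0.005 µbar) and recovers $R_d$, $\Gamma^*$, $s$ and $g_m$ to
better than 0.1% on noise-free synthetic leaves.

## Induction metrics

For a trace logged every 2 s around the irradiance step (time zero = first
high-PAR sample; pre-step samples carry negative time):

- `induction_fraction()`: $PI(t) = (A - A_i)/(A_f - A_i) \cdot 100$, with
  $A_i$ the pre-step window mean (default the last 5 pre-step minutes) and
  $A_f$ the final window mean (default minutes 55–60). The source protocol
  logs 60 min without stating an $A_f$ window; window means are robust to
  noise and configurable.
- `time_to_fraction()`: first upward crossing of the target, linearly
  interpolated between bracketing samples, after a rolling-median smooth
  (width 5 samples ≈ 10 s; width 1 disables). The same smoothing is applied
  for every target so t50 and t90 are comparable, and first-crossing
  semantics keep a post-peak transient dip from inflating the metrics; the
  dip is reported separately by `detect_dip()`.
- `wue_i()` ($A/g_s$), `stomatal_opening()` (final minus initial window
  means of $g_s$), `integrate_window()` (trapezoidal ∫A and ∫Ci over the
  first five minutes, reported in field-units × min).
- `gross_vs_j()`: quadratic fit of $A_g = A + R_d$ against $J$; a positive,
  significant quadratic coefficient flags the upward curvature that signals
  a rising carboxylation:oxygenation ratio (rising $C_c$) during induction.
- `detect_dip()`: on the smoothed A, a local maximum followed within
  0.5–4 min by a local minimum with a drop ≥ 0.5 µmol m⁻² s⁻¹ (configurable);
  absence is a valid result.

## The ground-truth simulator

`simulate_induction()` composes, at each 2-s step:

- **stomata**: $g_s(t) = g_{s,i} + (g_{s,f} - g_{s,i})
  (1 - e^{-\max(0, t-\lambda)/\tau_{gs}})$, lag $\lambda$ = 1 min;
- **biochemical activation**: Rubisco capacity and the RuBP-regeneration
  capacity ($J_{max}$ of a non-rectangular hyperbola anchored so that
  $J(1500) = J_{1500}$, curvature $\theta = 0.7$) relax exponentially from
  initial activation fractions 0.3 and 0.5 with time constants $\tau_R$ and
  $\tau_J$;
- **diffusion**: the supply–demand solver above, with $g_m$ and
  $g_b = 1.42$ mol m⁻² s⁻¹;
- **fluorescence**: inverted from the realized fluxes,
  $J_{true} = 4(A + R_d)(C_c + 2\Gamma^*)/(C_c - \Gamma^*)$,
  $\Phi_{PSII} = J_{true}/(s\,PAR)$, combined with a phenomenological NPQ
  trajectory (fast rise, partial relaxation, slow rise) under fixed dark
  $F_o$/$F_m$ (dark $F_v/F_m$ = 0.82), at the instrument cadence (every
  minute for 10 min, then every 2 min);
- **noise**: Gaussian, per channel (defaults $\sigma_A$ = 0.3 µmol m⁻² s⁻¹,
  $\sigma_{gs}$ = 0.01 mol m⁻² s⁻¹, $\sigma_{Ci}$ = 2 µbar, 0.5% on
  fluorescence counts; response curves get these divided by √6 for the
  steady-state logging average). A fixed seed gives bitwise-reproducible
  output; the RNG state of the session is restored afterwards.

An optional transient TPU depression (`dip`) reproduces the brief
assimilation dip 1.5–2 min into induction that is attributed to a transient
mismatch between Calvin-cycle fixation and downstream sucrose metabolism; it
is off by default, and only produces a visible dip when the depression cuts
below the current assimilation rate (a fractional depth ≈ 0.6 does so for
the flacca presets).

### Presets and their calibration

`preset_scenario(genotype, treatment)` pins each scenario to the published
steady-state table (`steady_state_targets()`): stomatal endpoints are taken
directly from the table, a scale factor applied jointly to
$V_{cmax}/J_{1500}/TPU$ is solved so the simulated high-PAR steady state
matches the tabulated final $A$, and the light-response slope $\alpha$ is
solved (capped at $0.82\,s$, since $\Phi_{PSII}$ cannot exceed dark
$F_v/F_m$) so the low-PAR steady state matches the tabulated initial $A$.
Three consequences are worth knowing:

- capacity becomes treatment-specific (e.g. the low-CO2 presets carry an
  inflated $V_{cmax}$). This is endpoint matching, not a claim that the same
  leaf changes capacity between environments; the presets reproduce each
  table row, which is what the downstream ordering tests need.
- where the cap binds (flacca control/high VPD; wildtype low CO2), the
  simulated initial $A$ falls up to ~0.3 µmol m⁻² s⁻¹ short of the tabulated
  value. Only the wildtype-control initial $A$ is pinned by the validation
  suite; the shortfall does not affect the conductance-driven orderings.
- day respiration presets are 1.0 (wildtype) and 1.4 (flacca)
  µmol m⁻² s⁻¹ — roughly 75–85% of the genotypes' dark effluxes (1.2 and
  1.9), reflecting light inhibition of respiration, and inside the
  0.5–3 plausibility window.

The base capacity ratio $J_{1500}/V_{cmax}$ = 1.25 puts the ambient-CO2
final steady states just into RuBP limitation (the usual co-limitation
picture at 400 µbar). Kinetic defaults are $\tau_{gs}$ = 14 min — mid-range
of the 4–29 min stomatal time constants reported for this kind of leaf —
and $\tau_R$ = 2 min, $\tau_J$ = 1.5 min, standard magnitudes for Rubisco
and RuBP-regeneration activation. This combination reproduces the
characteristic threshold relation between initial $g_s$ and t90 (steep rise
below ~0.4 mol m⁻² s⁻¹, flattening above) and genotype t90 ratios of
roughly 25–45%. Shorter stomatal or longer Rubisco time constants flatten
the threshold into a near-linear decline, because Rubisco activation then
gates t90 at every conductance. True time constants for these leaves are
unmeasured; all simulator kinetics are declared assumptions, exposed in
`sim_scenario()`.

### What the simulator does not emulate

No leaf energy balance (leaf temperature is implicitly constant), no
guard-cell mechanics or ABA signalling (VPD and CO2 act only through the
preset stomatal endpoints), no spatial patchiness, no slow photoinhibition,
and noise is Gaussian and serially uncorrelated, which real analysers'
drift is not. Passing recovery tests on this generator therefore validates
the *estimators* (their algebra, numerics and bookkeeping), not the
adequacy of the underlying leaf model for any particular real dataset.

## Problem sizes and runtime

The validation suite simulates 60-min traces at 2-s cadence (1951 samples),
runs 200 noise-free and 100 noisy A/Ci fits, 500 noisy calibration
regressions, and 100 noisy replicate transients per genotype × treatment
for the ordering checks — about 80 s in total on one CPU. The acceptance
script re-derives the headline quantities in under 10 s with 25 noisy
replicates per condition. These sizes give Monte-Carlo standard errors an
order of magnitude below every tolerance used.

## Worked example

```{r example, eval = FALSE}
library(photoinduct)

# simulate a wildtype control leaf with measurement noise
sc  <- preset_scenario("WT", "control", seed = 1)
sim <- simulate_induction(sc)
induction_metrics(sim$trace)

# calibrate a leaf from its two curves, then mesophyll conductance
apar <- simulate_response_curve(sc, "APAR", O2 = 2)
aci  <- simulate_response_curve(sc, "ACI")
cal  <- calibrate_leaf(apar, aci, refine_gm = TRUE)
cal

# the full genotype x treatment layout
run_pipeline(list(n_reps = 5, seed = 1))
```
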