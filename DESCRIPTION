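Package: photoinduct
Title: Photosynthetic Induction Kinetics and Combined Gas-Exchange /
    Fluorescence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing dynamic and steady-state leaf photosynthesis
    from combined gas-exchange and chlorophyll-fluorescence measurements.
    Implements steady-state FvCB (Farquhar-von Caemmerer-Berry) A/Ci curve
    fitting of Vcmax, J and TPU; calibration of day respiration (Rd), the
    apparent CO2 photocompensation point (Gamma*) and the fluorescence-to-
    electron-transport factor (s) from low-oxygen A/PAR and A/Ci curves;
    variable-J estimation of mesophyll conductance and chloroplastic CO2;
    chlorophyll-fluorescence quenching partitioning (PhiPSII, NPQ, qP,
    Fv'/Fm', Fo'); and induction metrics (PI, t50, t90, WUEi, stomatal
    opening, five-minute integrals, transient-dip detection) for low-to-high
    irradiance transients. A ground-truth simulator generates induction
    traces, A/Ci and A/PAR curves with self-consistent fluorescence for two
    stomatal phenotypes under three environments, so every analysis stage can
    be validated against known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
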