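#' Gas-exchange sample columns
#'
#' Standard column set used for logged gas-exchange instants: `time_s`
#' (seconds since the irradiance step; negative = pre-step baseline), `A`
#' (net photosynthesis, umol m-2 s-1), `gs` (stomatal conductance to water
#' vapour, mol m-2 s-1), `Ci` and `Ca` (substomatal / chamber CO2 partial
#' pressure, ubar), `PAR` (umol m-2 s-1), `VPD` (mbar), `O2` (%), and the
#' optional fluorescence columns `F`, `Fm_prime` plus dark `Fo`, `Fm`.
#'
#' @format Character vectors of mandatory and optional column names.
#' @keywords internal
#' @name gasx_columns
NULL

.gasx_mandatory <- c("time_s", "A", "gs", "Ci", "Ca", "PAR", "VPD", "O2")
.gasx_fluor    <- c("F", "Fm_prime", "Fo", "Fm")

#' Construct an induction trace
#'
#' An induction trace is a time-ordered data frame of gas-exchange samples
#' logged (typically every 2 s) around a single low-to-high irradiance step.
#' Time zero is the first sample at high PAR; pre-step samples carry negative
#' `time_s`.
#'
#' @param samples data frame with at least the mandatory gas-exchange columns
#'   (see [gasx_columns]); optional fluorescence columns are carried along.
#' @param genotype,treatment labels attached as attributes.
#' @param validate drop rows violating sample invariants (and record a report)?
#' @return A data frame of class `induction_trace` with attributes `genotype`,
#'   `treatment` and `report` (row counts of dropped samples by reason).
#' @export
induction_trace <- function(samples, genotype = NA_character_,
                            treatment = NA_character_, validate = TRUE) {
  missing_cols <- setdiff(.gasx_mandatory, names(samples))
  if (length(missing_cols) > 0)
    stop_photoinduct(
      paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      "photoinduct_format_error")
  samples <- as.data.frame(samples)
  report <- list(n_read = nrow(samples), n_dropped = 0L, reasons = integer(0))
  if (validate) {
    v <- validate_samples(samples)
    samples <- v$samples
    report <- v$report
  }
  if (nrow(samples) == 0L)
    stop_photoinduct("no valid samples remain", "photoinduct_empty_input_error")
  if (is.unsorted(samples$time_s, strictly = TRUE))
    stop_photoinduct("time_s must be strictly increasing",
                     "photoinduct_format_error")
  structure(samples,
            genotype = genotype, treatment = treatment, report = report,
            class = c("induction_trace", "data.frame"))
}

# row-level invariants shared by traces and response curves
validate_samples <- function(samples) {
  reasons <- c(
    nonfinite  = !stats::complete.cases(samples[, .gasx_mandatory]) |
      !apply(is.finite(as.matrix(samples[, .gasx_mandatory])), 1L, all),
    gs_nonpos  = samples$gs <= 0,
    ca_nonpos  = samples$Ca <= 0,
    o2_range   = samples$O2 < 0 | samples$O2 > 100,
    # Ci may exceed Ca only when the leaf is a net CO2 source
    ci_exceeds = samples$Ci > samples$Ca & samples$A >= 0
  )
  reasons <- matrix(reasons, nrow = nrow(samples),
                    dimnames = list(NULL, c("nonfinite", "gs_nonpos",
                                            "ca_nonpos", "o2_range",
                                            "ci_exceeds")))
  reasons[is.na(reasons)] <- TRUE
  bad <- rowSums(reasons) > 0
  list(samples = samples[!bad, , drop = FALSE],
       report = list(n_read = nrow(samples),
                     n_dropped = sum(bad),
                     reasons = colSums(reasons[bad, , drop = FALSE])))
}

#' Construct a steady-state response curve
#'
#' Ordered steady-state samples varying either chamber CO2 (`mode = "ACI"`,
#' constant PAR) or irradiance (`mode = "APAR"`, constant Ca) at a fixed
#' oxygen mole fraction.
#'
#' @param samples data frame with the mandatory gas-exchange columns.
#' @param mode `"ACI"` or `"APAR"`.
#' @param O2 oxygen mole fraction (%) of the measurement.
#' @param validate check constancy of the non-varied driver and row invariants.
#' @return Data frame of class `response_curve` with attributes `mode`, `O2`.
#' @export
response_curve <- function(samples, mode = c("ACI", "APAR"), O2 = 21,
                           validate = TRUE) {
  mode <- match.arg(mode)
  missing_cols <- setdiff(setdiff(.gasx_mandatory, "time_s"), names(samples))
  if (length(missing_cols) > 0)
    stop_photoinduct(
      paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      "photoinduct_format_error")
  samples <- as.data.frame(samples)
  if (!"time_s" %in% names(samples)) samples$time_s <- seq_len(nrow(samples))
  if (validate) {
    v <- validate_samples(samples)
    samples <- v$samples
    if (nrow(samples) == 0L)
      stop_photoinduct("no valid samples remain", "photoinduct_empty_input_error")
    held <- if (mode == "ACI") samples$PAR else samples$Ca
    if (diff(range(held)) > 1e-6 * max(abs(held)))
      stop_photoinduct(
        sprintf("%s curves must hold %s constant", mode,
                if (mode == "ACI") "PAR" else "Ca"),
        "photoinduct_format_error")
  }
  structure(samples, mode = mode, O2 = O2,
            class = c("response_curve", "data.frame"))
}

#' Read an induction trace from CSV
#'
#' Reads a comma-separated instrument export ('.' decimal, header row) into a
#' validated [induction_trace]. Column naming is declared, not sniffed: the
#' `dialect` maps standard names to file columns and may come from a YAML
#' config. Rows violating sample invariants (non-positive `gs` or `Ca`,
#' oxygen outside 0-100%, `Ci > Ca` at non-negative `A`, non-finite values)
#' are dropped and counted in the attached report.
#'
#' @param path CSV file path.
#' @param dialect named character vector or list mapping standard column names
#'   (e.g. `time_s`, `A`, `gs`, ...) to the file's column names, or the path
#'   of a YAML file with a top-level `columns:` map. `NULL` means the file
#'   already uses standard names.
#' @param genotype,treatment optional labels.
#' @return An [induction_trace]; inspect `attr(x, "report")` for dropped rows.
#' @export
read_trace <- function(path, dialect = NULL, genotype = NA_character_,
                       treatment = NA_character_) {
  if (!file.exists(path))
    stop_photoinduct(paste0("file not found: ", path), "photoinduct_io_error")
  raw <- utils::read.csv(path, check.names = FALSE)
  raw <- coerce_numeric_cols(apply_dialect(raw, dialect))
  induction_trace(raw, genotype = genotype, treatment = treatment)
}

#' @rdname read_trace
#' @param mode,O2 passed to [response_curve()].
#' @export
read_response_curve <- function(path, mode = c("ACI", "APAR"), O2 = 21,
                                dialect = NULL) {
  if (!file.exists(path))
    stop_photoinduct(paste0("file not found: ", path), "photoinduct_io_error")
  raw <- utils::read.csv(path, check.names = FALSE)
  raw <- coerce_numeric_cols(apply_dialect(raw, dialect))
  response_curve(raw, mode = mode, O2 = O2)
}

# standard numeric columns are stored as doubles so CSV round trips are exact
coerce_numeric_cols <- function(df) {
  for (nm in intersect(c(.gasx_mandatory, .gasx_fluor), names(df)))
    df[[nm]] <- as.double(df[[nm]])
  df
}

apply_dialect <- function(df, dialect) {
  if (is.null(dialect)) return(df)
  if (is.character(dialect) && length(dialect) == 1L && file.exists(dialect))
    dialect <- yaml::read_yaml(dialect)$columns
  dialect <- unlist(dialect)
  missing_src <- setdiff(unname(dialect), names(df))
  if (length(missing_src) > 0)
    stop_photoinduct(
      paste0("dialect maps to absent column(s): ",
             paste(missing_src, collapse = ", ")),
      "photoinduct_format_error")
  for (std in names(dialect)) df[[std]] <- df[[dialect[[std]]]]
  df
}

#' Write a trace or curve to CSV at full double precision
#'
#' Numeric fields are serialized with 17 significant digits so that
#' `read_trace(write_trace(x))` reproduces every double bit-for-bit.
#'
#' @param x an [induction_trace] or [response_curve].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  df <- as.data.frame(x)
  out <- df
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Correct net photosynthesis for chamber CO2 leakage
#'
#' Applies a linear diffusion-leak correction: a CO2 gradient between chamber
#' (`Ca`) and surrounding air (`C_ambient`) drives a diffusive leak that
#' biases apparent assimilation; the correction adds back
#' `k_leak * (Ca - C_ambient) / leaf_area`. With the default `k_leak = 0` the
#' correction is the identity; the coefficient is instrument-specific and
#' must be supplied from the chamber's calibration.
#'
#' @param A_raw apparent net photosynthesis, umol m-2 s-1.
#' @param Ca chamber CO2 partial pressure, ubar.
#' @param C_ambient CO2 partial pressure of the air surrounding the chamber,
#'   ubar (default 400).
#' @param k_leak leak coefficient, mol s-1 bar-1 (>= 0).
#' @param leaf_area enclosed leaf area, m2 (> 0).
#' @return Corrected A, umol m-2 s-1. Linear in `Ca - C_ambient`.
#' @export
leak_correct <- function(A_raw, Ca, C_ambient = 400, k_leak = 0,
                         leaf_area = 2e-4) {
  stopifnot(leaf_area > 0, k_leak >= 0)
  # ubar gradient x mol s-1 bar-1 = umol s-1; per m2 leaf
  A_raw + k_leak * (Ca - C_ambient) / leaf_area
}

#' Mean of a logged field over a time window
#'
#' Arithmetic mean of one trace field over `window = c(t_from, t_to)` seconds
#' (closed interval), e.g. to average the 30-s steady-state logging block of a
#' response-curve step.
#'
#' @param trace an [induction_trace] (or any data frame with `time_s`).
#' @param window numeric length-2, seconds.
#' @param field column name to average.
#' @return Scalar mean.
#' @export
steady_window_mean <- function(trace, window, field = "A") {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (!any(sel))
    stop_photoinduct("no samples in requested window",
                     "photoinduct_empty_window_error")
  mean(trace[[field]][sel])
}

# trapezoidal integral of y(t); units y * t
trapz_ <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}
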