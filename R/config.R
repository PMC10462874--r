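# Flat key=value configuration file: the desk-scale stand-in for the
# device's persisted settings (EEPROM). One `key = value` per line, `#`
# comments; keys are prefixed by subsystem. All values SI-annotated in the
# documentation below.

#' Default configuration
#'
#' Returns the full set of recognized configuration keys with their default
#' values. Keys (units in brackets):
#'
#' * `calib.pH_at_0V` (pH), `calib.pH_1V_range` (pH/V) -- meter analog
#'   output calibration, shared between meter and titrator.
#' * `adc.bits`, `adc.v_ref` (V), `adc.bias_supply` (V),
#'   `adc.divider_ratio` -- converter and bias-divider model.
#' * `pump.syringe_diameter_mm` (mm), `pump.lead_mm_per_rev` (mm),
#'   `pump.steps_per_rev`, `pump.microstepping`,
#'   `pump.syringe_capacity_uL` (uL) -- syringe/lead-screw geometry.
#' * `titration.target_pH` (pH), `titration.dosing_threshold` (pH),
#'   `titration.aliquot_uL` (uL), `titration.flowrate_uL_per_s` (uL/s),
#'   `titration.inter_aliquot_wait_s` (s),
#'   `titration.sampling_interval_s` (s), `titration.titrant_normality`
#'   (eq/L), `titration.max_duration_s` (s),
#'   `titration.stability_window_s` (s), `titration.stability_band_pH` (pH).
#' * `chem.pKw`, `chem.phosphate_pKa1/2/3` -- equilibrium constants of the
#'   ground-truth model.
#' * `sim.noise_sd` (V) -- sensor noise at the ADC node.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    calib.pH_at_0V = 6, calib.pH_1V_range = 1,
    adc.bits = 10, adc.v_ref = 5.0, adc.bias_supply = 3.3,
    adc.divider_ratio = 0.5,
    pump.syringe_diameter_mm = 14.5, pump.lead_mm_per_rev = 8,
    pump.steps_per_rev = 200, pump.microstepping = 16,
    pump.syringe_capacity_uL = 10000,
    titration.target_pH = 7, titration.dosing_threshold = 0.1,
    titration.aliquot_uL = 96.85, titration.flowrate_uL_per_s = 50,
    titration.inter_aliquot_wait_s = 5, titration.sampling_interval_s = 1,
    titration.titrant_normality = 0.1, titration.max_duration_s = 7200,
    titration.stability_window_s = 600, titration.stability_band_pH = 0.02,
    chem.pKw = 14, chem.phosphate_pKa1 = 2.15, chem.phosphate_pKa2 = 7.21,
    chem.phosphate_pKa3 = 12.35,
    sim.noise_sd = 0
  )
}

#' Read a flat key=value configuration file
#'
#' Lines are `key = value`; blank lines and `#` comments are ignored.
#' Numeric-looking values are converted. Unknown keys are kept (scenario
#' overrides may extend the set); missing keys fall back to
#' [default_config()].
#'
#' @param path Configuration file path.
#' @param defaults Base configuration the file overrides.
#' @return Named list of configuration values.
#' @export
read_config <- function(path, defaults = default_config()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- defaults
  for (i in seq_along(lines)) {
    line <- lines[i]
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) {
      stop("malformed config line: ", dQuote(line), call. = FALSE)
    }
    key <- trimws(substr(line, 1, eq - 1))
    val <- trimws(substr(line, eq + 1, nchar(line)))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' Write a configuration to a flat key=value file
#'
#' @param cfg Named list of configuration values.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  lines <- paste0(names(cfg), " = ",
                  vapply(cfg, function(v) {
                    if (is.numeric(v)) sprintf("%.10g", v) else as.character(v)
                  }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Build model objects from a configuration
#'
#' @param cfg Named list as returned by [read_config()].
#' @return A list with `calib`, `adc`, `pump`, `settings`, `pKw`,
#'   `phosphate_pKa` and `noise_sd` ready to pass to [run_titration()].
#' @export
config_to_models <- function(cfg = default_config()) {
  list(
    calib = calibration_settings(cfg$calib.pH_at_0V, cfg$calib.pH_1V_range),
    adc = adc_config(cfg$adc.bits, cfg$adc.v_ref, cfg$adc.bias_supply,
                     cfg$adc.divider_ratio),
    pump = pump_config(syringe_diameter_mm = cfg$pump.syringe_diameter_mm,
                       lead_mm_per_rev = cfg$pump.lead_mm_per_rev,
                       steps_per_rev = cfg$pump.steps_per_rev,
                       microstepping = cfg$pump.microstepping,
                       syringe_capacity_uL = cfg$pump.syringe_capacity_uL),
    settings = titration_settings(
      target_pH = cfg$titration.target_pH,
      aliquot_uL = cfg$titration.aliquot_uL,
      dosing_threshold = cfg$titration.dosing_threshold,
      flowrate_uL_per_s = cfg$titration.flowrate_uL_per_s,
      inter_aliquot_wait_s = cfg$titration.inter_aliquot_wait_s,
      sampling_interval_s = cfg$titration.sampling_interval_s,
      titrant_normality = cfg$titration.titrant_normality,
      max_duration_s = cfg$titration.max_duration_s,
      stability_window_s = cfg$titration.stability_window_s,
      stability_band_pH = cfg$titration.stability_band_pH),
    pKw = cfg$chem.pKw,
    phosphate_pKa = c(cfg$chem.phosphate_pKa1, cfg$chem.phosphate_pKa2,
                      cfg$chem.phosphate_pKa3),
    noise_sd = cfg$sim.noise_sd
  )
}
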