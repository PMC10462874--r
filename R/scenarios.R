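# Packaged, seedable end-to-end scenarios: the desk-scale test surface that
# exercises the whole closed loop without hardware or downloads.

#' Assemble a scenario object
#'
#' @param name Scenario name.
#' @param state Initial [solution_state()].
#' @param settings A [titration_settings()].
#' @param calib A [calibration_settings()].
#' @param adc An [adc_config()].
#' @param pump A [pump_config()].
#' @param kinetics Optional [lipolysis_kinetics()].
#' @param noise_sd Sensor noise (volts at the ADC node).
#' @param expected Free-form notes on the documented expected outcome (not
#'   enforced at run time).
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, state, settings, calib, adc, pump,
                     kinetics = NULL, noise_sd = 0, expected = NULL) {
  structure(list(name = name, state = state, settings = settings,
                 calib = calib, adc = adc, pump = pump, kinetics = kinetics,
                 noise_sd = noise_sd, expected = expected),
            class = "scenario")
}

#' Phosphate-buffer autotitration scenario
#'
#' The known-endpoint validation experiment: 38.98 mg of NaH2PO4.H2O
#' dissolved in 0.25 L (a 1.13e-3 M buffer) is titrated to pH 7 with 0.1 N
#' NaOH; about 1 mL is required, so an autotitration run with small
#' aliquots should dispense close to that before holding. Calibration puts
#' 0 V one pH unit below the target (pH 6) with a 1 pH/V range.
#'
#' @param aliquot_uL Aliquot volume, uL (default 10, the small-aliquot
#'   neutralization regime).
#' @param noise_sd Sensor noise, volts (default 0: noiseless instrument).
#' @param pre_acidified_pH Optional pH to which the buffer is pre-adjusted
#'   with strong acid before the run starts ("starting at a low pH value");
#'   `NULL` starts from the un-neutralized buffer.
#' @return A `scenario`.
#' @export
scenario_buffer_titration <- function(aliquot_uL = 10, noise_sd = 0,
                                      pre_acidified_pH = NULL) {
  st <- make_phosphate_buffer(0.03898, 0.25)$state
  if (!is.null(pre_acidified_pH)) {
    st <- equilibrate_to_ph(st, pre_acidified_pH)
  }
  scenario(
    name = "buffer_titration",
    state = st,
    settings = titration_settings(target_pH = 7, aliquot_uL = aliquot_uL,
                                  dosing_threshold = 0.1,
                                  flowrate_uL_per_s = 50,
                                  inter_aliquot_wait_s = 5,
                                  titrant_normality = 0.1),
    calib = calibration_settings(pH_at_0V = 6, pH_1V_range = 1),
    adc = adc_config(),
    pump = pump_config(syringe_diameter_mm = 4.7, syringe_capacity_uL = 2000),
    noise_sd = noise_sd,
    expected = "total dispensed volume close to 1 mL (hand value) at hold"
  )
}

#' Olive-oil emulsion lipolysis scenario
#'
#' An oil-in-water emulsion aliquot in simulated intestinal fluid (150 mM
#' NaCl, 3 mM CaCl2, 1.13 mM NaH2PO4, pH 7), held at pH 7 while lipase
#' releases free fatty acids from the oil's triglycerides. The emulsifier,
#' bile salts and pancreatin enter only through the kinetics parameters.
#' Defaults: 4 mL of a 20% w/w oil emulsion (0.8 g oil) in 40 mL total,
#' first-order release at `k = 1e-3` 1/s, aliquots of 96.85 uL at 50 uL/s.
#' Balanced salts (NaCl, CaCl2) contribute no net spectator charge; only
#' the Na+ bound in NaH2PO4 does.
#'
#' @param W_lipid_g Oil mass in the vessel, grams.
#' @param M_lipid Mean triglyceride molar mass, g/mol.
#' @param rate_constant First-order release rate constant, 1/s.
#' @param ffa_pKa_eff Effective interfacial pKa of the released FFAs.
#' @param lag_s Enzyme lag, seconds.
#' @param volume_L Total reaction volume, litres.
#' @param aliquot_uL Aliquot volume, uL.
#' @param sampling_interval_s Sampling period, seconds.
#' @param max_duration_s Hard stop, seconds.
#' @param noise_sd Sensor noise, volts.
#' @return A `scenario`.
#' @export
scenario_olive_oil_lipolysis <- function(W_lipid_g = 0.8, M_lipid = 885,
                                         rate_constant = 1e-3,
                                         ffa_pKa_eff = 7.5, lag_s = 0,
                                         volume_L = 0.040,
                                         aliquot_uL = 96.85,
                                         sampling_interval_s = 1,
                                         max_duration_s = 7200,
                                         noise_sd = 0) {
  phosphate_M <- 1.13e-3
  phosphate_mol <- phosphate_M * volume_L
  st <- solution_state(
    volume_L = volume_L,
    acids = list(acid_species("phosphate", phosphate_mol,
                              c(2.15, 7.21, 12.35))),
    fixed_ion_charge = phosphate_mol  # Na+ of NaH2PO4; NaCl/CaCl2 net zero
  )
  st <- equilibrate_to_ph(st, 7)  # SIF is prepared at pH 7
  scenario(
    name = "olive_oil_lipolysis",
    state = st,
    settings = titration_settings(target_pH = 7, aliquot_uL = aliquot_uL,
                                  dosing_threshold = 0.1,
                                  flowrate_uL_per_s = 50,
                                  inter_aliquot_wait_s = 5,
                                  sampling_interval_s = sampling_interval_s,
                                  titrant_normality = 0.1,
                                  max_duration_s = max_duration_s),
    calib = calibration_settings(pH_at_0V = 6, pH_1V_range = 1),
    adc = adc_config(),
    pump = pump_config(syringe_diameter_mm = 14.5,
                       syringe_capacity_uL = 10000),
    kinetics = lipolysis_kinetics(oil_ffa_pool(W_lipid_g, M_lipid),
                                  rate_constant, ffa_pKa_eff, lag_s),
    noise_sd = noise_sd,
    expected = "monotone saturating %FFA release curve"
  )
}

#' Run a packaged scenario end to end
#'
#' @param sc A `scenario`.
#' @param seed Integer seed (relevant when the scenario has sensor noise).
#' @param ... Passed on to [run_titration()] (e.g. `fault_windows`,
#'   `abort_at_s`).
#' @return The [titration_log()] from [run_titration()], with the scenario
#'   name recorded in the header.
#' @export
run_scenario <- function(sc, seed = NULL, ...) {
  stopifnot(inherits(sc, "scenario"))
  run_titration(sc$state, sc$settings, sc$calib, sc$adc, sc$pump,
                kinetics = sc$kinetics, noise_sd = sc$noise_sd, seed = seed,
                header = list(scenario = sc$name), ...)
}

#' Generate a synthetic, schema-valid fixture log
#'
#' Produces device-dialect log text with randomized settings and a
#' plausible record stream (random-walk pH, occasional doses), for parser
#' and analysis tests. Deterministic given the seed; the caller's RNG state
#' is preserved.
#'
#' @param n_records Records per experiment (>= 0).
#' @param seed Integer seed.
#' @param n_experiments Number of appended experiments.
#' @return The log file text as one string.
#' @export
make_fixture_log <- function(n_records, seed = 1, n_experiments = 1L) {
  stopifnot(n_records >= 0, n_experiments >= 1L)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  logs <- lapply(seq_len(n_experiments), function(e) {
    aliquot <- round(stats::runif(1, 5, 120), 2)
    target <- round(stats::runif(1, 4, 10), 2)
    header <- list(format_version = 1, target_pH = target,
                   dosing_threshold = 0.1, aliquot_uL = aliquot,
                   flowrate_uL_per_s = 50, titrant_normality = 0.1)
    if (n_records > 0) {
      doses <- stats::rbinom(n_records, 1, 0.1)
      doses[1] <- 0L
      aliquots <- cumsum(doses)
      ph <- round(target - 0.1 + cumsum(stats::rnorm(n_records, 0, 0.01)), 3)
      ph <- pmin(pmax(ph, 0), 14)
      records <- data.frame(t_s = 0:(n_records - 1L), pH = ph,
                            aliquots = as.integer(aliquots),
                            cum_volume_uL = round(aliquots * aliquot, 2))
    } else {
      records <- NULL
    }
    titration_log(header, records, "user_abort")
  })
  write_log(logs)
}
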