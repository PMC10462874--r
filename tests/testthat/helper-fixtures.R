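# Shared builders for the test suite. Everything is generated in code;
# no stored fixtures.

# The known-endpoint phosphate buffer: 38.98 mg NaH2PO4.H2O in 0.25 L.
buffer_state <- function() make_phosphate_buffer(0.03898, 0.25)$state

default_instrument <- function() {
  list(calib = calibration_settings(pH_at_0V = 6, pH_1V_range = 1),
       adc = adc_config(),
       pump = pump_config(syringe_diameter_mm = 4.7,
                          syringe_capacity_uL = 2000))
}

# Settings for fast controller tests: short stability window so runs finish
# in tens of simulated seconds.
quick_settings <- function(target_pH = 7, aliquot_uL = 10, ...) {
  titration_settings(target_pH = target_pH, aliquot_uL = aliquot_uL,
                     inter_aliquot_wait_s = 2, stability_window_s = 60,
                     max_duration_s = 1800, ...)
}

# One closed-loop lipolysis run sized for rate-constant recovery: substrate
# load small enough that the pump's dosing capacity exceeds the peak base
# demand even at k = 1e-2/s, horizon 4/k, sampling interval coarsened for
# slow kinetics to keep every run at a few thousand ticks.
recovery_sim <- function(k, seed = NULL) {
  dt <- max(1, round((4 / k) / 3600))
  sc <- scenario_olive_oil_lipolysis(W_lipid_g = 0.4, rate_constant = k,
                                     sampling_interval_s = dt,
                                     max_duration_s = 4 / k)
  sc$settings$inter_aliquot_wait_s <- 0
  log <- run_scenario(sc, seed = seed)
  list(log = log,
       curve = ffa_curve(log, lipolysis_assay(W_lipid = 0.4)),
       kinetics = attr(log, "final_kinetics"))
}

# Independent oracle: pH of a monoprotic weak acid from the textbook
# quadratic [H+]^2 + Ka [H+] - Ka C = 0 (water autoprotolysis neglected).
monoprotic_quadratic_ph <- function(C, pKa) {
  Ka <- 10^(-pKa)
  -log10((-Ka + sqrt(Ka^2 + 4 * Ka * C)) / 2)
}
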