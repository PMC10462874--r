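# Measurement and actuation chain: pH -> analog voltage -> biased/attenuated
# ADC code -> read-back pH; lead-screw/stepper discretization of dispensed
# volume; syringe bookkeeping with endstop.

#' pH-meter analog-output calibration
#'
#' The meter's recorder output is defined by two parameters copied into the
#' titrator at setup: the pH producing a 0 V reading (`pH_at_0V`) and the pH
#' deviation producing a 1 V swing (`pH_1V_range`). A common choice is to put
#' the 0 V point one pH unit below the target pH with a 1 pH/V range.
#'
#' @param pH_at_0V pH mapped to 0 V output, within `[0, 14]`.
#' @param pH_1V_range pH units per volt of output (> 0).
#' @return An object of class `calibration_settings`.
#' @export
calibration_settings <- function(pH_at_0V, pH_1V_range = 1) {
  if (!is.finite(pH_at_0V) || pH_at_0V < 0 || pH_at_0V > 14) {
    stop("'pH_at_0V' must lie in [0, 14]", call. = FALSE)
  }
  if (!is.finite(pH_1V_range) || pH_1V_range <= 0 || pH_1V_range > 14) {
    stop("'pH_1V_range' must be > 0 and at most 14", call. = FALSE)
  }
  structure(list(pH_at_0V = pH_at_0V, pH_1V_range = pH_1V_range),
            class = "calibration_settings")
}

#' Analog-to-digital converter and bias-divider configuration
#'
#' The controller board reads only positive voltages, so the meter output is
#' biased through two equal resistors between the 3.3 V rail and the meter:
#' the sampled node sits at `divider_ratio * (bias_supply + v_out)`, i.e.
#' +1.65 V bias and gain 1/2 with the defaults. Conversion is `bits`-wide
#' over `[0, v_ref)`.
#'
#' @param bits ADC resolution in bits (default 10: 1024 codes over 0-5 V).
#' @param v_ref ADC reference voltage in volts.
#' @param bias_supply Rail feeding the divider, volts.
#' @param divider_ratio Divider attenuation at the sampled node; 0.5 for two
#'   equal resistors. Set to 1 to emulate an ideal unity-gain bias stage.
#' @return An object of class `adc_config`.
#' @export
adc_config <- function(bits = 10L, v_ref = 5.0, bias_supply = 3.3,
                       divider_ratio = 0.5) {
  bits <- as.integer(bits)
  if (is.na(bits) || bits < 1L) stop("'bits' must be >= 1", call. = FALSE)
  if (!is.finite(v_ref) || v_ref <= 0) stop("'v_ref' must be > 0", call. = FALSE)
  if (!is.finite(bias_supply)) stop("'bias_supply' must be finite", call. = FALSE)
  if (!is.finite(divider_ratio) || divider_ratio <= 0) {
    stop("'divider_ratio' must be > 0", call. = FALSE)
  }
  structure(list(bits = bits, v_ref = v_ref, bias_supply = bias_supply,
                 divider_ratio = divider_ratio),
            class = "adc_config")
}

#' Map a pH to the meter's analog output voltage
#'
#' `V = (pH - pH_at_0V) / pH_1V_range`, clamped to the recorder output's
#' physical range of -2 to +2 V.
#'
#' @param pH True pH at the electrode (vectorised).
#' @param calib A [calibration_settings()].
#' @return Output voltage in volts, clamped to `[-2, 2]`.
#' @examples
#' ph_to_output_voltage(7, calibration_settings(6, 1))  # +1 V
#' @export
ph_to_output_voltage <- function(pH, calib) {
  stopifnot(inherits(calib, "calibration_settings"))
  v <- (pH - calib$pH_at_0V) / calib$pH_1V_range
  pmin(pmax(v, -2), 2)
}

#' Voltage at the divider node seen by the ADC
#'
#' @param v_out Meter output voltage in volts (vectorised).
#' @param adc An [adc_config()].
#' @return `divider_ratio * (bias_supply + v_out)` in volts.
#' @export
divider_voltage <- function(v_out, adc) {
  stopifnot(inherits(adc, "adc_config"))
  adc$divider_ratio * (adc$bias_supply + v_out)
}

#' Sample the biased meter output with the ADC
#'
#' Applies the bias divider, optional Gaussian sensor noise, and
#' floor-quantization (successive-approximation behaviour): the code is
#' `floor(v_adc / v_ref * 2^bits)` clamped to the code range. With
#' `noise_sd = 0` the result is deterministic and no random numbers are
#' drawn; with noise, reproducibility comes from `seed` (or the caller's RNG
#' state when `seed` is `NULL`).
#'
#' @inheritParams divider_voltage
#' @param noise_sd Gaussian noise standard deviation on the divider node, in
#'   volts.
#' @param seed Optional integer seed for the noise draw; the caller's RNG
#'   state is left untouched.
#' @return Integer ADC code(s) in `[0, 2^bits - 1]`.
#' @examples
#' adc_sample(0, adc_config())  # 1.65 V node -> code 337
#' @export
adc_sample <- function(v_out, adc, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(adc, "adc_config"))
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("'noise_sd' must be >= 0", call. = FALSE)
  }
  v_adc <- divider_voltage(v_out, adc)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    v_adc <- v_adc + stats::rnorm(length(v_adc), 0, noise_sd)
  }
  n_codes <- 2^adc$bits
  code <- floor(v_adc / adc$v_ref * n_codes)
  as.integer(pmin(pmax(code, 0), n_codes - 1))
}

#' Invert an ADC code back to a pH estimate
#'
#' Bin-centre inversion of the full measurement chain, as the firmware must
#' perform to display pH: `v_adc = (code + 0.5) / 2^bits * v_ref`, then the
#' divider and calibration maps are inverted.
#'
#' @param code Integer ADC code(s) in `[0, 2^bits - 1]`.
#' @param adc An [adc_config()].
#' @param calib A [calibration_settings()].
#' @return pH estimate(s).
#' @export
code_to_ph <- function(code, adc, calib) {
  stopifnot(inherits(adc, "adc_config"), inherits(calib, "calibration_settings"))
  if (any(code < 0 | code > 2^adc$bits - 1)) {
    stop("'code' out of ADC range", call. = FALSE)
  }
  v_adc <- (code + 0.5) / 2^adc$bits * adc$v_ref
  v_out <- v_adc / adc$divider_ratio - adc$bias_supply
  calib$pH_at_0V + v_out * calib$pH_1V_range
}

#' Read a true pH through the full instrument chain
#'
#' Convenience composition `code_to_ph(adc_sample(ph_to_output_voltage(.)))`:
#' what the firmware sees each sampling tick.
#'
#' @inheritParams ph_to_output_voltage
#' @inheritParams adc_sample
#' @param calib A [calibration_settings()].
#' @return The read-back (quantized, possibly noisy) pH.
#' @export
measure_ph <- function(pH, calib, adc, noise_sd = 0, seed = NULL) {
  code_to_ph(adc_sample(ph_to_output_voltage(pH, calib), adc, noise_sd, seed),
             adc, calib)
}

#' Syringe-pump geometry and stepper discretization
#'
#' The set of dispensable volumes is discrete: one microstep advances the
#' plunger by `lead / (steps_per_rev * microstepping)` millimetres, sweeping
#' `volume_per_microstep = advance * pi d^2 / 4` microlitres. Either the
#' syringe inner diameter or its length-to-volume ratio (mm of travel per
#' microlitre) may be given; they are reciprocal descriptions of the barrel
#' cross-section.
#'
#' @param syringe_diameter_mm Syringe inner diameter, mm.
#' @param length_to_volume Alternative to the diameter: plunger travel per
#'   unit volume, mm/uL.
#' @param lead_mm_per_rev Lead-screw advance per revolution, mm (T8/L8: 8).
#' @param steps_per_rev Full motor steps per revolution (NEMA 17: 200).
#' @param microstepping Driver microstepping factor (default 16).
#' @param syringe_capacity_uL Usable syringe volume, uL.
#' @return An object of class `pump_config` with the derived
#'   `volume_per_microstep_uL`.
#' @export
pump_config <- function(syringe_diameter_mm = NULL, length_to_volume = NULL,
                        lead_mm_per_rev = 8, steps_per_rev = 200L,
                        microstepping = 16L, syringe_capacity_uL = 10000) {
  if (is.null(syringe_diameter_mm) && is.null(length_to_volume)) {
    stop("give either 'syringe_diameter_mm' or 'length_to_volume'", call. = FALSE)
  }
  if (is.null(syringe_diameter_mm)) {
    if (!is.finite(length_to_volume) || length_to_volume <= 0) {
      stop("'length_to_volume' must be > 0", call. = FALSE)
    }
    # area (mm^2) is uL swept per mm of travel = 1 / (mm per uL)
    area_mm2 <- 1 / length_to_volume
    syringe_diameter_mm <- sqrt(4 * area_mm2 / pi)
  }
  for (v in c(syringe_diameter_mm, lead_mm_per_rev, steps_per_rev,
              microstepping, syringe_capacity_uL)) {
    if (!is.finite(v) || v <= 0) {
      stop("all pump parameters must be > 0", call. = FALSE)
    }
  }
  area_mm2 <- pi * syringe_diameter_mm^2 / 4
  vps <- lead_mm_per_rev / (steps_per_rev * microstepping) * area_mm2
  structure(list(syringe_diameter_mm = syringe_diameter_mm,
                 lead_mm_per_rev = lead_mm_per_rev,
                 steps_per_rev = as.integer(steps_per_rev),
                 microstepping = as.integer(microstepping),
                 syringe_capacity_uL = syringe_capacity_uL,
                 volume_per_microstep_uL = vps),
            class = "pump_config")
}

#' Round a requested volume to the nearest dispensable value
#'
#' Volumes not reachable by an integer number of microsteps are rounded to
#' the nearest allowed value (ties round up), so the returned volume differs
#' from the request by at most half a microstep's volume.
#'
#' @param requested_uL Requested volume, uL (>= 0).
#' @param pump A [pump_config()].
#' @return A list with `allowed_uL` and the integer `microsteps`.
#' @export
quantize_volume <- function(requested_uL, pump) {
  stopifnot(inherits(pump, "pump_config"))
  if (!is.finite(requested_uL) || requested_uL < 0) {
    stop("'requested_uL' must be >= 0", call. = FALSE)
  }
  vps <- pump$volume_per_microstep_uL
  steps <- floor(requested_uL / vps + 0.5)  # round half up
  list(allowed_uL = steps * vps, microsteps = as.integer(steps))
}

#' Syringe fill state
#'
#' @param remaining_uL Titrant remaining in the syringe, uL (>= 0).
#' @return An object of class `syringe_state`; `endstop` is asserted once
#'   the plunger bottoms out (syringe empty).
#' @export
syringe_state <- function(remaining_uL) {
  if (!is.finite(remaining_uL) || remaining_uL < 0) {
    stop("'remaining_uL' must be >= 0", call. = FALSE)
  }
  structure(list(remaining_uL = remaining_uL, endstop = remaining_uL <= 0),
            class = "syringe_state")
}

#' Dispense an aliquot from the syringe
#'
#' Decrements the syringe by the requested (already quantized) volume at the
#' given flowrate. If less titrant remains than requested, the remainder is
#' dispensed and the endstop is asserted -- an observable state, not an
#' error, mirroring the pump's limit switch.
#'
#' @param syringe A [syringe_state()].
#' @param allowed_uL Volume to dispense, uL (>= 0; typically a quantized value).
#' @param flowrate_uL_per_s Dispense flowrate, uL/s (> 0).
#' @return A list with the updated `syringe`, the actually `dispensed_uL`,
#'   and `duration_s = dispensed / flowrate`.
#' @examples
#' d <- dispense(syringe_state(10000), 96.85, 50)
#' d$duration_s  # 1.937 s
#' @export
dispense <- function(syringe, allowed_uL, flowrate_uL_per_s) {
  stopifnot(inherits(syringe, "syringe_state"))
  if (!is.finite(allowed_uL) || allowed_uL < 0) {
    stop("'allowed_uL' must be >= 0", call. = FALSE)
  }
  if (!is.finite(flowrate_uL_per_s) || flowrate_uL_per_s <= 0) {
    stop("'flowrate_uL_per_s' must be > 0", call. = FALSE)
  }
  actual <- min(allowed_uL, syringe$remaining_uL)
  syringe$remaining_uL <- syringe$remaining_uL - actual
  if (syringe$remaining_uL <= 1e-9 || actual < allowed_uL) {
    syringe$remaining_uL <- max(syringe$remaining_uL, 0)
    syringe$endstop <- TRUE
  }
  list(syringe = syringe, dispensed_uL = actual,
       duration_s = actual / flowrate_uL_per_s)
}
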