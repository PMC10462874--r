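# The pH-stat firmware logic: per-tick sampling through the instrument
# chain, threshold dosing with inter-aliquot gating, fault holds, stop
# conditions, and the per-second log stream.

#' Titration run settings
#'
#' The operator-facing settings of a pH-stat run. The dosing rule is: add
#' one aliquot whenever the read-back pH falls strictly below
#' `target_pH - dosing_threshold` and neither a dispense nor the
#' inter-aliquot wait is in progress. The run stops when the recorded pH has
#' stayed within `stability_band_pH` for `stability_window_s` seconds with
#' no aliquot dosed in that window, when the syringe empties, or at
#' `max_duration_s`.
#'
#' @param target_pH pH to hold.
#' @param aliquot_uL Aliquot volume in uL; quantized to the pump's microstep
#'   grid at setup.
#' @param dosing_threshold Dosing deadband in pH units (default 0.1).
#' @param flowrate_uL_per_s Dispense flowrate, uL/s.
#' @param inter_aliquot_wait_s Wait after each dispense before the next dose
#'   is allowed, seconds.
#' @param sampling_interval_s Sampling/recording period, seconds (default 1).
#' @param titrant_normality Titrant strength, eq/L (0.1 N NaOH by default).
#' @param max_duration_s Hard stop, seconds (default 7200: runs of this kind
#'   take 30-120 min).
#' @param stability_window_s Window for the stability stop, seconds.
#' @param stability_band_pH Max recorded pH spread within the window.
#' @return An object of class `titration_settings`.
#' @export
titration_settings <- function(target_pH, aliquot_uL,
                               dosing_threshold = 0.1,
                               flowrate_uL_per_s = 50,
                               inter_aliquot_wait_s = 5,
                               sampling_interval_s = 1,
                               titrant_normality = 0.1,
                               max_duration_s = 7200,
                               stability_window_s = 600,
                               stability_band_pH = 0.02) {
  if (!is.finite(target_pH) || target_pH < 0 || target_pH > 14) {
    stop("'target_pH' must lie in [0, 14]", call. = FALSE)
  }
  if (!is.finite(dosing_threshold) || dosing_threshold <= 0) {
    stop("'dosing_threshold' must be > 0", call. = FALSE)
  }
  if (!is.finite(aliquot_uL) || aliquot_uL < 0) {
    stop("'aliquot_uL' must be >= 0", call. = FALSE)
  }
  if (!is.finite(sampling_interval_s) || sampling_interval_s <= 0) {
    stop("'sampling_interval_s' must be > 0", call. = FALSE)
  }
  if (stability_window_s < sampling_interval_s) {
    stop("'stability_window_s' must be >= the sampling interval", call. = FALSE)
  }
  for (v in c(flowrate_uL_per_s, titrant_normality, max_duration_s,
              stability_band_pH)) {
    if (!is.finite(v) || v <= 0) {
      stop("settings must be finite and > 0", call. = FALSE)
    }
  }
  if (!is.finite(inter_aliquot_wait_s) || inter_aliquot_wait_s < 0) {
    stop("'inter_aliquot_wait_s' must be >= 0", call. = FALSE)
  }
  structure(list(target_pH = target_pH, dosing_threshold = dosing_threshold,
                 aliquot_uL = aliquot_uL,
                 flowrate_uL_per_s = flowrate_uL_per_s,
                 inter_aliquot_wait_s = inter_aliquot_wait_s,
                 sampling_interval_s = sampling_interval_s,
                 titrant_normality = titrant_normality,
                 max_duration_s = max_duration_s,
                 stability_window_s = stability_window_s,
                 stability_band_pH = stability_band_pH),
            class = "titration_settings")
}

#' Should the controller dose at this tick?
#'
#' True iff the measured pH is strictly below `target_pH - dosing_threshold`
#' and the controller is not in a dispense/wait period. A reading exactly at
#' the threshold does not dose.
#'
#' @param measured_pH The read-back pH at this tick.
#' @param settings A [titration_settings()].
#' @param waiting Logical: is a dispense or the inter-aliquot wait still in
#'   progress?
#' @return Logical.
#' @export
dosing_decision <- function(measured_pH, settings, waiting = FALSE) {
  stopifnot(inherits(settings, "titration_settings"))
  !waiting && measured_pH < settings$target_pH - settings$dosing_threshold
}

in_fault <- function(t, fault_windows) {
  if (is.null(fault_windows)) return(FALSE)
  for (w in fault_windows) {
    if (t >= w[1] && t < w[2]) return(TRUE)
  }
  FALSE
}

#' Run a closed-loop pH-stat titration
#'
#' Discrete-time simulation of the firmware main loop at
#' `sampling_interval_s` ticks: optionally advance the lipolysis chemistry,
#' read the pH through the full instrument chain (analog output, bias
#' divider, ADC, bin-centre inversion), apply the dosing rule, dispense
#' quantized aliquots into the vessel, and append one log record per tick.
#' Mixing and acid-base re-equilibration are treated as instantaneous
#' (stirred vessel); sampling continues during the dispense time and the
#' inter-aliquot wait, but dosing is gated.
#'
#' Fault windows model a missing microSD card or a broken sensor cable: while
#' a fault is active the firmware holds -- no records are produced and no
#' dosing occurs -- and the run resumes when it clears (the chemistry,
#' being external reality, keeps evolving).
#'
#' @param state Initial [solution_state()] of the vessel.
#' @param settings A [titration_settings()].
#' @param calib A [calibration_settings()].
#' @param adc An [adc_config()].
#' @param pump A [pump_config()].
#' @param syringe Optional [syringe_state()]; defaults to a full syringe of
#'   `pump$syringe_capacity_uL`.
#' @param kinetics Optional [lipolysis_kinetics()] driving acid release.
#' @param noise_sd Sensor noise at the ADC node, volts (0 = noiseless).
#' @param seed Integer seed making a noisy run reproducible; the caller's
#'   RNG state is preserved. Ignored (and irrelevant) when `noise_sd = 0`.
#' @param pKw Water ion product used by the ground-truth solver.
#' @param fault_windows Optional list of `c(start_s, end_s)` fault intervals.
#' @param abort_at_s Simulated user abort time, seconds (default `Inf`).
#' @param header Optional named list of extra header fields for the log
#'   (e.g. a scenario name).
#' @return A [titration_log()] whose `stop_reason` is one of
#'   `"user_abort"`, `"endstop_syringe_empty"`, `"stability_reached"`,
#'   `"max_duration"`; the final chemistry, syringe and kinetics states are
#'   attached as attributes `final_state`, `final_syringe`, `final_kinetics`.
#' @examples
#' b <- make_phosphate_buffer(0.03898, 0.25)
#' log <- run_titration(b$state,
#'                      titration_settings(7, aliquot_uL = 50,
#'                                         max_duration_s = 900,
#'                                         stability_window_s = 60),
#'                      calibration_settings(6, 1), adc_config(),
#'                      pump_config(syringe_diameter_mm = 4.7,
#'                                  syringe_capacity_uL = 2000))
#' log$stop_reason
#' @export
run_titration <- function(state, settings, calib, adc, pump, syringe = NULL,
                          kinetics = NULL, noise_sd = 0, seed = NULL,
                          pKw = 14, fault_windows = NULL, abort_at_s = Inf,
                          header = list()) {
  stopifnot(inherits(state, "solution_state"),
            inherits(settings, "titration_settings"),
            inherits(calib, "calibration_settings"),
            inherits(adc, "adc_config"),
            inherits(pump, "pump_config"))
  if (is.null(syringe)) syringe <- syringe_state(pump$syringe_capacity_uL)
  if (!is.null(seed) && noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  q <- quantize_volume(settings$aliquot_uL, pump)
  dt <- settings$sampling_interval_s
  n_max <- floor(settings$max_duration_s / dt) + 1L

  t_v <- numeric(n_max); ph_v <- numeric(n_max)
  al_v <- integer(n_max); cum_v <- numeric(n_max)
  i <- 0L
  aliquots <- 0L
  cum_uL <- 0
  last_dose_t <- -Inf
  next_free_t <- -Inf
  j_win <- 1L  # left pointer of the stability window over the record vectors
  stop_reason <- NULL

  for (k in 0:(n_max - 1L)) {
    t <- k * dt
    if (t >= abort_at_s) { stop_reason <- "user_abort"; break }
    if (k > 0L && !is.null(kinetics)) {
      adv <- release_ffa(state, kinetics, dt)
      state <- adv$state
      kinetics <- adv$kinetics
    }
    if (in_fault(t, fault_windows)) next  # firmware holds: no record, no dose

    true_ph <- solve_ph(state, pKw)
    meas <- measure_ph(true_ph, calib, adc, noise_sd)
    waiting <- t < next_free_t
    hit_endstop <- FALSE

    if (!syringe$endstop && dosing_decision(meas, settings, waiting)) {
      d <- dispense(syringe, q$allowed_uL, settings$flowrate_uL_per_s)
      syringe <- d$syringe
      if (d$dispensed_uL > 0) {
        state <- add_titrant(state, d$dispensed_uL * 1e-6,
                             settings$titrant_normality)
        aliquots <- aliquots + 1L
        cum_uL <- cum_uL + d$dispensed_uL
        last_dose_t <- t
        next_free_t <- t + d$duration_s + settings$inter_aliquot_wait_s
      }
      hit_endstop <- syringe$endstop
    }

    i <- i + 1L
    t_v[i] <- t
    ph_v[i] <- round(meas, 3)
    al_v[i] <- aliquots
    cum_v[i] <- round(cum_uL, 2)

    if (hit_endstop) { stop_reason <- "endstop_syringe_empty"; break }

    if (t >= settings$stability_window_s &&
        last_dose_t <= t - settings$stability_window_s) {
      while (t_v[j_win] < t - settings$stability_window_s) j_win <- j_win + 1L
      win <- ph_v[j_win:i]
      if (max(win) - min(win) <= settings$stability_band_pH) {
        stop_reason <- "stability_reached"
        break
      }
    }
  }
  if (is.null(stop_reason)) stop_reason <- "max_duration"

  records <- data.frame(t_s = t_v[seq_len(i)], pH = ph_v[seq_len(i)],
                        aliquots = al_v[seq_len(i)],
                        cum_volume_uL = cum_v[seq_len(i)])
  hdr <- c(list(format_version = 1,
                target_pH = settings$target_pH,
                dosing_threshold = settings$dosing_threshold,
                aliquot_uL = q$allowed_uL,
                aliquot_requested_uL = settings$aliquot_uL,
                flowrate_uL_per_s = settings$flowrate_uL_per_s,
                inter_aliquot_wait_s = settings$inter_aliquot_wait_s,
                sampling_interval_s = settings$sampling_interval_s,
                titrant_normality = settings$titrant_normality,
                stability_window_s = settings$stability_window_s,
                stability_band_pH = settings$stability_band_pH,
                pH_at_0V = calib$pH_at_0V,
                pH_1V_range = calib$pH_1V_range,
                adc_bits = adc$bits,
                noise_sd = noise_sd),
           header)
  log <- titration_log(hdr, records, stop_reason)
  attr(log, "final_state") <- state
  attr(log, "final_syringe") <- syringe
  attr(log, "final_kinetics") <- kinetics
  log
}

#' Neutralize a sample before a lipolysis measurement
#'
#' Convenience wrapper around [run_titration()] for the pre-measurement
#' phase: small aliquots are dosed (no release kinetics) until the pH holds
#' at the target over the stability window, and the neutralized vessel state
#' is returned for the subsequent lipolysis run.
#'
#' @inheritParams run_titration
#' @param ... Passed on to [run_titration()].
#' @return A list with the phase `log` and the neutralized `state`.
#' @export
neutralization_phase <- function(state, settings, calib, adc, pump,
                                 syringe = NULL, ...) {
  log <- run_titration(state, settings, calib, adc, pump, syringe = syringe,
                       kinetics = NULL, ...)
  list(log = log, state = attr(log, "final_state"))
}
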