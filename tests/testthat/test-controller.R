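test_that("the dosing rule is a strict threshold gated by the wait", {
  s <- quick_settings(target_pH = 7)
  expect_true(dosing_decision(6.85, s, waiting = FALSE))
  expect_false(dosing_decision(6.90, s, waiting = FALSE))  # boundary: no dose
  expect_false(dosing_decision(6.5, s, waiting = TRUE))    # wait gate
  expect_false(dosing_decision(7.2, s, waiting = FALSE))
})

test_that("a sample already at target holds with zero aliquots", {
  ins <- default_instrument()
  st <- equilibrate_to_ph(buffer_state(), 7)
  log <- run_titration(st, quick_settings(), ins$calib, ins$adc, ins$pump)
  expect_identical(log$stop_reason, "stability_reached")
  expect_identical(max(log$records$aliquots), 0L)
  expect_equal(max(log$records$t_s), 60)  # the stability window itself
})

test_that("an undersized syringe ends the run at the endstop", {
  ins <- default_instrument()
  log <- run_titration(buffer_state(), quick_settings(aliquot_uL = 50),
                       ins$calib, ins$adc, ins$pump,
                       syringe = syringe_state(120))
  expect_identical(log$stop_reason, "endstop_syringe_empty")
  n <- nrow(log$records)
  expect_equal(log$records$cum_volume_uL[n], 120, tolerance = 0.01)
})

test_that("the closed loop neutralizes the buffer and never over-doses", {
  ins <- default_instrument()
  set <- quick_settings()
  log <- run_titration(buffer_state(), set, ins$calib, ins$adc, ins$pump)
  r <- log$records
  expect_identical(log$stop_reason, "stability_reached")

  # never dose at a read pH at or above target - threshold
  dosed <- c(FALSE, diff(r$aliquots) > 0)
  expect_true(all(r$pH[dosed] < set$target_pH - set$dosing_threshold))

  # cumulative volume non-decreasing and consistent with the aliquot count
  expect_true(all(diff(r$cum_volume_uL) >= 0))
  allowed <- log$header$aliquot_uL
  expect_equal(r$cum_volume_uL, round(r$aliquots * allowed, 2),
               tolerance = 0.011)

  # final read-back pH holds inside the deadband
  expect_gte(r$pH[nrow(r)], set$target_pH - set$dosing_threshold)

  # overshoot bound: the final true pH cannot exceed what a single aliquot
  # dosed right at the threshold would produce
  bound_state <- add_titrant(equilibrate_to_ph(buffer_state(),
                                               set$target_pH - set$dosing_threshold),
                             allowed * 1e-6, set$titrant_normality)
  expect_lte(solve_ph(attr(log, "final_state")), solve_ph(bound_state) + 1e-9)
})

test_that("after stability no further dosing ever occurs (noiseless)", {
  ins <- default_instrument()
  log <- run_titration(buffer_state(), quick_settings(), ins$calib, ins$adc,
                       ins$pump)
  st <- attr(log, "final_state")
  # re-run from the converged state: nothing more is dosed
  log2 <- run_titration(st, quick_settings(), ins$calib, ins$adc, ins$pump)
  expect_identical(max(log2$records$aliquots), 0L)
  expect_identical(log2$stop_reason, "stability_reached")
})

test_that("identical seeds give byte-identical logs; noise needs its seed", {
  ins <- default_instrument()
  set <- quick_settings()
  a <- run_titration(buffer_state(), set, ins$calib, ins$adc, ins$pump,
                     noise_sd = 0.005, seed = 42)
  b <- run_titration(buffer_state(), set, ins$calib, ins$adc, ins$pump,
                     noise_sd = 0.005, seed = 42)
  c <- run_titration(buffer_state(), set, ins$calib, ins$adc, ins$pump,
                     noise_sd = 0.005, seed = 43)
  expect_identical(write_log(a), write_log(b))
  expect_false(identical(write_log(a), write_log(c)))
})

test_that("fault windows hold the firmware: no records, then resume", {
  ins <- default_instrument()
  log <- run_titration(equilibrate_to_ph(buffer_state(), 7), quick_settings(),
                       ins$calib, ins$adc, ins$pump,
                       fault_windows = list(c(10, 20)))
  t <- log$records$t_s
  expect_false(any(t >= 10 & t < 20))
  expect_true(any(t >= 20))  # resumed after the fault cleared
})

test_that("a user abort stops the run with its own reason", {
  ins <- default_instrument()
  log <- run_titration(buffer_state(), quick_settings(), ins$calib, ins$adc,
                       ins$pump, abort_at_s = 30)
  expect_identical(log$stop_reason, "user_abort")
  expect_lt(max(log$records$t_s), 30)
})

test_that("neutralization phase returns a state the target re-accepts", {
  ins <- default_instrument()
  acidified <- equilibrate_to_ph(buffer_state(), 4.5)
  out <- neutralization_phase(acidified, quick_settings(), ins$calib,
                              ins$adc, ins$pump)
  expect_identical(out$log$stop_reason, "stability_reached")
  final_ph <- solve_ph(out$state)
  expect_gte(final_ph, 7 - 0.1 - 0.01)  # within the deadband (quantization slack)
  expect_lte(final_ph, 7.1)
  # idempotence: an immediate re-run doses nothing
  again <- neutralization_phase(out$state, quick_settings(), ins$calib,
                                ins$adc, ins$pump)
  expect_identical(max(again$log$records$aliquots), 0L)
})
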