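test_that("pure water is neutral and the residual contract holds", {
  w <- solution_state(1)
  ph <- solve_ph(w)
  expect_equal(ph, 7, tolerance = 1e-9)
  expect_lt(abs(charge_residual(ph, w)), 1e-12)
})

test_that("constructors enforce their invariants", {
  expect_error(acid_species("x", -1, 4), "non-negative|>= 0")
  expect_error(acid_species("x", 1, c(7, 3)), "ascending")
  expect_error(solution_state(0), "> 0")
  expect_error(make_phosphate_buffer(0, 0.25), "> 0")
  expect_error(make_phosphate_buffer(0.04, -1), "> 0")
  expect_error(add_titrant(buffer_state(), -1e-3, 0.1), ">= 0")
  expect_error(solve_ph(solution_state(1, fixed_ion_charge = -2)),
               "no sign change")
})

test_that("weighed phosphate mass maps to molarity and spectator sodium", {
  b <- make_phosphate_buffer(0.03898, 0.25)
  expect_equal(signif(b$molarity, 3), 1.13e-3)
  expect_equal(b$state$fixed_ion_charge, 0.03898 / 137.99)
  # hand arithmetic with MW 137.99 g/mol
  expect_equal(make_phosphate_buffer(0.137990, 1.0)$molarity, 1.000e-3,
               tolerance = 1e-12)
})

test_that("the manual buffer adjustment reaches pH ~7 with 1 mL of 0.1 N NaOH", {
  s <- add_titrant(buffer_state(), 1.0e-3, 0.1)
  expect_equal(s$strong_base_moles, 1e-4)
  expect_equal(s$volume_L, 0.251)
  ph <- solve_ph(s)
  expect_lt(abs(ph - 7), 0.15)
  expect_lt(abs(charge_residual(ph, s)), 1e-12)
})

test_that("equimolar H2PO4-/HPO4(2-) sits at pKa2 (Henderson-Hasselbalch)", {
  # 20 mM phosphate, half-converted by strong base: closed-form pH = pKa2
  s <- solution_state(1,
                      acids = list(acid_species("phosphate", 0.02,
                                                c(2.15, 7.21, 12.35))),
                      strong_base_moles = 0.01, fixed_ion_charge = 0.02)
  expect_equal(solve_ph(s), 7.21, tolerance = 1e-3)
})

test_that("solver matches the monoprotic quadratic closed form", {
  for (C in c(1e-3, 5e-3, 0.05)) {
    for (pKa in c(3, 4.2, 5)) {
      s <- solution_state(1, acids = list(acid_species("HA", C, pKa)))
      expect_lt(abs(solve_ph(s) - monoprotic_quadratic_ph(C, pKa)), 1e-6)
    }
  }
})

test_that("titrant addition is path-independent and conserves acid totals", {
  one <- add_titrant(buffer_state(), 1e-3, 0.1)
  many <- buffer_state()
  for (i in 1:10) many <- add_titrant(many, 1e-4, 0.1)
  expect_equal(solve_ph(many), solve_ph(one), tolerance = 1e-9)
  expect_equal(many$acids$phosphate$total_moles,
               buffer_state()$acids$phosphate$total_moles)
  expect_identical(add_titrant(buffer_state(), 0, 0.1), buffer_state())
})

test_that("solve_ph is strictly increasing in the strong-base total", {
  base <- seq(0, 2.5e-4, length.out = 30)
  ph <- vapply(base, function(b) {
    s <- buffer_state()
    s$strong_base_moles <- b
    solve_ph(s)
  }, numeric(1))
  expect_true(all(diff(ph) > 0))
})

test_that("charge-balance residual stays under 1e-12 across varied states", {
  set.seed(42)
  for (i in 1:25) {
    s <- solution_state(
      volume_L = runif(1, 0.01, 1),
      acids = list(acid_species("phosphate", runif(1, 0, 1e-3),
                                c(2.15, 7.21, 12.35)),
                   acid_species("FFA", runif(1, 0, 2e-3), 7.5)),
      strong_base_moles = runif(1, 0, 1e-3),
      fixed_ion_charge = runif(1, -1e-4, 1e-3)
    )
    expect_lt(abs(charge_residual(solve_ph(s), s)), 1e-12)
  }
})

test_that("the simulated titration curve is monotone with its flat point at pKa2", {
  vols <- seq(0, 2.0e-3, by = 2e-5)
  ph <- vapply(vols, function(v) solve_ph(add_titrant(buffer_state(), v, 0.1)),
               numeric(1))
  expect_true(all(diff(ph) > 0))
  slope <- diff(ph) / diff(vols)
  # buffering is strongest (slope minimal) at the half-equivalence point
  i_flat <- which.min(slope)
  expect_lt(abs(ph[i_flat] - 7.21), 0.3)
})

test_that("FFA release follows first-order saturation and conserves the pool", {
  kin <- lipolysis_kinetics(1e-3, rate_constant = 2e-3)
  st <- solution_state(0.04)

  # dt = 0 and k = 0 are identities
  expect_equal(release_ffa(st, kin, 0)$state, st)
  kin0 <- lipolysis_kinetics(1e-3, 0)
  expect_equal(release_ffa(st, kin0, 500)$kinetics$remaining_moles, 1e-3)

  # closed-form exponential: released(t) = pool * (1 - exp(-k t)), stepwise
  cur_s <- st; cur_k <- kin
  for (i in 1:40) {
    r <- release_ffa(cur_s, cur_k, 25)
    cur_s <- r$state; cur_k <- r$kinetics
  }
  released <- cur_s$acids$FFA$total_moles
  expect_equal(released, 1e-3 * (1 - exp(-2e-3 * 1000)), tolerance = 1e-9)
  expect_equal(released + cur_k$remaining_moles, 1e-3, tolerance = 1e-12)

  # t >> 1/k exhausts the pool
  r <- release_ffa(st, kin, 1e5)
  expect_equal(r$state$acids$FFA$total_moles, 1e-3, tolerance = 1e-6)

  # lag delays release
  kin_lag <- lipolysis_kinetics(1e-3, 2e-3, lag_s = 100)
  expect_equal(release_ffa(st, kin_lag, 100)$kinetics$remaining_moles, 1e-3)
})

test_that("released FFA monotonically depresses the pH at fixed base", {
  s <- equilibrate_to_ph(solution_state(0.04), 7)
  kin <- lipolysis_kinetics(2e-3, 1e-3)
  ph_prev <- solve_ph(s)
  for (i in 1:10) {
    r <- release_ffa(s, kin, 100)
    s <- r$state; kin <- r$kinetics
    ph_now <- solve_ph(s)
    expect_lt(ph_now, ph_prev)
    ph_prev <- ph_now
  }
})

test_that("equilibrate_to_ph pins a state at the requested pH exactly", {
  for (target in c(3, 5, 7, 9)) {
    s <- equilibrate_to_ph(buffer_state(), target)
    expect_equal(solve_ph(s), target, tolerance = 1e-9)
  }
})
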