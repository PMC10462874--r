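test_that("percent FFA implements the lipolysis stoichiometry", {
  a <- lipolysis_assay(W_lipid = 0.35, N_NaOH = 0.1, M_lipid = 885)
  expect_equal(percent_ffa(0, a), 0)
  # hand arithmetic: 100 * 2e-3 * 0.1 * 885 / (0.35 * 2)
  expect_equal(percent_ffa(2.0e-3, a), 25.29, tolerance = 1e-3)
  # full-hydrolysis equivalents give exactly 100%
  W <- 0.5; M <- 885; N <- 0.1
  V_full <- 2 * W / M / N
  expect_equal(percent_ffa(V_full, lipolysis_assay(W, N, M)), 100)
  # linear and homogeneous in the dosed volume
  v <- runif(20, 0, 5e-3)
  expect_equal(percent_ffa(3 * v, a), 3 * percent_ffa(v, a))
  expect_error(lipolysis_assay(W_lipid = 0), "> 0")
  expect_error(percent_ffa(-1e-3, a), ">= 0")
})

test_that("the FFA curve tracks the log volume and is monotone", {
  a <- lipolysis_assay(W_lipid = 0.4)
  # all-zero volumes -> flat zero curve
  flat <- titration_log(records = data.frame(t_s = 0:9, pH = rep(7, 10),
                                             aliquots = 0L,
                                             cum_volume_uL = 0))
  expect_true(all(ffa_curve(flat, a)$percent_ffa == 0))
  # a single aliquot is a step function
  step <- titration_log(records = data.frame(t_s = 0:9, pH = rep(7, 10),
                                             aliquots = rep(c(0L, 1L), each = 5),
                                             cum_volume_uL = rep(c(0, 50), each = 5)))
  cur <- ffa_curve(step, a)
  expect_identical(length(unique(cur$percent_ffa)), 2L)
  expect_true(all(diff(cur$percent_ffa) >= 0))
  # inconsistent constants are flagged, not hidden
  tiny <- lipolysis_assay(W_lipid = 1e-6)
  expect_warning(ffa_curve(step, tiny), "100")
  expect_error(ffa_curve(titration_log(), a), NA)
})

test_that("endpoint detection finds the quiet stable window", {
  quiet <- titration_log(records = data.frame(t_s = 0:700, pH = 7,
                                              aliquots = 0L,
                                              cum_volume_uL = 0))
  expect_equal(detect_endpoint(quiet), 0)
  # dosing until the final record: no endpoint
  busy <- titration_log(records = data.frame(t_s = 0:700, pH = 6.9,
                                             aliquots = 0:700,
                                             cum_volume_uL = (0:700) * 10))
  expect_true(is.na(detect_endpoint(busy)))
  # a log shorter than the window cannot contain one
  short <- titration_log(records = data.frame(t_s = 0:100, pH = 7,
                                              aliquots = 0L,
                                              cum_volume_uL = 0))
  expect_true(is.na(detect_endpoint(short)))
  # endpoint starts where dosing stops and the pH settles
  n <- 1000L
  al <- c(0:299, rep(300L, n - 300L))
  ph <- c(rep(6.9, 300), rep(7.0, n - 300))
  mixed <- titration_log(records = data.frame(t_s = 0:(n - 1L), pH = ph,
                                              aliquots = al,
                                              cum_volume_uL = al * 10))
  # t = 299 still sees the pre-dose pH 6.9 reading; the first window that is
  # both dose-free and inside the band starts at 300
  expect_equal(detect_endpoint(mixed), 300)
})

test_that("rate-constant recovery is exact on noiseless exponentials", {
  t <- seq(0, 4000, by = 5)
  for (k in c(2e-4, 1e-3, 6e-3)) {
    cur <- data.frame(t_s = t, percent_ffa = 35 * (1 - exp(-k * t)))
    fit <- recover_rate_constant(cur)
    expect_equal(fit$rate_constant, k, tolerance = 1e-6)
    expect_equal(fit$plateau, 35, tolerance = 1e-6)
  }
  expect_error(recover_rate_constant(data.frame(t_s = 0:9,
                                                percent_ffa = rep(2, 10))),
               class = "phstatsim_no_fit")
  expect_error(recover_rate_constant(data.frame(t_s = 0:3,
                                                percent_ffa = 1:4)),
               "5 distinct")
})

test_that("a closed-loop lipolysis run yields a recoverable rate and endpoint", {
  sim <- recovery_sim(1e-3)
  log <- sim$log

  # the curve matches the first-order ground truth within dosing granularity
  fit <- recover_rate_constant(sim$curve)
  expect_lt(abs(fit$rate_constant - 1e-3) / 1e-3, 0.10)

  # endpoint appears once dosing has ceased; by then the pool is nearly
  # exhausted (the deadband makes the last few percent titrimetrically
  # invisible, so full release is not observable)
  ep <- detect_endpoint(log, window_s = 600, band_pH = 0.02)
  expect_false(is.na(ep))
  r <- log$records
  dose_t <- r$t_s[c(FALSE, diff(r$aliquots) > 0)]
  expect_gte(ep, max(dose_t))
  released_at_ep <- 1 - exp(-1e-3 * ep)
  expect_gte(released_at_ep, 0.90)
})
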