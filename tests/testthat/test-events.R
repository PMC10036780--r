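# Measurement layer: resting potentials, AP detection, event classification,
# I-V diagrams, sweeps.

test_that("resting potential of a constant trace is that constant", {
  tr <- make_fixtures("flat")
  tr$V_myo_mV[] <- -86
  rp <- measure_resting_potentials(tr)
  expect_true(all(abs(rp$rp_myo_mV + 86) < 1e-12))
})

test_that("AP detection counts a synthetic pulse train exactly", {
  expect_identical(nrow(detect_action_potentials(make_fixtures("flat"))), 0L)
  aps <- detect_action_potentials(make_fixtures("plain-AP"))
  expect_identical(nrow(aps), 3L)
  expect_equal(aps$onset_ms, c(0, 1000, 2000), tolerance = 3)
  expect_true(all(is.finite(aps$apd90)))
})

test_that("classifier outcomes on template traces: none / EAD / extrasystole", {
  expect_identical(detect_triggered_activity(make_fixtures("flat"))$outcome,
                   "failure")  # no APs and no force at all
  ev_plain <- detect_triggered_activity(make_fixtures("plain-AP"))
  expect_identical(ev_plain$outcome, "none")
  ev_ead <- detect_triggered_activity(make_fixtures("EAD-template"))
  expect_identical(ev_ead$outcome, "EAD")
  expect_identical(nrow(ev_ead$eads), 1L)
  expect_gte(ev_ead$eads$amplitude_mv[1], 5)
  ev_ex <- detect_triggered_activity(make_fixtures("extrasystole-template"))
  expect_identical(ev_ex$outcome, "extrasystole")
  expect_identical(nrow(ev_ex$extrasystoles), 1L)
  expect_equal(ev_ex$first_extrasystole_ms, 1500, tolerance = 3)
})

test_that("extrasystoles are never attributed to stimulus-triggered upstrokes", {
  ev <- detect_triggered_activity(make_fixtures("extrasystole-template"))
  stim <- c(0, 1000, 2000)
  for (t0 in ev$extrasystoles$time_ms)
    expect_true(all(abs(t0 - stim) > 10))
})

test_that("a missing force channel downgrades confirmation with a warning", {
  tr <- make_fixtures("extrasystole-template")
  tr$F_active_norm <- NULL
  expect_warning(ev <- detect_triggered_activity(tr), "voltage-only")
  expect_identical(ev$outcome, "extrasystole")
})

test_that("a paced run yields exactly one AP per stimulus", {
  tr <- memo_run("single5s", simulate_ensemble(short_cfg(duration = 5000)))
  aps <- detect_action_potentials(tr)
  expect_identical(nrow(aps), 5L)
  ev <- suppressWarnings(detect_triggered_activity(tr))
  expect_identical(ev$outcome, "none")
})

test_that("mechanosensitive I-V lines cross zero at their reversal potentials", {
  iv <- msc_iv_curves(c(0.80, 0.90), seq(-100, 40, by = 1))
  for (k in 1:2) {
    line <- iv$lines[[k]]
    vr <- iv$curves$v_rev_mV[k]
    i_at_vr <- approx(line$V_mV, line$i_MS_pA, xout = vr)$y
    expect_equal(i_at_vr, 0, tolerance = 1e-9)
  }
  expect_equal(sort(iv$band_mV), c(-38, -30))
  # requesting the endpoint lengths reproduces the calibrated lines
  cal <- msc_calibration(FB)
  expect_equal(iv$curves$v_rev_mV, cal$v_rev(c(0.80, 0.90)))
})

test_that("vulnerability sweeps are reproducible and reduce at n = 0", {
  base <- ensemble_config("model2", n = 0, g_gap = 0.5, duration = 15000)
  s1 <- vulnerability_sweep(base, n_values = c(0, 2), g_gap_values = c(0.5, 3),
                            i_cal_multiplier = 1)
  s2 <- vulnerability_sweep(base, n_values = c(0, 2), g_gap_values = c(0.5, 3),
                            i_cal_multiplier = 1)
  expect_identical(s1$outcomes, s2$outcomes)
  expect_true(all(s1$outcomes == "none"))   # no triggered activity at norm
  # n = 0 cells match the single-myocyte outcome regardless of g_gap
  single <- suppressWarnings(detect_triggered_activity(
    simulate_ensemble(ensemble_config("single", duration = 15000))))
  expect_true(all(s1$outcomes["n0", ] == single$outcome))
})

test_that("threshold scan reports above-grid when nothing triggers", {
  base <- ensemble_config("single", duration = 10000)
  res <- threshold_scan(base, grid = c(1.0, 1.1))
  expect_true(is.na(res$any_triggered))
  expect_identical(nrow(res$runs), 2L)
})
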