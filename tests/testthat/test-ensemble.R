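# Assembly and integration of the coupled system.

test_that("a model1 ensemble with n = 0 reproduces the single myocyte exactly", {
  tr0 <- simulate_ensemble(short_cfg("single", duration = 2000))
  tr1 <- simulate_ensemble(short_cfg("model1", n = 0, g_gap = 1, duration = 2000))
  expect_equal(tr1$V_myo_mV, tr0$V_myo_mV, tolerance = 1e-14)
  expect_equal(tr1$Ca_i_mM, tr0$Ca_i_mM, tolerance = 1e-14)
})

test_that("identical configurations give bit-identical traces", {
  cfg <- short_cfg("model2", n = 2, g_gap = 2, duration = 1500)
  a <- simulate_ensemble(cfg)
  b <- simulate_ensemble(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("halving the integration step changes the potential by < 0.5 mV", {
  cfg1 <- short_cfg(duration = 2000, solver = list(dt = 0.02, output_dt = 1))
  cfg2 <- short_cfg(duration = 2000, solver = list(dt = 0.01, output_dt = 1))
  a <- simulate_ensemble(cfg1)
  b <- simulate_ensemble(cfg2)
  # the explicit solver shifts the near-discontinuous upstroke by a fraction
  # of a step; compare away from the 10 ms upstroke window
  last <- a$time_ms >= 1000 & (a$time_ms %% 1000) > 10
  expect_lt(max(abs(a$V_myo_mV[last] - b$V_myo_mV[last])), 0.5)
  apd <- function(tr) detect_action_potentials(tr[tr$time_ms >= 1000, ])$apd90[1]
  expect_lt(abs(apd(a) - apd(b)), 2)
})

test_that("state dimension mismatches are rejected", {
  cfg <- short_cfg("model2", n = 2, g_gap = 1, duration = 500)
  expect_error(simulate_ensemble(cfg, init = rest_state()), "dimension")
})

test_that("RyR occupancies remain normalized over a long trajectory", {
  cfg <- short_cfg(duration = 20000)
  tr <- simulate_ensemble(cfg)
  fin <- attr(tr, "final_state")
  occ <- fin[c("ryr_r", "ryr_o", "ryr_i", "ryr_ri")]
  expect_lt(abs(sum(occ) - 1), 1e-9)
  expect_true(all(occ >= 0))
})

test_that("the paced single myocyte settles to a period-1 rhythm", {
  ss <- run_to_steady_state(short_cfg(duration = 1000), max_beats = 30)
  expect_true(ss$converged)
  expect_false(ss$alternans)
  expect_lte(ss$beats_taken, 30)
})

test_that("doubling i_CaL produces SR-load alternans", {
  fin <- memo_run("x2_60s", {
    cfg <- ensemble_config("single", duration = 60000,
                           multipliers = list(i_CaL = 2))
    attr(simulate_ensemble(cfg), "final_state")
  })
  ss <- run_to_steady_state(
    ensemble_config("single", duration = 1000, multipliers = list(i_CaL = 2)),
    max_beats = 40, init = fin)
  expect_true(ss$alternans)
})

test_that("steady-state detector returns promptly for an already-settled input", {
  ss1 <- run_to_steady_state(short_cfg(duration = 1000), max_beats = 30)
  ss2 <- run_to_steady_state(short_cfg(duration = 1000), max_beats = 30,
                             init = ss1$final_state)
  expect_true(ss2$converged)
  expect_lte(ss2$beats_taken, 4)
})

test_that("force falls as fibroblast number and junctional conductance rise", {
  peak <- function(mode, n, g) {
    tr <- simulate_ensemble(ensemble_config(mode, n = n, g_gap = g,
                                            duration = 15000))
    max(tr$F_active_norm[tr$time_ms > 13000])
  }
  f_n0 <- peak("model2", 0, 3)
  f_n2 <- peak("model2", 2, 3)
  f_n4 <- peak("model2", 4, 3)
  expect_gt(f_n0, f_n2)
  expect_gt(f_n2, f_n4)
  f_g05 <- peak("model2", 4, 0.5)
  expect_gt(f_g05, f_n4)   # g_gap 0.5 vs 3.0 at n = 4
})

test_that("an extreme ensemble severely depresses contraction without arrhythmia", {
  cfg <- ensemble_config("model2", n = 10, g_gap = 4, duration = 120000)
  tr <- simulate_ensemble(cfg)
  ev <- suppressWarnings(detect_triggered_activity(tr))
  expect_lt(ev$peak_force, 0.2)   # > 80% loss versus the uncoupled norm
  expect_identical(nrow(ev$extrasystoles), 0L)
})
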