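# Fibroblast membrane model and the mechanosensitive current.

test_that("fibroblast inward rectifier vanishes at its K+ reversal", {
  ekf <- RTF * log(5.4 / FB$K_if)
  g <- fb_gate_tables(ekf)
  cur <- fb_ionic_currents(ekf, g["inf", "r_kv"], g["inf", "s_kv"], FB)
  expect_equal(cur$i_K1, 0, tolerance = 1e-12)
  expect_equal(cur$i_Kv, 0, tolerance = 1e-12)
})

test_that("default fibroblast capacitance is 6.3 pF", {
  expect_identical(FB$C_mf, 6.3)
})

test_that("uncoupled resting potential: bisection root equals ODE relaxation", {
  skip_if_not_installed("deSolve")
  v_root <- fb_resting_potential(FB)
  expect_gt(v_root, -90); expect_lt(v_root, 0)
  ode_fun <- function(t, y, p) {
    g <- fb_gate_tables(y[1])
    dv <- fb_membrane_derivative(y[1], y[2], y[3], v_myo = 0, g_gap = 0,
                                 mode = "model1", fb = FB)
    list(c(dv,
           (g["inf", "r_kv"] - y[2]) / g["tau", "r_kv"],
           (g["inf", "s_kv"] - y[3]) / g["tau", "s_kv"]))
  }
  out <- deSolve::ode(c(v = -20, r = 0.5, s = 0.5), seq(0, 20000, 100),
                      ode_fun, NULL, method = "lsoda")
  expect_equal(unname(out[nrow(out), "v"]), v_root, tolerance = 1e-3)
})

test_that("i_MS reverses at V_rev and has slope g_max at zero deformation", {
  cal <- msc_calibration(FB)
  for (L in c(0.80, 0.84, 0.90)) {
    vr <- cal$v_rev(L)
    expect_equal(msc_current(0, vr, L, FB), 0, tolerance = 1e-12)
  }
  slope <- (msc_current(0, -30, 0.9, FB) - msc_current(0, -50, 0.9, FB)) / 20
  expect_equal(slope, FB$g_max, tolerance = 1e-12)
})

test_that("i_MS sign band: depolarizing below -38 mV, repolarizing above -30 mV", {
  for (flip in c(1, 0)) {
    fb <- fibroblast_params(vrev_neg_at_long = flip)
    for (L in seq(0.80, 0.90, by = 0.01)) {
      dl <- L - 0.90
      for (v in c(-85, -60, -38.01)) expect_lt(msc_current(dl, v, L, fb), 0)
      for (v in c(-29.99, -10, 20)) expect_gt(msc_current(dl, v, L, fb), 0)
    }
  }
})

test_that("reversal-potential line hits its calibrated endpoints", {
  cal <- msc_calibration(FB)
  ends <- sort(cal$v_rev(c(FB$length_lo, FB$length_hi)))
  expect_equal(ends, c(-38, -30))
  mid <- cal$v_rev((FB$length_lo + FB$length_hi) / 2)
  expect_equal(mid, -34)                       # affine interpolation
  expect_equal(cal$a(0), 1)
  expect_error(msc_calibration(fibroblast_params(length_hi = 0.80)),
               "degenerate")
})

test_that("membrane derivative: rest balance and coupling sign", {
  vrest <- fb_resting_potential(FB)
  g <- fb_gate_tables(vrest)
  d0 <- fb_membrane_derivative(vrest, g["inf", "r_kv"], g["inf", "s_kv"],
                               v_myo = -85, g_gap = 0, mode = "model1", fb = FB)
  expect_equal(d0, 0, tolerance = 1e-8)
  # a more depolarized myocyte pulls the fibroblast up
  d_up <- fb_membrane_derivative(vrest, g["inf", "r_kv"], g["inf", "s_kv"],
                                 v_myo = vrest + 30, g_gap = 1,
                                 mode = "model1", fb = FB)
  expect_gt(d_up, d0)
  expect_error(fb_membrane_derivative(-50, 0.1, 0.9, -85, g_gap = -1), "g_gap")
})

test_that("coupled fibroblast rests higher with the mechanosensitive current", {
  rp1 <- memo_run("rp_m1_n2g2", settled_rp("model1", 2, 2))
  rp2 <- memo_run("rp_m2_n2g2", settled_rp("model2", 2, 2))
  expect_gt(rp2$cf, rp1$cf)
  expect_gt(rp2$myo, rp1$myo)
})
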