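# Electrophysiology of the myocyte: currents, gating, RyR release, SR fluxes,
# stimulus generation.

test_that("potassium currents vanish at the K+ reversal potential", {
  st <- rest_state()
  ek <- RTF * log(MYO$K_o / st[["K_i"]])
  st[["V"]] <- ek
  cur <- ep_currents(st, MYO)
  expect_equal(cur$i_K1, 0, tolerance = 1e-12)
  expect_equal(cur$i_Kr, 0, tolerance = 1e-12)
  expect_equal(cur$i_to, 0, tolerance = 1e-12)
  expect_equal(cur$i_pK, 0, tolerance = 1e-12)
})

test_that("i_CaL scales linearly with its multiplier, other currents unchanged", {
  st <- rest_state()
  st[["V"]] <- -20  # away from rest so i_CaL is non-trivial
  st[["d"]] <- 0.5; st[["f"]] <- 0.7
  c1 <- ep_currents(st, myocyte_params(x_ical = 1))
  c2 <- ep_currents(st, myocyte_params(x_ical = 2))
  expect_equal(c2$i_CaL, 2 * c1$i_CaL, tolerance = 1e-12)
  for (nm in c("i_Na", "i_K1", "i_Kr", "i_Ks", "i_NaCa", "i_NaK", "i_pCa"))
    expect_identical(c2[[nm]], c1[[nm]])
})

test_that("i_myo_total is the sum of the sarcolemmal currents", {
  st <- rest_state()
  st[["V"]] <- -30
  cur <- ep_currents(st, MYO)
  parts <- c("i_CaL", "i_bCa", "i_K1", "i_to", "i_Kr", "i_Ks", "i_pK",
             "i_Na", "i_bNa", "i_pCa", "i_NaK", "i_NaCa")
  expect_equal(cur$i_myo_total, sum(unlist(cur[parts])),
               tolerance = 1e-12)
})

test_that("algebraic resting root (bisection) matches the ODE relaxation limit", {
  # oracle: root of the total membrane current with every gate at its
  # voltage steady state and concentrations frozen at the paced snapshot
  st <- rest_state()
  total_at <- function(v) {
    s <- st
    s[["V"]] <- v
    tab <- gate_tables(v, s[["Ca_ss"]])
    s[c("m","h","j","xr1","xr2","xs","r","s","d","f","f2","fcass")] <- tab["inf", ]
    ep_currents(s, MYO)$i_myo_total
  }
  v_root <- uniroot(total_at, c(-90, -70), tol = 1e-10)$root
  expect_lt(abs(total_at(v_root)), 1e-8)   # zero net current at the root
  # relaxation limit: integrate 8 s with the stimulus disabled; the slow ion
  # pools keep drifting, so agreement is to a fraction of a millivolt
  cfg <- short_cfg(duration = 8000,
                   pacing = list(amplitude = 0))
  tr <- simulate_ensemble(cfg)
  v_relax <- tr$V_myo_mV[nrow(tr)]
  expect_lt(abs(v_root - v_relax), 0.5)
})

test_that("gate derivatives vanish at steady state and relax monotonically", {
  st <- rest_state()
  tab <- gate_tables(st[["V"]], st[["Ca_ss"]])
  st[c("m","h","j","xr1","xr2","xs","r","s","d","f","f2","fcass")] <- tab["inf", ]
  expect_equal(unname(gating_derivatives(st)), rep(0, 12), tolerance = 1e-12)
  st[["xs"]] <- tab["inf", "xs"] / 2   # below steady state -> rate > 0
  expect_gt(gating_derivatives(st)[["xs"]], 0)
  st[["xs"]] <- min(1, tab["inf", "xs"] * 2 + 0.1)
  expect_lt(gating_derivatives(st)[["xs"]], 0)
})

test_that("voltage-clamped gates follow the closed-form exponential", {
  skip_if_not_installed("deSolve")
  v <- -20
  tab <- gate_tables(v, 0.0001)
  g0 <- 0.1
  ode_fun <- function(t, y, p) {
    st <- rest_state()
    st[["V"]] <- v
    st[["xs"]] <- y[1]
    list(gating_derivatives(st)[["xs"]])
  }
  times <- seq(0, 200, by = 20)
  num <- deSolve::ode(c(xs = g0), times, ode_fun, NULL)[, "xs"]
  closed <- tab["inf", "xs"] + (g0 - tab["inf", "xs"]) * exp(-times / tab["tau", "xs"])
  expect_equal(unname(num), unname(closed), tolerance = 1e-5)
})

test_that("RyR release is zero with closed channels and conserves occupancy", {
  st <- rest_state()
  st[["ryr_r"]] <- 1; st[["ryr_o"]] <- 0; st[["ryr_i"]] <- 0; st[["ryr_ri"]] <- 0
  rel <- ryr_release(st, MYO)
  expect_identical(rel$I_rel, 0)
  # derivative conservation at assorted states
  for (occ in list(c(0.7, 0.1, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25))) {
    st[c("ryr_r", "ryr_o", "ryr_i", "ryr_ri")] <- occ
    st[["Ca_ss"]] <- 0.01
    expect_lt(abs(sum(ryr_release(st, MYO)$d_occ)), 1e-12)
  }
})

test_that("RyR shows post-release refractoriness to a second Ca pulse", {
  skip_if_not_installed("deSolve")
  # direct integration of the gating scheme under two identical subspace Ca
  # pulses 300 ms apart, luminal Ca clamped
  pulse <- function(t) ifelse((t >= 0 & t < 10) | (t >= 300 & t < 310), 0.3, 0.0003)
  ode_fun <- function(t, y, p) {
    st <- rest_state()
    st[c("ryr_r", "ryr_o", "ryr_i", "ryr_ri")] <- y / sum(y)
    st[["Ca_ss"]] <- pulse(t)
    st[["Ca_sr"]] <- 3.5
    list(unname(ryr_release(st, MYO)$d_occ))
  }
  times <- seq(0, 600, by = 0.5)
  y <- deSolve::ode(c(r = 1, o = 0, i = 0, ri = 0), times, ode_fun, NULL,
                    method = "lsoda")
  o <- y[, "o"]
  peak1 <- max(o[times < 300])
  peak2 <- max(o[times >= 300])
  expect_gt(peak1, 0)
  expect_lt(peak2, peak1)
})

test_that("SR flux laws: saturable uptake, linear leak and transfer", {
  st <- rest_state()
  st[["Ca_i"]] <- 1e-12
  expect_lt(sr_cytosol_fluxes(st, MYO)$I_up, 1e-15)
  st <- rest_state()
  st[["Ca_sr"]] <- st[["Ca_i"]]
  expect_equal(sr_cytosol_fluxes(st, MYO)$I_leak, 0, tolerance = 1e-18)
  st <- rest_state()
  f1 <- sr_cytosol_fluxes(st, myocyte_params(x_serca = 1))$I_up
  f05 <- sr_cytosol_fluxes(st, myocyte_params(x_serca = 0.5))$I_up
  expect_equal(f05, f1 / 2, tolerance = 1e-12)
})

test_that("stimulus pulses land on the pacing grid", {
  prot <- list(frequency_hz = 1, amplitude = -52, duration = 1, start = 0)
  expect_equal(apply_stimulus(c(0, 1000, 2000, 2000.5), prot), rep(-52, 4))
  expect_equal(apply_stimulus(c(500, 1500, 999.9), prot), rep(0, 3))
  # pulse integral independent of period
  tt <- seq(0, 5000, by = 0.01)
  for (f in c(1, 2)) {
    p2 <- modifyList(prot, list(frequency_hz = f))
    s <- apply_stimulus(tt, p2)
    n_pulses <- f * 5
    expect_equal(sum(s) * 0.01 / n_pulses, -52 * 1, tolerance = 0.02)
  }
  expect_error(apply_stimulus(10, list(frequency_hz = 0)), "positive")
})

test_that("invalid states are rejected with a diagnostic naming the variable", {
  st <- rest_state()
  st[["Ca_i"]] <- NaN
  expect_error(ep_currents(st, MYO), "Ca_i")
  st <- rest_state()
  st[["ryr_o"]] <- 0.8  # breaks the occupancy sum
  expect_error(ryr_release(st, MYO), "sum to 1")
})
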