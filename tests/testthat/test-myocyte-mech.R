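# Mechanics: cooperative Ca-TnC kinetics, cross-bridge kinetics, element
# forces and the isometric force balance.

test_that("Ca-TnC kinetics: zero flux with empty pool, cooperative off-rate", {
  expect_identical(catnc_rate(0, 0, 0, MYO), 0)
  # off-rate falls as attached cross-bridges rise
  k01 <- catnc_koff(30, 0.1, MYO)
  k05 <- catnc_koff(30, 0.5, MYO)
  expect_lt(k05, k01)
  # strictly decreasing along a fine grid
  ks <- vapply(seq(0, 1, by = 0.05), function(n) catnc_koff(30, n, MYO),
               numeric(1))
  expect_true(all(diff(ks) < 0))
  expect_error(catnc_rate(80, 0.001, 0.2, MYO), "troponin")
})

test_that("freezing the off-rate reduces the later dissociation flux", {
  # engage the clamp at mid-relaxation values, then let N_xb fall further:
  # the unclamped off-rate rises while the frozen one does not
  koff_frz <- catnc_koff(40, 0.4, MYO)
  flux_frozen <- koff_frz * 30
  flux_coop <- catnc_koff(30, 0.2, MYO) * 30  # later: fewer Xbs, less CaTnC
  expect_gt(flux_coop, flux_frozen)
})

test_that("cross-bridge kinetics: decay without activation, bounded fraction", {
  expect_lt(xb_kinetics(0.5, 0, 0.09, 0, MECH), 0)
  expect_lte(xb_kinetics(1, 60, 0.09, 0, MECH), 0)
  expect_gte(xb_kinetics(0, 60, 0.09, 0, MECH), 0)
})

test_that("length-dependent activation: higher steady N_xb at longer sarcomere", {
  # fixed-point solve of dN_xb/dt = 0 at the two lengths (equal CaTnC)
  nss <- function(l1) uniroot(function(n) xb_kinetics(n, 40, l1, 0, MECH),
                              c(0, 1), tol = 1e-12)$root
  expect_gt(nss(0.10), nss(0.00))  # sarcomere at 90% vs 80% of L_max
})

test_that("element forces: slack zero, convexity, shared PE/PEfb pair", {
  f0 <- element_forces(0, 0, 0, 0, 0, 0, 0, MECH)
  expect_equal(f0$F_PEfb, 0)
  expect_equal(f0$F_PE, 0)
  l2 <- seq(0.01, 0.09, by = 0.01)
  fb <- vapply(l2, function(l) element_forces(l, l, 0, 0, 0, 0, 0, MECH)$F_PEfb,
               numeric(1))
  expect_true(all(diff(fb) > 0))            # strictly increasing
  expect_true(all(diff(diff(fb)) > 0))      # convex
  for (l in c(0.02, 0.05, 0.08)) {
    f <- element_forces(l, l, 0, 0, 0, 0, 0, MECH)
    expect_equal(f$F_PE, f$F_PEfb, tolerance = 1e-15)
  }
})

test_that("isometric balance: passive statics and fibroblast load terms", {
  rest <- passive_rest_lengths(0.90, 0L, MECH)
  sol <- solve_isometric_balance(rest$l1, rest$l2, 0, L = 0.90, n = 0, MECH)
  expect_lt(abs(sol$residual), 1e-8)
  expect_lt(abs(sol$v1), 1e-10)   # static at rest
  expect_lt(abs(sol$dl2), 1e-10)
  # each added fibroblast adds one F_PEfb term, slackening the branch
  sol2 <- solve_isometric_balance(rest$l1, rest$l2, 0, L = 0.90, n = 3, MECH)
  expect_equal(sol2$dl2, sol$dl2 - 3 * sol2$F_PEfb / MECH$nu_vs1,
               tolerance = 1e-12)
})

test_that("force-balance residual stays below 1e-8 along a paced twitch", {
  tr <- memo_run("single5s", simulate_ensemble(short_cfg(duration = 5000)))
  expect_lt(attr(tr, "max_residual"), 1e-8)
})

test_that("sarcomeres shorten but stay above 80% L_max in a 90% isometric run", {
  tr <- memo_run("single5s", simulate_ensemble(short_cfg(duration = 5000)))
  expect_lt(min(tr$sarc_frac), max(tr$sarc_frac))  # shortening happened
  expect_gt(min(tr$sarc_frac), 0.80)
  expect_lte(max(tr$sarc_frac), 0.90)
})

test_that("peak twitch force is normalized to 1 and ordered in length", {
  tr90 <- memo_run("single5s", simulate_ensemble(short_cfg(duration = 5000)))
  expect_equal(max(tr90$F_active_norm), 1.0, tolerance = 0.01)
  f <- vapply(c(0.80, 0.85), function(L) {
    trl <- simulate_ensemble(short_cfg(duration = 4000, initial_length = L))
    max(trl$F_active_norm[trl$time_ms > 3000])
  }, numeric(1))
  expect_lt(f[1], f[2])   # 80% < 85%
  expect_lt(f[2], max(tr90$F_active_norm[tr90$time_ms > 4000]))  # < 90%
})

test_that("N_xb stays within [0, 1] along a paced run", {
  tr <- memo_run("single5s", simulate_ensemble(short_cfg(duration = 5000)))
  expect_true(all(tr$N_xb >= 0 & tr$N_xb <= 1))
})
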