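test_that("gating_steady matches the closed-form tanh curve", {
  # midpoint symmetry
  expect_identical(gating_steady(-1.2, -1.2, 18), 0.5)
  # one slope-length above midpoint
  expect_equal(gating_steady(-1.2 + 18, -1.2, 18), 0.5 * (1 + tanh(1)),
               tolerance = 1e-15)
  expect_equal(0.5 * (1 + tanh(1)), 0.8807970779778823)
  # deep hyperpolarization: sodium activation essentially shut
  m70 <- gating_steady(-70, -1.2, 18)
  expect_equal(m70, 0.5 * (1 + tanh((-70 + 1.2) / 18)), tolerance = 1e-15)
  expect_lt(m70, 5e-4)
  expect_gt(m70, 4e-4)
  # monotone with the sign of gamma
  V <- seq(-100, 50, 1)
  expect_true(all(diff(gating_steady(V, -20, 10)) > 0))
  expect_true(all(diff(gating_steady(V, -28, -14)) < 0))
  expect_true(all(gating_steady(V, -20, 10) > 0 &
                    gating_steady(V, -20, 10) < 1))
  expect_error(gating_steady(-70, -1.2, 0), "gamma")
})

test_that("gating_tau is the even sech curve with maximum 1 at beta", {
  expect_identical(gating_tau(-20, -20, 10), 1)
  expect_equal(gating_tau(-20 + 2 * 10, -20, 10), 1 / cosh(1),
               tolerance = 1e-15)
  expect_equal(1 / cosh(1), 0.6480542736638855)
  for (x in c(0.5, 3, 17, 42))
    expect_identical(gating_tau(-20 + x, -20, 10),
                     gating_tau(-20 - x, -20, 10))
  expect_error(gating_tau(-70, -20, 0), "gamma")
})

test_that("parameter presets carry the published values", {
  d <- neuron_params()
  expect_equal(d[c("C", "g_Na_bar", "E_Na", "beta_m", "gamma_m",
                   "g_K_bar", "E_K", "phi_w", "beta_w", "gamma_w",
                   "g_leak", "E_leak", "beta_h", "gamma_h", "phi_h")],
               list(C = 2, g_Na_bar = 20, E_Na = 50, beta_m = -1.2,
                    gamma_m = 18, g_K_bar = 20, E_K = -100, phi_w = 0.15,
                    beta_w = -20, gamma_w = 10, g_leak = 2, E_leak = -70,
                    beta_h = -28, gamma_h = -14, phi_h = 0.005))
  expect_identical(d$p, 0)
  r <- neuron_params("revised")
  expect_identical(r$g_leak, 0.7)
  expect_identical(r$g_K_bar, 30)
  expect_identical(r$g_Na_bar, d$g_Na_bar)
  cb <- neuron_params("cable")
  expect_identical(cb$g_Na_bar, 30)
  expect_identical(cb$g_K_bar, 30)
})

test_that("parameter invariants are enforced", {
  expect_error(neuron_params(C = -1), "C must be")
  expect_error(neuron_params(p = 1.5), "p must lie")
  expect_error(neuron_params(gamma_h = 14), "gamma_h")
  expect_error(neuron_params(g_K_bar = -3), "g_K_bar")
  expect_error(neuron_params(nonsense = 1), "unknown parameter")
  # a field named p must not be swallowed by partial matching
  expect_identical(neuron_params(p = 1)$p, 1)
})

test_that("capacitance normalization converts densities both ways", {
  expect_identical(nspf_to_density(2, C = 2), 4)
  expect_identical(density_to_nspf(4, C = 2), 2)
  expect_identical(papf_to_density(10, C = 2), 20)
  g <- c(0.3, 1.7, 9)
  expect_equal(density_to_nspf(nspf_to_density(g, 2), 2), g)
})

test_that("membrane_rhs reduces to the expected limits", {
  st <- c(V = -50, w = 0.1, h = 0.9)
  # bare capacitor
  p0 <- neuron_params(g_Na_bar = 0, g_K_bar = 0, g_leak = 0)
  expect_equal(membrane_rhs(st, 0, p0, i_stim = 6)[["dV"]], 6 / p0$C)
  # leak equilibrium
  pl <- neuron_params(g_Na_bar = 0, g_K_bar = 0)
  expect_equal(membrane_rhs(c(V = -70, w = 0, h = 1), 0, pl)[["dV"]], 0)
  # h = 1 makes the inactivating split invisible at any p
  d0 <- membrane_rhs(c(V = -30, w = 0.2, h = 1), 0, neuron_params(p = 0))
  d5 <- membrane_rhs(c(V = -30, w = 0.2, h = 1), 0, neuron_params(p = 0.5))
  expect_identical(d0[["dV"]], d5[["dV"]])
  # with p = 0 the inactivation parameters cannot influence dV (Eq 7 -> Eq 1)
  a <- membrane_rhs(st, 0, neuron_params(p = 0))
  b <- membrane_rhs(st, 0, neuron_params(p = 0, beta_h = -60, phi_h = 1))
  expect_identical(a[["dV"]], b[["dV"]])
  expect_identical(a[["dw"]], b[["dw"]])
  expect_error(membrane_rhs(c(V = NaN, w = 0, h = 1), 0, neuron_params()),
               "non-finite")
})

test_that("resting_state is a genuine fixed point near the leak reversal", {
  p <- neuron_params()
  rs <- resting_state(p)
  expect_equal(rs[["V"]], -69.4053, tolerance = 1e-3)
  d <- membrane_rhs(rs, 0, p)
  expect_true(all(abs(d) < 1e-9))
  # independent check: the ODE relaxes to the same point from elsewhere
  tr <- simulate_neuron(p, list(), t_end = 3000,
                        state0 = c(V = -60,
                                   w = gating_steady(-60, p$beta_w,
                                                     p$gamma_w),
                                   h = gating_steady(-60, p$beta_h,
                                                     p$gamma_h)))
  expect_equal(tr$V[nrow(tr)], rs[["V"]], tolerance = 1e-3)
  # leak-only model rests exactly at E_leak
  pl <- neuron_params(g_Na_bar = 0, g_K_bar = 0)
  expect_equal(resting_state(pl)[["V"]], -70, tolerance = 1e-8)
})

test_that("gating variables stay inside the unit box along trajectories", {
  stims <- list(conductance_step(3, -20),
                synaptic_fast(4, -10),
                current_step(30))
  for (p in list(neuron_params(beta_w = -10, p = 0.7),
                 neuron_params("revised", p = 1))) {
    for (s in stims) {
      tr <- simulate_neuron(p, s, t_end = 800)
      expect_true(all(tr$w >= 0 & tr$w <= 1))
      expect_true(all(tr$h >= 0 & tr$h <= 1))
    }
  }
})
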