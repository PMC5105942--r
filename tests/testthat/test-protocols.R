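test_that("titration brackets the minimum spiking conductance", {
  cc <- pt_c()
  res <- find_min_ggaba(cc$params, synaptic_fast(1, cc$e_gaba),
                        resolution = 0.01)
  expect_lte(res$min_g_bar, 2)       # fast input spikes at 2 nS/pF here
  expect_gt(res$min_g_bar, 0)
  # bracketing invariant: spiking at the minimum, none one step below
  at_min <- label_of(cc$params, synaptic_fast(res$min_g_bar, cc$e_gaba))
  below <- label_of(cc$params,
                    synaptic_fast(res$min_g_bar - res$resolution,
                                  cc$e_gaba))
  expect_false(at_min == "none")
  expect_identical(below, "none")
})

test_that("slow-onset input needs more conductance in the transient regime", {
  cc <- pt_c()
  fast <- find_min_ggaba(cc$params, synaptic_fast(1, cc$e_gaba),
                         resolution = 0.01)
  slow <- find_min_ggaba(cc$params, synaptic_slow(1, cc$e_gaba),
                         resolution = 0.01)
  expect_lte(fast$min_g_bar, 2)
  expect_gt(slow$min_g_bar, 2)
  expect_lte(slow$min_g_bar, 3.5)
})

test_that("a purely shunting input never elicits spikes", {
  res <- find_min_ggaba(neuron_params(beta_w = -10),
                        conductance_step(1, -70), upper = 10,
                        resolution = 0.05)
  expect_true(is.na(res$min_g_bar))
})

test_that("shunt non-monotonicity is detected and worked around", {
  # near beta_w = 0 at E_GABA = -20 mV, moderate steps spike but strong
  # steps are fully shunted, so the bisection upper bound is silent and
  # the fallback scan must recover the spiking window
  p <- neuron_params(beta_w = -2)
  bis <- find_min_ggaba(p, conductance_step(1, -20), upper = 10,
                        resolution = 0.05)
  expect_false(is.na(bis$min_g_bar))
  expect_true(bis$non_monotone)
  sc <- find_min_ggaba(p, conductance_step(1, -20), upper = 10,
                       resolution = 0.05, scan = TRUE)
  expect_false(is.na(sc$min_g_bar))
  expect_true(sc$non_monotone)
  # both routes land on the same spiking onset
  expect_lt(abs(sc$min_g_bar - bis$min_g_bar), 2 * 0.05)
  expect_false(label_of(p, conductance_step(sc$min_g_bar, -20)) == "none")
})

test_that("kinetics comparison flags rate sensitivity by regime", {
  cc <- pt_c()
  k <- compare_kinetics(cc$params, e_rev = cc$e_gaba, upper = 6,
                        resolution = 0.02)
  expect_true(k$rate_sensitive)
  expect_gt(k$min_g_bar[["slow"]], k$min_g_bar[["fast"]])
  # a ramp at 2.5x the step minimum still fails to elicit spiking
  expect_identical(k$ramp_spikes_at_factor, 0L)
  # repetitive regime: spike initiation depends on amplitude only, so
  # the fast and slow minima nearly coincide
  ee <- pt_e()
  k2 <- compare_kinetics(ee$params, e_rev = ee$e_gaba, upper = 6,
                         resolution = 0.02)
  expect_false(k2$rate_sensitive)
  expect_lt(abs(k2$min_g_bar[["slow"]] - k2$min_g_bar[["fast"]]) /
              k2$min_g_bar[["fast"]], 0.1)
  # amplitude-only initiation: slow, step and ramp minima coincide
  expect_equal(k2$min_g_bar[["slow"]], k2$min_g_bar[["step"]],
               tolerance = 2 * k2$resolution)
  expect_equal(k2$min_g_bar[["slow"]], k2$min_g_bar[["ramp"]],
               tolerance = 2 * k2$resolution)
  # the slow/fast ratio cleanly separates the regimes
  expect_gt(k$min_g_bar[["slow"]] / k$min_g_bar[["fast"]],
            k2$min_g_bar[["slow"]] / k2$min_g_bar[["fast"]])
})

test_that("excitability manipulations lower the titrated minimum", {
  p <- neuron_params(beta_w = -14)
  inp <- synaptic_fast(1, -20)
  before <- find_min_ggaba(p, inp, resolution = 0.02)
  after <- find_min_ggaba(apply_4ap_analog(p, 10), inp,
                          resolution = 0.02)
  expect_lt(after$min_g_bar, before$min_g_bar)
  # depolarizing E_GABA shift likewise, in a cell that spikes at both
  # reversal potentials (the revised, more sensitive membrane)
  p2 <- neuron_params("revised", beta_w = -5)
  m35 <- find_min_ggaba(p2, synaptic_fast(1, -35), resolution = 0.02)
  m20 <- find_min_ggaba(p2, synaptic_fast(1, -20), resolution = 0.02)
  expect_lt(m20$min_g_bar, m35$min_g_bar)
})

test_that("virtual sodium is inert at zero and enables repetitive firing", {
  p <- neuron_params(beta_w = -10)
  tr0 <- simulate_neuron(p, conductance_step(2, -20), t_end = 400)
  tr1 <- simulate_neuron(add_virtual_sodium(p, 0),
                         conductance_step(2, -20), t_end = 400)
  expect_identical(tr0$V, tr1$V)
  # with the 4-AP analog, a persistent virtual sodium conductance
  # activating near rest produces spontaneous repetitive spiking at zero
  # stimulus when inserted into the resting cell, and then slow or step
  # input drives repetitive spiking
  hot <- add_virtual_sodium(apply_4ap_analog(neuron_params(), 10), 0.3,
                            beta = -60, gamma = 10)
  spont <- simulate_neuron(hot, list(), t_end = 1500,
                           state0 = resting_state(neuron_params()))
  sp <- detect_spikes(spont)$times
  expect_gt(length(sp), 10)
  expect_gt(max(sp), 1200)     # sustained, not an insertion transient
  expect_identical(label_of(hot, synaptic_slow(2, -20),
                            state0 = resting_state(neuron_params())),
                   "repetitive")
  expect_identical(label_of(hot, conductance_step(2, -20),
                            state0 = resting_state(neuron_params())),
                   "repetitive")
  expect_error(add_virtual_sodium(p, -1), "g_na_virtual")
})

test_that("rheobase rises with shunting conductance, E_GABA secondary", {
  p <- neuron_params(p = 1)
  rb <- sapply(c(-35, -20), function(E)
    sapply(c(0, 2, 4), function(g)
      as.numeric(rheobase(p, g_bar = g, e_rev = E, resolution = 0.25))))
  expect_true(all(is.finite(rb)))
  expect_true(all(rb > 0))
  expect_true(all(diff(rb[, 1]) > 0))
  expect_true(all(diff(rb[, 2]) > 0))
  # the E_GABA effect at matched conductance is small relative to the
  # conductance effect
  e_effect <- max(abs(rb[, 1] - rb[, 2]))
  g_effect <- mean(rb[3, ] - rb[1, ])
  expect_lt(e_effect, g_effect)
})

test_that("rheobase reports none-found when the bracket is too small", {
  rb <- rheobase(neuron_params(), g_bar = 0, upper = 1)
  expect_true(is.na(rb))
  expect_true(attr(rb, "none_found"))
})

test_that("inhibition assay resolves epoch structure and spike heights", {
  p <- neuron_params(beta_w = 0, p = 1)
  thr <- repetitive_current_threshold(p)
  amp <- 1.5 * thr
  # no conductance: uninterrupted repetitive spiking, no attenuation
  a0 <- inhibition_assay(p, g_bar = 0, e_rev = -35, i_amp = amp)
  expect_gt(a0$spikes_before, 0)
  expect_gt(a0$spikes_during, 0)
  expect_gt(a0$spikes_after, 0)
  expect_false(a0$inhibited_stop)
  # strong conductance inside the current step: silence during overlap,
  # spiking resumes after the conductance ends
  a1 <- inhibition_assay(p, g_bar = 4, e_rev = -35, i_amp = amp)
  expect_true(a1$inhibited_stop)
  expect_true(a1$inhibited_reduce)
  expect_gt(a1$spikes_after, 0)
  # moderate conductance: spikes during the step are shorter than outside
  a2 <- inhibition_assay(p, g_bar = 1, e_rev = -35, i_amp = amp)
  if (a2$spikes_during > 0)
    expect_lt(a2$spike_height_in, a2$spike_height_out)
  # conductance leading the current step: the cell spikes at the
  # conductance onset yet sustained repetitive spiking starts only after
  # the conductance ends
  hot <- neuron_params(beta_w = -5, p = 1)
  thr2 <- repetitive_current_threshold(hot)
  alone <- classify_trace(hot, conductance_step(4, -20, t_on = 100,
                                                duration = 400))
  expect_gte(alone$n_spikes, 1)
  a3 <- inhibition_assay(hot, g_bar = 4, e_rev = -20,
                         i_amp = 1.5 * thr2, ordering = "g_before_i")
  expect_true(a3$inhibited_stop)
  expect_lte(a3$spikes_during, 2)
  expect_gt(a3$spikes_after, 10)
})

test_that("coexistence: one conductance step both spikes and inhibits", {
  p0 <- neuron_params(beta_w = 0, p = 1)
  thr <- repetitive_current_threshold(p0)
  gi <- conductance_step(2, -20, t_on = 400, duration = 400)
  alone <- classify_trace(p0, gi)
  expect_gt(alone$n_spikes, 0)
  a <- inhibition_assay(p0, g_bar = 2, e_rev = -20, i_amp = 1.5 * thr)
  expect_true(a$inhibited_stop || a$inhibited_reduce)
})
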