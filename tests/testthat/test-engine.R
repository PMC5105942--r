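test_that("an unstimulated simulation stays at rest", {
  p <- neuron_params()
  tr <- simulate_neuron(p, list(), t_end = 500)
  v0 <- resting_state(p)[["V"]]
  expect_lt(max(abs(tr$V - v0)), 0.5)
  expect_equal(nrow(tr), 500 / 0.05 + 1)
  expect_true(all(diff(tr$t) > 0))
})

test_that("normal conditions depolarize without spiking", {
  b <- pt_b()
  tr <- simulate_neuron(b$params, conductance_step(2, b$e_gaba),
                        t_end = 1300)
  sp <- detect_spikes(tr)
  expect_length(sp$times, 0)
  dep <- measure_depolarization(tr, c(100, 1100))
  expect_gt(dep, 5)           # clearly depolarized...
  expect_lt(max(tr$V), -40)   # ...but well below spike threshold
})

test_that("strong conductance clamps the membrane near its reversal", {
  b <- pt_b()
  tr <- simulate_neuron(b$params, conductance_step(20, b$e_gaba),
                        t_end = 1300)
  late <- tr$V[tr$t > 600 & tr$t < 1100]
  expect_lt(max(abs(late - b$e_gaba)), 2)
})

test_that("spike detection applies threshold, refractory and prominence", {
  expect_length(detect_spikes(synth_trace(numeric(0)))$times, 0)
  sp <- detect_spikes(synth_trace(c(200, 250, 300)), refractory = 2)
  expect_length(sp$times, 3)
  expect_true(all(sp$peaks > 0))
  # two crossings 1 ms apart collapse under a 2 ms refractory
  sp2 <- detect_spikes(synth_trace(c(200, 201), width = 0.8),
                       refractory = 2)
  expect_length(sp2$times, 1)
  # a sustained plateau above threshold is not a spike (prominence)
  t <- seq(0, 500, 0.05)
  plateau <- data.frame(t = t, V = ifelse(t > 100, 5, -10))
  expect_length(detect_spikes(plateau)$times, 0)
})

test_that("response classification separates none/transient/repetitive", {
  mk <- function(times) structure(list(times = times,
                                       peaks = rep(20, length(times))),
                                  class = "spike_train")
  expect_identical(classify_response(mk(numeric(0)), c(100, 1100))$label,
                   "none")
  # a single onset spike in a 1000 ms step is transient
  expect_identical(classify_response(mk(105), c(100, 1100))$label,
                   "transient")
  # an onset burst is still transient (never repetitive)
  expect_identical(classify_response(mk(c(105, 115, 125, 135)),
                                     c(100, 1100))$label, "transient")
  # regular spiking through the window is repetitive
  expect_identical(classify_response(mk(seq(110, 1090, 50)),
                                     c(100, 1100))$label, "repetitive")
  expect_error(classify_response(mk(1), c(200, 100)), "window")
})

test_that("real traces classify as expected at reference points", {
  cc <- pt_c()
  expect_identical(label_of(cc$params, synaptic_fast(2, cc$e_gaba)),
                   "transient")
  ee <- pt_e()
  expect_identical(label_of(ee$params, conductance_step(2, ee$e_gaba)),
                   "repetitive")
  b <- pt_b()
  expect_identical(label_of(b$params, conductance_step(2, b$e_gaba)),
                   "none")
})

test_that("subthreshold depolarization grows with conductance toward the
          shunt-clamp limit", {
  b <- pt_b()
  deps <- vapply(c(0.5, 1, 1.5, 2, 8, 20), function(g) {
    tr <- simulate_neuron(b$params, conductance_step(g, b$e_gaba),
                          t_end = 1300)
    as.numeric(measure_depolarization(tr, c(100, 1100)))
  }, numeric(1))
  expect_true(all(diff(deps) > 0))
  v0 <- resting_state(b$params)[["V"]]
  expect_lt(deps[length(deps)], b$e_gaba - v0)          # from below
  expect_gt(deps[length(deps)], b$e_gaba - v0 - 2)
  # no stimulus: no depolarization
  tr0 <- simulate_neuron(b$params, list(), t_end = 500)
  expect_lt(abs(measure_depolarization(tr0, c(100, 400))), 0.1)
})

test_that("depolarization of a spiking window is flagged", {
  cc <- pt_c()
  tr <- simulate_neuron(cc$params, conductance_step(2, cc$e_gaba),
                        t_end = 1300)
  expect_warning(dep <- measure_depolarization(tr, c(100, 1100)),
                 "spikes")
  expect_true(attr(dep, "spiking"))
})

test_that("spike counts are robust to detection threshold for full spikes", {
  cc <- pt_c()
  tr <- simulate_neuron(cc$params, synaptic_fast(2, cc$e_gaba),
                        t_end = 400)
  n <- vapply(c(-10, -5, 0, 5, 10), function(th)
    length(detect_spikes(tr, threshold = th)$times), integer(1))
  expect_true(all(n == n[1]))
  expect_gt(n[1], 0)
})

test_that("solver refinement does not change classifications", {
  cases <- list(
    list(p = neuron_params(), s = conductance_step(2, -35)),
    list(p = neuron_params(beta_w = -10), s = synaptic_fast(2, -20)),
    list(p = neuron_params(beta_w = -10), s = synaptic_slow(2, -20)),
    list(p = neuron_params(beta_w = 0), s = conductance_step(2, -10)),
    list(p = neuron_params(beta_w = 0, p = 0.5),
         s = conductance_step(2, -20)))
  for (cs in cases) {
    base <- classify_trace(cs$p, cs$s)
    half <- classify_trace(cs$p, cs$s, dt = 0.025)
    tight <- classify_trace(cs$p, cs$s, rtol = 1e-7, atol = 1e-9)
    expect_identical(half$label, base$label)
    expect_identical(tight$label, base$label)
    # refinement invariance contract on the voltage itself
    tr1 <- simulate_neuron(cs$p, cs$s, t_end = 300)
    tr2 <- simulate_neuron(cs$p, cs$s, t_end = 300, dt = 0.025)
    expect_lt(max(abs(tr2$V[seq(1, nrow(tr2), 2)] - tr1$V)), 0.5)
  }
})
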