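# Shared fixtures: representative operating points of the model.
# "point b" = normal conditions (E_GABA = -35 mV, beta_w = -20 mV);
# "point c" regime = transient spiking (depolarized E_GABA, raised beta_w);
# "point e" regime = repetitive spiking.
pt_b <- function() list(params = neuron_params(), e_gaba = -35)
pt_c <- function() list(params = neuron_params(beta_w = -10), e_gaba = -20)
pt_e <- function() list(params = neuron_params(beta_w = 0), e_gaba = -10)

# Label of the response to one stimulus (quiet shortcut).
label_of <- function(params, input, ...)
  classify_trace(params, input, ...)$label

# A synthetic trace with triangular spikes at given times (for testing
# detection logic independently of the integrator).
synth_trace <- function(spike_times, t_end = 1000, dt = 0.05,
                        baseline = -70, peak = 20, width = 2) {
  t <- seq(0, t_end, by = dt)
  V <- rep(baseline, length(t))
  for (ts in spike_times) {
    sel <- abs(t - ts) <= width / 2
    V[sel] <- pmax(V[sel],
                   peak - (peak - baseline) * abs(t[sel] - ts) / (width / 2))
  }
  data.frame(t = t, V = V)
}

# Coarse cable used in unit tests (acceptance work uses the printed
# d_lambda = 0.01; the coarse version keeps unit tests fast).
coarse_cable <- function(d_lambda = 0.1)
  build_cable(cable_params(d_lambda = d_lambda))
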