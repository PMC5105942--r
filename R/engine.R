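#' Integrate the single-compartment model under arbitrary stimuli
#'
#' Simulates the membrane model from its resting state using an
#' adaptive-step, stiff-capable integrator (`lsoda`) with a compiled
#' right-hand side, returning dense output on a fixed grid (default
#' 0.05 ms) so that spike detection is decoupled from solver stepping.
#'
#' @param params a [neuron_params()] object.
#' @param stimuli a single stimulus or a list of `conductance_input` /
#'   `current_input` objects (at most 16).
#' @param t_end end of the simulation (ms).
#' @param dt output grid spacing (ms).
#' @param rtol,atol relative and absolute solver tolerances.
#' @param state0 optional initial state `c(V, w, h)`; defaults to
#'   [resting_state()].
#' @return a `pad_trace` data frame with columns `t`, `V`, `w`, `h`,
#'   `g_gaba` (total applied GABA conductance, nS/pF) and `i_stim`
#'   (applied current, pA/pF); the parameter set and stimuli are attached
#'   as attributes.
#' @examples
#' \donttest{
#' tr <- simulate_neuron(neuron_params(),
#'                       conductance_step(2, e_rev = -35), t_end = 1300)
#' max(tr$V)
#' }
#' @export
simulate_neuron <- function(params, stimuli = list(), t_end,
                            dt = 0.05, rtol = 1e-6, atol = 1e-8,
                            state0 = NULL) {
  validate_neuron_params(params)
  if (inherits(stimuli, "conductance_input") ||
      inherits(stimuli, "current_input"))
    stimuli <- list(stimuli)
  if (t_end <= 0) stop("t_end must be > 0")
  if (length(stimuli) > 16L) stop("at most 16 stimuli are supported")
  if (is.null(state0)) state0 <- resting_state(params)

  parms <- c(params$C, params$g_Na_bar, params$E_Na, params$beta_m,
             params$gamma_m, params$g_K_bar, params$E_K, params$phi_w,
             params$beta_w, params$gamma_w, params$g_leak, params$E_leak,
             params$p, params$beta_h, params$gamma_h, params$phi_h,
             nspf_to_density(params$g_Na_virtual, params$C),
             params$beta_mv, params$gamma_mv,
             length(stimuli))
  for (s in stimuli) parms <- c(parms, encode_stimulus(s, params$C))
  parms <- c(parms, numeric(20 + 16 * 8 - length(parms)))

  times <- seq(0, t_end, by = dt)
  out <- deSolve::ode(y = unname(state0), times = times,
                      func = "padsim_deriv_memb", parms = parms,
                      dllname = "padsim", initfunc = "padsim_init_memb",
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 100000)
  V <- out[, 2]
  if (anyNA(V) || any(!is.finite(V))) {
    bad <- which(!is.finite(V))[1]
    stop(sprintf("integration error: non-finite state at t = %.3f ms",
                 out[bad, 1]))
  }
  g_tot <- numeric(length(times))
  i_tot <- numeric(length(times))
  for (s in stimuli) {
    if (inherits(s, "conductance_input"))
      g_tot <- g_tot + conductance_at(times, s)
    else
      i_tot <- i_tot + current_at(times, s)
  }
  tr <- data.frame(t = out[, 1], V = V, w = out[, 3], h = out[, 4],
                   g_gaba = g_tot, i_stim = i_tot)
  attr(tr, "params") <- params
  attr(tr, "stimuli") <- stimuli
  attr(tr, "v_rest") <- unname(state0[1])
  class(tr) <- c("pad_trace", "data.frame")
  tr
}

#' Detect spikes in a voltage trace
#'
#' One spike is recorded per upward crossing of `threshold` separated by
#' at least `refractory` ms. Because strong GABA shunting attenuates spike
#' height (membrane clamped near E_GABA), a prominence criterion is
#' applied: the spike peak must exceed the pre-crossing baseline (voltage
#' `baseline_lag` ms before the crossing) by at least `prominence` mV,
#' which prevents a depolarized plateau from being counted as a spike.
#'
#' @param trace a `pad_trace`, or any data frame with columns `t` and `V`.
#' @param threshold detection threshold (mV), upward crossing.
#' @param refractory minimum spike separation (ms).
#' @param prominence minimum peak height above baseline (mV).
#' @param baseline_lag lag used for the baseline sample (ms).
#' @return an object of class `spike_train`: list with `times` (ms) and
#'   `peaks` (mV).
#' @export
detect_spikes <- function(trace, threshold = 0, refractory = 2,
                          prominence = 20, baseline_lag = 10) {
  t <- trace$t; V <- trace$V
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold) + 1L
  times <- numeric(0); peaks <- numeric(0)
  last <- -Inf
  n <- length(V)
  for (i in up) {
    ti <- t[i]
    if (ti - last < refractory) next
    # peak: max V until V falls back below threshold (or trace end)
    j <- i
    while (j < n && V[j] >= threshold) j <- j + 1L
    pk <- max(V[i:j])
    ib <- findInterval(ti - baseline_lag, t)
    base <- V[max(ib, 1L)]
    if (pk - base < prominence) next
    times <- c(times, ti)
    peaks <- c(peaks, pk)
    last <- ti
  }
  structure(list(times = times, peaks = peaks, threshold = threshold,
                 refractory = refractory, prominence = prominence),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("<spike_train>", length(x$times), "spike(s)\n")
  if (length(x$times))
    print(data.frame(time = x$times, peak = x$peaks))
  invisible(x)
}

#' Classify a spiking response as none, transient or repetitive
#'
#' Applying a sustained depolarizing conductance can elicit no spikes,
#' spikes confined to the stimulus onset (*transient*), or spiking
#' sustained through the stimulus (*repetitive*). The rule used here:
#' **none** if no spike falls in the stimulus window; **repetitive** if at
#' least `min_spikes` spikes fall in the window *and* the last of them
#' lies in the final `tail_frac` fraction of the window; **transient**
#' otherwise. A burst confined to onset is therefore never classified
#' repetitive. The rule parameters are recorded in the result.
#'
#' @param spikes a [detect_spikes()] result.
#' @param window numeric `c(start, end)` (ms), e.g. [stim_window()].
#' @param min_spikes minimum spike count for the repetitive label.
#' @param tail_frac final fraction of the window the last spike must reach.
#' @return an object of class `response_class` with fields `label`,
#'   `n_spikes` (in window), `spikes_in_onset_window`.
#' @export
classify_response <- function(spikes, window, min_spikes = 3,
                              tail_frac = 0.25) {
  if (!is.numeric(window) || length(window) != 2 || window[2] <= window[1])
    stop("window must be c(start, end) with end > start")
  tin <- spikes$times[spikes$times >= window[1] & spikes$times <= window[2]]
  n <- length(tin)
  onset_end <- window[1] + (window[2] - window[1]) * tail_frac
  tail_start <- window[2] - (window[2] - window[1]) * tail_frac
  label <- if (n == 0) "none"
  else if (n >= min_spikes && max(tin) >= tail_start) "repetitive"
  else "transient"
  structure(list(label = label, n_spikes = n,
                 spikes_in_onset_window = sum(tin <= onset_end),
                 window = window, min_spikes = min_spikes,
                 tail_frac = tail_frac),
            class = "response_class")
}

#' @export
print.response_class <- function(x, ...) {
  cat("<response_class>", x$label, "-", x$n_spikes, "spike(s) in window\n")
  invisible(x)
}

#' Simulate and classify the response to a single stimulus
#'
#' Convenience wrapper: simulates `params` under `input` (plus optional
#' extra stimuli), detects spikes and classifies the response over the
#' stimulus window of `input`.
#'
#' @param params a [neuron_params()] object.
#' @param input the stimulus whose window defines the classification.
#' @param extra optional list of additional stimuli.
#' @param t_end simulation end; defaults to 100 ms past the window.
#' @param ... passed to [simulate_neuron()] and [detect_spikes()].
#' @return a `response_class` with the `spike_train` and `pad_trace`
#'   attached as attributes `spikes` and `trace`.
#' @export
classify_trace <- function(params, input, extra = list(), t_end = NULL,
                           ...) {
  dots <- list(...)
  sim_args <- dots[names(dots) %in% c("dt", "rtol", "atol", "state0")]
  det_args <- dots[names(dots) %in%
                     c("threshold", "refractory", "prominence",
                       "baseline_lag")]
  win <- stim_window(input)
  if (is.null(t_end)) t_end <- win[2] + 100
  tr <- do.call(simulate_neuron,
                c(list(params = params, stimuli = c(list(input), extra),
                       t_end = t_end), sim_args))
  sp <- do.call(detect_spikes, c(list(trace = tr), det_args))
  cl <- classify_response(sp, win)
  attr(cl, "spikes") <- sp
  attr(cl, "trace") <- tr
  cl
}

#' Peak subthreshold depolarization in a window
#'
#' Maximum voltage in `window` minus the resting potential. Intended for
#' subthreshold traces; if the window contains detected spikes the value
#' is returned with attribute `spiking = TRUE` and a warning, since the
#' depolarization of a spiking trace is ill-defined.
#'
#' @param trace a `pad_trace`.
#' @param window numeric `c(start, end)` in ms.
#' @param ... passed to [detect_spikes()].
#' @return depolarization (mV) with attribute `spiking`.
#' @export
measure_depolarization <- function(trace, window, ...) {
  if (window[1] < min(trace$t) || window[2] > max(trace$t))
    stop("window must lie inside the trace")
  v_rest <- attr(trace, "v_rest")
  if (is.null(v_rest)) v_rest <- trace$V[1]
  sel <- trace$t >= window[1] & trace$t <= window[2]
  dep <- max(trace$V[sel]) - v_rest
  sp <- detect_spikes(trace, ...)
  spiking <- any(sp$times >= window[1] & sp$times <= window[2])
  if (spiking)
    warning("window contains spikes; depolarization is ill-defined")
  attr(dep, "spiking") <- spiking
  dep
}
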