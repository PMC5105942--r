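#' Minimum GABA conductance density eliciting spiking
#'
#' In-silico analog of the dynamic-clamp titration: bisects the amplitude
#' of a conductance input between `lower` and `upper` (nS/pF) for the
#' smallest value whose response matches `target` (default: any spiking),
#' to a stated resolution. Bisection assumes spiking is monotone in the
#' amplitude over the bracket. Because strong conductance can suppress
#' spiking again through shunting, a failed upper bound triggers an
#' automatic fallback: a coarse linear scan locates a spiking amplitude,
#' the result is flagged `non_monotone`, and the spiking onset below it
#' is bisected as usual. `scan = TRUE` forces a fine linear scan from
#' `lower` upward instead of bisection.
#'
#' @param params a [neuron_params()] object.
#' @param input a `conductance_input` template; its `g_bar` is varied.
#' @param lower,upper titration bounds (nS/pF).
#' @param resolution titration resolution (nS/pF).
#' @param target `"any"`, `"transient"` or `"repetitive"`.
#' @param scan use a linear scan instead of bisection.
#' @param ... passed to [classify_trace()].
#' @return a `titration_result`: list with `min_g_bar` (nS/pF, `NA` if
#'   none found within bounds), `resolution`, `target`, `tested` (data
#'   frame of amplitude/label pairs), `non_monotone` flag, `input`,
#'   `params`.
#' @export
find_min_ggaba <- function(params, input, lower = 0, upper = 10,
                           resolution = 0.01,
                           target = c("any", "transient", "repetitive"),
                           scan = FALSE, ...) {
  target <- match.arg(target)
  if (!(upper > lower)) stop("bounds must satisfy upper > lower")
  if (resolution <= 0) stop("resolution must be > 0")
  tested_g <- numeric(0); tested_lab <- character(0)
  hit <- function(g) {
    input$g_bar <- g
    lab <- classify_trace(params, input, ...)$label
    tested_g <<- c(tested_g, g); tested_lab <<- c(tested_lab, lab)
    switch(target, any = lab != "none", transient = lab == "transient",
           repetitive = lab == "repetitive")
  }
  non_monotone <- FALSE
  if (scan) {
    gs <- seq(lower, upper, by = resolution)
    if (gs[length(gs)] < upper) gs <- c(gs, upper)
    min_g <- NA_real_
    for (g in gs) if (hit(g)) { min_g <- g; break }
    # shunting can suppress spiking again at high amplitude; report it
    if (!is.na(min_g) && min_g < upper) non_monotone <- !hit(upper)
  } else {
    hi <- NA_real_
    if (hit(upper)) {
      hi <- upper
    } else {
      # upper bound silent: spiking may still exist at intermediate
      # amplitudes (shunting non-monotonicity) - coarse scan for it
      step <- max(resolution, (upper - lower) / 40)
      for (g in rev(seq(lower + step, upper - step / 2, by = step))) {
        if (hit(g)) { hi <- g; non_monotone <- TRUE; break }
      }
    }
    if (is.na(hi)) {
      min_g <- NA_real_
    } else if (hit(lower)) {
      min_g <- lower
    } else {
      lo <- lower
      while (hi - lo > resolution) {
        mid <- (lo + hi) / 2
        if (hit(mid)) hi <- mid else lo <- mid
      }
      min_g <- hi
    }
  }
  structure(list(min_g_bar = min_g, resolution = resolution,
                 target = target,
                 tested = data.frame(g_bar = tested_g, label = tested_lab),
                 non_monotone = non_monotone,
                 input = input, params = params),
            class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat("<titration_result> target:", x$target, " min g_bar:",
      if (is.na(x$min_g_bar)) "none found" else
        paste(x$min_g_bar, "nS/pF"),
      " (resolution", x$resolution, "nS/pF)\n")
  invisible(x)
}

#' Compare stimulus kinetics: fast vs slow waveform, step vs ramp
#'
#' Titrates the minimum conductance density separately for the fast
#' synaptic waveform, the slow synaptic waveform, a step and a slow ramp,
#' all sharing one reversal potential, and reports whether spike
#' initiation is rate-sensitive (slow-onset input needing more
#' conductance than fast-onset, the transient-regime signature) or
#' amplitude-only (equal minima, the repetitive-regime signature).
#'
#' @param params a [neuron_params()] object.
#' @param e_rev shared reversal potential (mV).
#' @param lower,upper,resolution titration settings (nS/pF).
#' @param ramp_factor amplitude multiple of the step minimum at which the
#'   ramp is additionally tested (reported as `ramp_spikes_at_factor`).
#' @param ... passed to [find_min_ggaba()] / [classify_trace()].
#' @return a `kinetics_comparison`: list of per-waveform titration
#'   results, `rate_sensitive` flag, and the ramp check.
#' @export
compare_kinetics <- function(params, e_rev = -20, lower = 0, upper = 10,
                             resolution = 0.01, ramp_factor = 2.5, ...) {
  tpl <- list(fast = synaptic_fast(1, e_rev),
              slow = synaptic_slow(1, e_rev),
              step = conductance_step(1, e_rev),
              ramp = conductance_ramp(1, e_rev))
  tit <- lapply(tpl, function(w)
    find_min_ggaba(params, w, lower, upper, resolution, ...))
  mins <- vapply(tit, `[[`, numeric(1), "min_g_bar")
  # transient-regime cells need markedly more conductance for slow-onset
  # input; repetitive-regime cells have near-equal minima. A 10% relative
  # margin separates the two regimes robustly.
  rate_sensitive <- if (anyNA(mins[c("fast", "slow")])) NA
  else mins[["slow"]] > 1.1 * mins[["fast"]] + resolution
  ramp_spikes <- NA
  if (!is.na(mins[["step"]])) {
    ri <- tpl$ramp
    ri$g_bar <- ramp_factor * mins[["step"]]
    ramp_spikes <- classify_trace(params, ri, ...)$n_spikes
  }
  structure(list(titrations = tit, min_g_bar = mins,
                 rate_sensitive = rate_sensitive,
                 ramp_factor = ramp_factor,
                 ramp_spikes_at_factor = ramp_spikes,
                 e_rev = e_rev, resolution = resolution),
            class = "kinetics_comparison")
}

#' @export
print.kinetics_comparison <- function(x, ...) {
  cat("<kinetics_comparison> E_rev:", x$e_rev, "mV\n")
  print(x$min_g_bar)
  cat("rate sensitive (slow > fast):", x$rate_sensitive, "\n")
  invisible(x)
}

#' Add a virtual sodium conductance
#'
#' Returns the parameter set with an additional non-inactivating sodium
#' conductance, the in-silico analog of the virtual conductance inserted
#' via dynamic clamp to raise excitability. The activation curve defaults
#' to the model's own instantaneous sodium activation; midpoint and slope
#' can be overridden.
#'
#' @param params a [neuron_params()] object.
#' @param g_na_virtual conductance density (nS/pF), `>= 0`.
#' @param beta,gamma optional activation midpoint/slope (mV).
#' @return modified `neuron_params`.
#' @export
add_virtual_sodium <- function(params, g_na_virtual,
                               beta = params$beta_m,
                               gamma = params$gamma_m) {
  if (g_na_virtual < 0) stop("g_na_virtual must be >= 0")
  params$g_Na_virtual <- params$g_Na_virtual + g_na_virtual
  params$beta_mv <- beta
  params$gamma_mv <- gamma
  validate_neuron_params(params)
  params
}

#' 4-AP analog: shift of the recovery-variable midpoint
#'
#' Blocking low-threshold potassium channels (experimentally with 4-AP)
#' corresponds in the model to setting `beta_w` to less negative values.
#' No single shift value maps to a 4-AP dose; the default +10 mV
#' (-20 -> -10 mV) is a representative hyperexcitability increment and
#' results should be read across a range of shifts.
#'
#' @param params a [neuron_params()] object.
#' @param delta_beta_w shift in mV (positive = more excitable).
#' @return modified `neuron_params`.
#' @export
apply_4ap_analog <- function(params, delta_beta_w = 10) {
  params$beta_w <- params$beta_w + delta_beta_w
  params
}

#' Rheobase under GABA shunting
#'
#' Minimum current-step amplitude evoking at least one spike while a GABA
#' conductance step is active, found by bisection. Default timing: the
#' conductance step runs 100-500 ms and the current step 300-700 ms, so
#' spikes are counted in their 200 ms overlap (300-500 ms); any transient
#' spike at the conductance onset falls outside the counted window. With
#' `g_bar = 0` the same window yields the baseline rheobase.
#'
#' @param params a [neuron_params()] object.
#' @param g_bar GABA conductance density (nS/pF).
#' @param e_rev GABA reversal potential (mV).
#' @param lower,upper current bracket (pA/pF).
#' @param resolution bisection resolution (pA/pF).
#' @param g_input,i_input optional explicit stimulus templates; the
#'   current amplitude of `i_input` is varied.
#' @param ... passed to [simulate_neuron()] / [detect_spikes()].
#' @return rheobase in pA/pF (`NA` with attribute `none_found` if `upper`
#'   is subthreshold), with the overlap window attached as attribute.
#' @export
rheobase <- function(params, g_bar = 0, e_rev = -35, lower = 0,
                     upper = 100, resolution = 0.1,
                     g_input = NULL, i_input = NULL, ...) {
  if (is.null(g_input))
    g_input <- conductance_step(g_bar, e_rev, t_on = 100, duration = 400)
  else
    g_input$g_bar <- g_bar
  if (is.null(i_input))
    i_input <- current_step(0, t_on = 300, duration = 400)
  g_win <- stim_window(g_input)
  i_win <- stim_window(i_input)
  win <- c(max(g_win[1], i_win[1]), min(g_win[2], i_win[2]))
  if (win[2] <= win[1])
    stop("protocol error: current and conductance windows do not overlap")
  t_end <- max(g_win[2], i_win[2]) + 100
  dots <- list(...)
  sim_args <- dots[names(dots) %in% c("dt", "rtol", "atol")]
  det_args <- dots[names(dots) %in%
                     c("threshold", "refractory", "prominence",
                       "baseline_lag")]
  spikes_at <- function(a) {
    i_input$amplitude <- a
    stims <- if (g_input$g_bar > 0) list(g_input, i_input)
             else list(i_input)
    tr <- do.call(simulate_neuron,
                  c(list(params = params, stimuli = stims, t_end = t_end),
                    sim_args))
    sp <- do.call(detect_spikes, c(list(trace = tr), det_args))
    sum(sp$times >= win[1] & sp$times <= win[2]) >= 1
  }
  if (!spikes_at(upper)) {
    out <- NA_real_
    attr(out, "none_found") <- TRUE
    return(out)
  }
  lo <- lower; hi <- upper
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  out <- hi
  attr(out, "window") <- win
  out
}

#' Combined conductance/current inhibition assay
#'
#' Reproduces the paired-step protocols: a current step drives repetitive
#' spiking and a GABA conductance step is applied either within the
#' current step (`"g_within_i"`: current 100-1100 ms, conductance
#' 400-800 ms) or beginning before it (`"g_before_i"`: conductance
#' 100-500 ms, current from 400 ms for 1000 ms, 100 ms overlap). Spike
#' counts are reported per epoch of the current window (before / during /
#' after the conductance step), spike heights are compared inside vs
#' outside the conductance window, and the stopped / reduced inhibition
#' criteria are evaluated on the overlap against a current-alone
#' baseline.
#'
#' @param params a [neuron_params()] object.
#' @param g_bar,e_rev conductance step amplitude (nS/pF) and reversal (mV).
#' @param i_amp current step amplitude (pA/pF).
#' @param ordering `"g_within_i"` or `"g_before_i"`.
#' @param rate_drop factor for the *reduced* criterion.
#' @param ... passed to the simulator/detector.
#' @return an `inhibition_assay` list: epoch spike counts, mean spike
#'   heights in/out of the conductance window, `inhibited_stop`,
#'   `inhibited_reduce`, `baseline_repetitive`, and the underlying spike
#'   trains.
#' @export
inhibition_assay <- function(params, g_bar, e_rev, i_amp,
                             ordering = c("g_within_i", "g_before_i"),
                             rate_drop = 0.5, ...) {
  ordering <- match.arg(ordering)
  if (ordering == "g_within_i") {
    i_input <- current_step(i_amp, t_on = 100, duration = 1000)
    g_input <- conductance_step(g_bar, e_rev, t_on = 400, duration = 400)
  } else {
    g_input <- conductance_step(g_bar, e_rev, t_on = 100, duration = 400)
    i_input <- current_step(i_amp, t_on = 400, duration = 1000)
  }
  g_win <- stim_window(g_input)
  i_win <- stim_window(i_input)
  overlap <- c(max(g_win[1], i_win[1]), min(g_win[2], i_win[2]))
  t_end <- max(g_win[2], i_win[2]) + 100
  base_cl <- classify_trace(params, i_input, t_end = t_end, ...)
  both_cl <- classify_trace(params, i_input, extra = list(g_input),
                            t_end = t_end, ...)
  sp <- attr(both_cl, "spikes")
  sb <- attr(base_cl, "spikes")
  in_i <- sp$times >= i_win[1] & sp$times <= i_win[2]
  in_g <- sp$times >= g_win[1] & sp$times <= g_win[2]
  n_before <- sum(in_i & sp$times < g_win[1])
  n_during <- sum(in_i & in_g)
  n_after <- sum(in_i & sp$times > g_win[2])
  height_in <- if (any(in_i & in_g)) mean(sp$peaks[in_i & in_g]) else NA
  height_out <- if (any(in_i & !in_g)) mean(sp$peaks[in_i & !in_g]) else NA
  n_ov <- sum(sp$times >= overlap[1] & sp$times <= overlap[2])
  n_base <- sum(sb$times >= overlap[1] & sb$times <= overlap[2])
  half <- c(mean(overlap), overlap[2])
  structure(list(
    ordering = ordering, g_window = g_win, i_window = i_win,
    overlap = overlap,
    spikes_before = n_before, spikes_during = n_during,
    spikes_after = n_after,
    spike_height_in = height_in, spike_height_out = height_out,
    baseline_repetitive = base_cl$label == "repetitive",
    n_overlap = n_ov, n_baseline = n_base,
    inhibited_stop = sum(sp$times >= half[1] & sp$times <= half[2]) == 0,
    inhibited_reduce = if (n_base > 0) n_ov <= rate_drop * n_base else NA,
    spikes = sp, baseline_spikes = sb),
    class = "inhibition_assay")
}

#' @export
print.inhibition_assay <- function(x, ...) {
  cat("<inhibition_assay>", x$ordering,
      sprintf("- spikes before/during/after g window: %d/%d/%d\n",
              x$spikes_before, x$spikes_during, x$spikes_after))
  cat("inhibited (stopped):", x$inhibited_stop,
      " (reduced):", x$inhibited_reduce, "\n")
  invisible(x)
}
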