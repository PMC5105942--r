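#' Stimulus waveform constructors
#'
#' Conductance inputs describe the GABA-A conductance time course applied
#' to the model; amplitudes are given as capacitance-normalized densities
#' (nS/pF, see [nspf_to_density()]). Three kinds are supported:
#'
#' * **step** - `g_bar` from `t_on` for `duration` ms;
#' * **ramp** - linear rise from 0 to `g_bar` over `rise_time` ms starting
#'   at `t_on`, then held at `g_bar` for `duration` ms;
#' * **synaptic** - double-exponential waveform
#'   `g_bar * x * (exp(-t/tau_decay) - exp(-t/tau_rise))`, peak-normalized
#'   to `g_bar` by the factor `x` (see [normalization_factor()]). The fast
#'   preset (`tau_rise = 2`, `tau_decay = 20` ms) mimics synaptic
#'   (intrasynaptic receptor) activation; the slow preset (`tau_rise = 20`,
#'   `tau_decay = 200` ms) mimics asynchronous activation of extrasynaptic
#'   receptors by spilled-over GABA.
#'
#' The default hold of 1000 ms makes "repetitive" spiking (sustained to
#' stimulus end) unambiguous; the default ramp rise of 500 ms provides a
#' slow-onset challenge to rate-sensitive spike initiation.
#'
#' @param g_bar peak conductance density (nS/pF), `>= 0`.
#' @param e_rev reversal potential E_GABA (mV).
#' @param t_on onset time (ms).
#' @param duration hold duration (ms) for step/ramp kinds.
#' @param rise_time ramp rise time (ms).
#' @param tau_rise,tau_decay synaptic kinetics (ms), `tau_decay > tau_rise > 0`.
#' @return an object of class `conductance_input`.
#' @export
conductance_step <- function(g_bar, e_rev = -35, t_on = 100,
                             duration = 1000) {
  new_conductance_input("step", g_bar, e_rev, t_on, duration = duration)
}

#' @rdname conductance_step
#' @export
conductance_ramp <- function(g_bar, e_rev = -35, t_on = 100,
                             duration = 1000, rise_time = 500) {
  if (rise_time <= 0) stop("rise_time must be > 0")
  new_conductance_input("ramp", g_bar, e_rev, t_on, duration = duration,
                        rise_time = rise_time)
}

#' @rdname conductance_step
#' @export
conductance_synaptic <- function(g_bar, e_rev = -35, t_on = 100,
                                 tau_rise = 2, tau_decay = 20) {
  nf <- normalization_factor(tau_rise, tau_decay)
  new_conductance_input("synaptic", g_bar, e_rev, t_on,
                        tau_rise = tau_rise, tau_decay = tau_decay,
                        x = nf$x, t_peak = nf$t_peak)
}

#' @rdname conductance_step
#' @export
synaptic_fast <- function(g_bar, e_rev = -35, t_on = 100)
  conductance_synaptic(g_bar, e_rev, t_on, tau_rise = 2, tau_decay = 20)

#' @rdname conductance_step
#' @export
synaptic_slow <- function(g_bar, e_rev = -35, t_on = 100)
  conductance_synaptic(g_bar, e_rev, t_on, tau_rise = 20, tau_decay = 200)

new_conductance_input <- function(kind, g_bar, e_rev, t_on, ...) {
  if (!is.numeric(g_bar) || g_bar < 0) stop("g_bar must be >= 0")
  structure(c(list(kind = kind, g_bar = g_bar, e_rev = e_rev, t_on = t_on),
              list(...)),
            class = "conductance_input")
}

#' Current step stimulus
#'
#' A rectangular stimulating-current step. The amplitude is a
#' capacitance-normalized current density (pA/pF), converted internally to
#' uA/cm2 by the same factor as conductances, so single-compartment
#' results are independent of cell size.
#'
#' @param amplitude current density (pA/pF).
#' @param t_on onset (ms).
#' @param duration step length (ms), `> 0`.
#' @return an object of class `current_input`.
#' @export
current_step <- function(amplitude, t_on = 100, duration = 1000) {
  if (duration <= 0) stop("duration must be > 0")
  structure(list(kind = "current_step", amplitude = amplitude,
                 t_on = t_on, duration = duration),
            class = "current_input")
}

#' Peak normalization of the double-exponential synaptic waveform
#'
#' The raw waveform `exp(-t/tau_decay) - exp(-t/tau_rise)` peaks at
#' `t* = ln(tau_decay/tau_rise) * tau_rise * tau_decay /
#' (tau_decay - tau_rise)` with a maximum below 1; the factor
#' `x = 1 / (exp(-t*/tau_decay) - exp(-t*/tau_rise))` rescales the peak to
#' exactly 1 before multiplication by `g_bar`.
#'
#' @param tau_rise,tau_decay kinetics (ms) with `tau_decay > tau_rise > 0`.
#' @return list with `x` (dimensionless) and `t_peak` (ms).
#' @examples
#' normalization_factor(2, 20)   # t_peak ~ 5.12 ms, x ~ 1.44
#' @export
normalization_factor <- function(tau_rise, tau_decay) {
  if (!(tau_decay > tau_rise) || tau_rise <= 0)
    stop("invalid kinetics: require tau_decay > tau_rise > 0")
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  x <- 1 / (exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise))
  list(x = x, t_peak = t_peak)
}

#' Evaluate a stimulus at given times
#'
#' Total functions returning the conductance (nS/pF) or current (pA/pF)
#' carried by an input at times `t`; zero outside the active window.
#'
#' @param t times (ms); vectorized.
#' @param input a `conductance_input` or `current_input`.
#' @return numeric vector of the same length as `t`.
#' @export
conductance_at <- function(t, input) {
  stopifnot(inherits(input, "conductance_input"))
  s <- t - input$t_on
  g <- numeric(length(t))
  if (input$kind == "step") {
    on <- s >= 0 & s < input$duration
    g[on] <- input$g_bar
  } else if (input$kind == "ramp") {
    rise <- s >= 0 & s < input$rise_time
    hold <- s >= input$rise_time & s < input$rise_time + input$duration
    g[rise] <- input$g_bar * s[rise] / input$rise_time
    g[hold] <- input$g_bar
  } else {
    on <- s >= 0
    g[on] <- input$g_bar * input$x *
      (exp(-s[on] / input$tau_decay) - exp(-s[on] / input$tau_rise))
  }
  g
}

#' @rdname conductance_at
#' @export
current_at <- function(t, input) {
  stopifnot(inherits(input, "current_input"))
  s <- t - input$t_on
  ifelse(s >= 0 & s < input$duration, input$amplitude, 0)
}

#' Classification window of a stimulus
#'
#' The time window over which spiking responses to an input are
#' classified: for steps, the step itself; for ramps, rise plus hold; for
#' synaptic waveforms, from onset until the waveform has decayed below
#' `decay_frac` (default 5\%) of its peak.
#'
#' @param input a `conductance_input` or `current_input`.
#' @param decay_frac fraction of the peak at which a synaptic waveform is
#'   considered over.
#' @return numeric `c(start, end)` in ms.
#' @export
stim_window <- function(input, decay_frac = 0.05) {
  if (inherits(input, "current_input"))
    return(c(input$t_on, input$t_on + input$duration))
  stopifnot(inherits(input, "conductance_input"))
  if (input$kind == "step")
    return(c(input$t_on, input$t_on + input$duration))
  if (input$kind == "ramp")
    return(c(input$t_on, input$t_on + input$rise_time + input$duration))
  # synaptic: solve x*(exp(-s/td) - exp(-s/tr)) = decay_frac past the peak
  f <- function(s) input$x * (exp(-s / input$tau_decay) -
                                exp(-s / input$tau_rise)) - decay_frac
  upper <- input$tau_decay * (log(input$x) - log(decay_frac)) +
    input$t_peak + input$tau_decay
  s_end <- stats::uniroot(f, c(input$t_peak, upper), tol = 1e-6)$root
  c(input$t_on, input$t_on + s_end)
}

#' @export
print.conductance_input <- function(x, ...) {
  cat("<conductance_input>", x$kind, " g_bar:", x$g_bar, "nS/pF  E_rev:",
      x$e_rev, "mV  t_on:", x$t_on, "ms\n")
  invisible(x)
}

#' @export
print.current_input <- function(x, ...) {
  cat("<current_input> amplitude:", x$amplitude, "pA/pF  t_on:", x$t_on,
      "ms  duration:", x$duration, "ms\n")
  invisible(x)
}

# Encode one stimulus as an 8-double record for the compiled rhs.
# Conductance densities converted to mS/cm2, currents to uA/cm2.
encode_stimulus <- function(input, C) {
  if (inherits(input, "current_input"))
    return(c(4, papf_to_density(input$amplitude, C), 0,
             input$t_on, input$duration, 0, 0, 0))
  stopifnot(inherits(input, "conductance_input"))
  gden <- nspf_to_density(input$g_bar, C)
  switch(input$kind,
    step = c(1, gden, input$e_rev, input$t_on, input$duration, 0, 0, 0),
    ramp = c(2, gden, input$e_rev, input$t_on, input$duration,
             input$rise_time, 0, 0),
    synaptic = c(3, gden, input$e_rev, input$t_on, input$tau_rise,
                 input$tau_decay, input$x, 0))
}
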