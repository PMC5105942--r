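#' Geometry and membrane parameters of the three-compartment axon
#'
#' Defines an unmyelinated-axon model of three serially connected
#' compartments (default 1 mm each, 1 um diameter, axial resistivity
#' 150 Ohm cm) whose membrane follows the single-compartment model with
#' `g_Na_bar = g_K_bar = 30` mS/cm2. Spatial discretization follows the
#' d_lambda rule: each compartment is subdivided into an odd number of
#' equipotential segments no longer than `d_lambda` times the membrane
#' space constant at 100 Hz.
#'
#' @param membrane a [neuron_params()] object; default the `"cable"`
#'   preset.
#' @param n_compartments number of compartments (default 3).
#' @param compartment_length compartment length (um).
#' @param diameter axon diameter (um).
#' @param r_a axial resistivity (Ohm cm).
#' @param d_lambda discretization control (fraction of the 100 Hz space
#'   constant).
#' @return an object of class `cable_params`.
#' @export
cable_params <- function(membrane = neuron_params("cable"),
                         n_compartments = 3, compartment_length = 1000,
                         diameter = 1, r_a = 150, d_lambda = 0.01) {
  validate_neuron_params(membrane)
  if (n_compartments < 1 || compartment_length <= 0 || diameter <= 0 ||
      r_a <= 0 || d_lambda <= 0)
    stop("invalid parameter: cable geometry must be positive")
  structure(list(membrane = membrane, n_compartments = n_compartments,
                 compartment_length = compartment_length,
                 diameter = diameter, r_a = r_a, d_lambda = d_lambda),
            class = "cable_params")
}

#' Discretize the axon cable
#'
#' Computes the 100 Hz space constant
#' `lambda = sqrt(d / (4 pi f R_a C_m))` from the passive properties,
#' sizes an odd number of segments per compartment so that no segment
#' exceeds `d_lambda * lambda`, and computes the ohmic axial coupling
#' between adjacent segment centres (expressed as a conductance density
#' over the segment membrane, so that coupling currents share the
#' membrane-equation units). Ends are sealed.
#'
#' @param params a [cable_params()] object.
#' @return a `cable` object: segment counts, positions (mm), midpoint
#'   segment indices, axial coupling (mS/cm2), segment area (cm2) and the
#'   space constant (um).
#' @export
build_cable <- function(params = cable_params()) {
  stopifnot(inherits(params, "cable_params"))
  m <- params$membrane
  f <- 100
  lambda_um <- 1e5 * sqrt(params$diameter /
                            (4 * pi * f * params$r_a * m$C))
  nspc <- as.integer((params$compartment_length /
                        (params$d_lambda * lambda_um) + 0.9) / 2) * 2L + 1L
  nspc <- max(nspc, 3L)
  n_seg <- as.integer(params$n_compartments) * nspc
  seg_len_cm <- params$compartment_length / nspc * 1e-4
  a_cm <- params$diameter / 2 * 1e-4
  r_axial <- params$r_a * seg_len_cm / (pi * a_cm^2)   # Ohm
  area_cm2 <- pi * params$diameter * 1e-4 * seg_len_cm
  # (mV / Ohm) / cm2 = mA/cm2; factor 1e3 converts to uA/cm2, i.e. the
  # coupling coefficient has conductance-density units (mS/cm2)
  k_axial <- 1e3 / (r_axial * area_cm2)
  mid <- (nspc + 1L) / 2L
  midpoints <- mid + nspc * (seq_len(params$n_compartments) - 1L)
  structure(list(params = params, n_seg_per_comp = nspc, n_seg = n_seg,
                 seg_length_um = params$compartment_length / nspc,
                 seg_area_cm2 = area_cm2, k_axial = k_axial,
                 lambda_100_um = lambda_um,
                 positions_mm = (seq_len(n_seg) - 0.5) *
                   params$compartment_length / nspc / 1000,
                 midpoints = midpoints),
            class = "cable")
}

#' @export
print.cable <- function(x, ...) {
  cat("<cable>", x$params$n_compartments, "compartments x",
      x$n_seg_per_comp, "segments;",
      sprintf("lambda(100 Hz) = %.1f um, segment = %.2f um\n",
              x$lambda_100_um, x$seg_length_um))
  invisible(x)
}

#' Simulate the axon cable
#'
#' Method-of-lines integration of the coupled segment equations: every
#' segment obeys the membrane model (including the inactivating fraction
#' `p` of its parameter set) plus axial currents from its neighbours. A
#' GABA conductance step is applied uniformly over the middle compartment
#' and one or more current pulses are injected into the leftmost segment.
#' The interleaved state ordering keeps the system banded (half-bandwidth
#' 3), which the stiff solver exploits.
#'
#' @param cable a [build_cable()] result.
#' @param g_bar GABA conductance density (nS/pF) over the middle
#'   compartment.
#' @param e_gaba GABA reversal potential (mV).
#' @param g_t_on,g_duration conductance step timing (ms).
#' @param pulse_nA amplitude of the injected current pulse(s) (nA,
#'   absolute current into the leftmost segment).
#' @param pulse_ms pulse width (ms).
#' @param pulse_t0 first pulse onset (ms).
#' @param n_pulses,pulse_interval train description (interval in ms).
#' @param t_end simulation end (ms).
#' @param dt output grid (ms); 0.25 ms keeps the space-time matrix small
#'   while resolving spikes for detection.
#' @param p optional override of the inactivating fraction.
#' @param rtol,atol solver tolerances.
#' @param keep_full keep the full space-time voltage matrix (can be
#'   large); midpoint traces are always kept.
#' @return a `cable_trace`: data frame columns `t`, `V_left`, `V_mid`,
#'   `V_right` (compartment midpoints); full matrix in attribute
#'   `V_all` when requested.
#' @export
simulate_cable <- function(cable, g_bar = 0, e_gaba = -35,
                           g_t_on = 50, g_duration = 1000,
                           pulse_nA = 0, pulse_ms = 1, pulse_t0 = 450,
                           n_pulses = 1, pulse_interval = 50,
                           t_end = 700, dt = 0.25, p = NULL,
                           rtol = 1e-6, atol = 1e-6, keep_full = FALSE) {
  stopifnot(inherits(cable, "cable"))
  m <- cable$params$membrane
  if (!is.null(p)) m$p <- p
  validate_neuron_params(m)
  rest <- resting_state(m)
  n <- cable$n_seg
  nspc <- cable$n_seg_per_comp
  mid_comp <- ceiling(cable$params$n_compartments / 2)
  glo <- (mid_comp - 1L) * nspc + 1L
  ghi <- mid_comp * nspc
  amp_density <- pulse_nA * 1e-3 / cable$seg_area_cm2   # nA -> uA/cm2
  parms <- c(n, cable$params$n_compartments, nspc, cable$k_axial,
             m$C, m$g_Na_bar, m$E_Na, m$beta_m, m$gamma_m,
             m$g_K_bar, m$E_K, m$phi_w, m$beta_w, m$gamma_w,
             m$g_leak, m$E_leak, m$p, m$beta_h, m$gamma_h, m$phi_h,
             nspf_to_density(g_bar, m$C), e_gaba, g_t_on, g_duration,
             glo, ghi, 1, amp_density, pulse_ms, pulse_t0,
             pulse_interval, n_pulses)
  y0 <- rep(unname(rest), times = n)
  out <- deSolve::ode(y = y0, times = seq(0, t_end, by = dt),
                      func = "padsim_deriv_cable", parms = parms,
                      dllname = "padsim", initfunc = "padsim_init_cable",
                      method = "lsoda", jactype = "bandint",
                      bandup = 3, banddown = 3,
                      rtol = rtol, atol = atol, maxsteps = 500000)
  vcols <- 1 + 3 * (seq_len(n) - 1) + 1
  Vmid <- out[, vcols[cable$midpoints], drop = FALSE]
  if (any(!is.finite(Vmid)))
    stop("integration error: non-finite cable state")
  tr <- data.frame(t = out[, 1], V_left = Vmid[, 1], V_mid = Vmid[, 2],
                   V_right = Vmid[, 3])
  if (keep_full)
    attr(tr, "V_all") <- out[, vcols, drop = FALSE]
  attr(tr, "cable") <- cable
  attr(tr, "v_rest") <- unname(rest[1])
  attr(tr, "g_bar") <- g_bar
  attr(tr, "e_gaba") <- e_gaba
  attr(tr, "pulses") <- list(nA = pulse_nA, ms = pulse_ms, t0 = pulse_t0,
                             n = n_pulses, interval = pulse_interval)
  class(tr) <- c("cable_trace", "data.frame")
  tr
}

#' Threshold current for spike initiation at the cable end
#'
#' Bisection for the minimum current-pulse amplitude (nA, width
#' `pulse_ms`) injected at the leftmost segment that propagates a spike
#' to the left-compartment midpoint, with no GABA conductance applied.
#'
#' @param cable a [build_cable()] result.
#' @param lower,upper bracket (nA).
#' @param resolution bisection resolution (nA).
#' @param pulse_ms pulse width (ms).
#' @param ... passed to [simulate_cable()].
#' @return threshold in nA (`NA` if `upper` is subthreshold).
#' @export
cable_threshold_current <- function(cable, lower = 0.05, upper = 4,
                                    resolution = 0.05, pulse_ms = 1,
                                    ...) {
  fires <- function(a) {
    tr <- simulate_cable(cable, g_bar = 0, pulse_nA = a,
                         pulse_ms = pulse_ms, pulse_t0 = 20,
                         t_end = 60, ...)
    max(tr$V_left) > 0
  }
  if (!fires(upper)) return(NA_real_)
  lo <- lower; hi <- upper
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Conduction-block assay on the axon cable
#'
#' Runs the standard conduction protocol: a GABA conductance step over
#' the middle compartment, plus a single test pulse or a pulse train at
#' the left end, and classifies what each midpoint saw. For every pulse
#' the assay reports whether the evoked spike appeared at the left and
#' right compartment midpoints (with latencies); propagation through the
#' PAD-affected middle compartment fails when the right midpoint records
#' no spike. Spikes arising at the middle midpoint without a preceding
#' left-midpoint wavefront are attributed to PAD itself, with flags for
#' whether they propagated into the left and right compartments
#' (bidirectional conduction); a PAD spike colliding with an evoked
#' wavefront inside the attribution window is flagged ambiguous rather
#' than silently classified.
#'
#' @param cable a [build_cable()] result.
#' @param g_bar,e_gaba,p conductance density (nS/pF), reversal (mV) and
#'   inactivating fraction.
#' @param pulse_nA pulse amplitude (nA); typically twice
#'   [cable_threshold_current()].
#' @param n_pulses,rate_hz train description (single pulse when
#'   `n_pulses = 1`).
#' @param g_t_on conductance onset (ms).
#' @param single_pulse_delay delay from conductance onset to a single
#'   test pulse (ms), allowing sodium-channel inactivation to develop.
#' @param train_delay delay from conductance onset to the first pulse of
#'   a train (ms).
#' @param attribution_ms window used to attribute midpoint spikes to a
#'   wavefront (ms).
#' @param ... passed to [simulate_cable()].
#' @return a `conduction_result`: per-pulse data frame (`reached_left`,
#'   `reached_right`, latencies), `pad_spikes` data frame (times and
#'   direction flags), `ambiguous` flag and the midpoint `cable_trace`.
#' @export
conduction_assay <- function(cable, g_bar, e_gaba = -35, p = 0,
                             pulse_nA, n_pulses = 1, rate_hz = 20,
                             g_t_on = 50, single_pulse_delay = 400,
                             train_delay = 100, attribution_ms = 10,
                             ...) {
  interval <- 1000 / rate_hz
  t0 <- g_t_on + if (n_pulses == 1) single_pulse_delay else train_delay
  t_end <- t0 + n_pulses * interval + 60
  tr <- simulate_cable(cable, g_bar = g_bar, e_gaba = e_gaba,
                       g_t_on = g_t_on,
                       g_duration = t_end - g_t_on + 100,
                       pulse_nA = pulse_nA, pulse_t0 = t0,
                       n_pulses = n_pulses, pulse_interval = interval,
                       p = p, t_end = t_end, ...)
  spk <- function(V) detect_spikes(data.frame(t = tr$t, V = V))$times
  tl <- spk(tr$V_left); tm <- spk(tr$V_mid); tright <- spk(tr$V_right)

  pulse_times <- t0 + (seq_len(n_pulses) - 1) * interval
  pulse_win <- interval
  per_pulse <- do.call(rbind, lapply(seq_len(n_pulses), function(k) {
    w0 <- pulse_times[k]
    l <- tl[tl >= w0 & tl < w0 + pulse_win]
    r <- tright[tright >= w0 & tright < w0 + pulse_win]
    data.frame(pulse = k, t_pulse = w0,
               reached_left = length(l) > 0,
               latency_left = if (length(l)) l[1] - w0 else NA_real_,
               reached_right = length(r) > 0,
               latency_right = if (length(r)) r[1] - w0 else NA_real_)
  }))

  # PAD-evoked: middle-midpoint spikes with no left-midpoint spike in the
  # preceding attribution window (i.e. not part of a left-origin wavefront)
  pad <- lapply(tm, function(s) {
    fed_from_left <- any(tl >= s - attribution_ms & tl < s)
    if (fed_from_left) return(NULL)
    data.frame(time = s,
               to_left = any(tl > s & tl <= s + attribution_ms),
               to_right = any(tright > s & tright <= s + attribution_ms))
  })
  pad <- do.call(rbind, pad)
  if (is.null(pad))
    pad <- data.frame(time = numeric(0), to_left = logical(0),
                      to_right = logical(0))
  ambiguous <- any(vapply(pad$time, function(s)
    any(abs(pulse_times - s) < attribution_ms + 10), logical(1)))

  structure(list(per_pulse = per_pulse, pad_spikes = pad,
                 ambiguous = ambiguous,
                 blocked = !any(per_pulse$reached_right),
                 g_bar = g_bar, e_gaba = e_gaba, p = p,
                 trace = tr),
            class = "conduction_result")
}

#' @export
print.conduction_result <- function(x, ...) {
  cat(sprintf(
    "<conduction_result> g_bar = %g nS/pF, E_GABA = %g mV, p = %g\n",
    x$g_bar, x$e_gaba, x$p))
  cat(sprintf("pulses propagated: %d/%d; PAD-evoked spikes: %d%s\n",
              sum(x$per_pulse$reached_right), nrow(x$per_pulse),
              nrow(x$pad_spikes),
              if (x$ambiguous) " (ambiguous attribution)" else ""))
  invisible(x)
}
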