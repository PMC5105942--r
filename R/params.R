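#' Biophysical parameter sets for the PAD neuron model
#'
#' Constructs a validated parameter set for the single-compartment
#' Morris-Lecar-type membrane model with depolarizing GABA-A input and
#' optional partial sodium-channel inactivation.
#'
#' Three named presets are provided:
#' \describe{
#'   \item{`"default"`}{the standard single-compartment model:
#'     `C = 2` uF/cm2, `g_Na_bar = 20`, `E_Na = 50` mV, `beta_m = -1.2`,
#'     `gamma_m = 18`, `g_K_bar = 20`, `E_K = -100` mV, `phi_w = 0.15`,
#'     `beta_w = -20`, `gamma_w = 10`, `g_leak = 2`, `E_leak = -70` mV.}
#'   \item{`"revised"`}{identical except `g_leak = 0.7` mS/cm2 and
#'     `g_K_bar = 30` mS/cm2, which raises the sensitivity to GABA
#'     conductance into the sub-1 nS/pF range seen in dissociated DRG
#'     neurons.}
#'   \item{`"cable"`}{identical to `"default"` except
#'     `g_Na_bar = g_K_bar = 30` mS/cm2, used for the multicompartment
#'     axon model.}
#' }
#'
#' The inactivation gate `h` (midpoint `beta_h = -28` mV, slope
#' `gamma_h = -14` mV, rate scale `phi_h = 0.005`) acts on the fraction `p`
#' of sodium channels; with the default `p = 0` the model reduces exactly
#' to the three-current formulation without inactivation.
#'
#' `beta_w` is the excitability dial: shifting it toward 0 mV emulates
#' injury- or 4-AP-induced hyperexcitability. `g_Na_virtual` (nS/pF) adds a
#' non-inactivating virtual sodium conductance as applied via dynamic
#' clamp; its activation curve defaults to the model's own
#' (`beta_mv = beta_m`, `gamma_mv = gamma_m`) but can be overridden.
#'
#' @param ... named overrides of individual fields, e.g. `beta_w = -10`;
#'   a single unnamed character argument is accepted as the preset.
#' @param preset one of `"default"`, `"revised"`, `"cable"`.
#' @return an object of class `neuron_params` (named list of numeric
#'   fields).
#' @examples
#' p <- neuron_params()
#' p$beta_w
#' hot <- neuron_params(beta_w = -10)
#' rev <- neuron_params("revised")
#' @export
neuron_params <- function(..., preset = "default") {
  dots <- list(...)
  nm <- names(dots)
  if (is.null(nm)) nm <- rep("", length(dots))
  un <- which(nm == "")
  if (length(un) == 1L && is.character(dots[[un]])) {
    preset <- dots[[un]]
    dots <- dots[-un]
  } else if (length(un)) {
    stop("unnamed arguments (other than a preset name) are not allowed")
  }
  preset <- match.arg(preset, c("default", "revised", "cable"))
  base <- list(
    C = 2, g_Na_bar = 20, E_Na = 50, beta_m = -1.2, gamma_m = 18,
    g_K_bar = 20, E_K = -100, phi_w = 0.15, beta_w = -20, gamma_w = 10,
    g_leak = 2, E_leak = -70,
    p = 0, beta_h = -28, gamma_h = -14, phi_h = 0.005,
    g_Na_virtual = 0, beta_mv = -1.2, gamma_mv = 18
  )
  if (preset == "revised") {
    base$g_leak <- 0.7
    base$g_K_bar <- 30
  } else if (preset == "cable") {
    base$g_Na_bar <- 30
    base$g_K_bar <- 30
  }
  if (length(dots)) {
    bad <- setdiff(names(dots), names(base))
    if (length(bad))
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    base[names(dots)] <- dots
  }
  out <- structure(base, class = "neuron_params", preset = preset)
  validate_neuron_params(out)
  out
}

#' Validate a neuron parameter set
#'
#' Checks the structural invariants of [neuron_params()]: positive
#' capacitance, nonnegative conductance densities, `p` in `[0, 1]`,
#' `gamma_m > 0`, `gamma_w > 0` and `gamma_h < 0` (so that `h` decreases
#' with depolarization).
#'
#' @param params a `neuron_params` object or plain named list.
#' @return `params`, invisibly; errors on violation.
#' @export
validate_neuron_params <- function(params) {
  need <- c("C", "g_Na_bar", "E_Na", "beta_m", "gamma_m", "g_K_bar", "E_K",
            "phi_w", "beta_w", "gamma_w", "g_leak", "E_leak",
            "p", "beta_h", "gamma_h", "phi_h", "g_Na_virtual")
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("missing parameter field(s): ", paste(miss, collapse = ", "))
  num <- vapply(params[need], function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num))
    stop("non-finite or non-scalar parameter field(s): ",
         paste(need[!num], collapse = ", "))
  if (params$C <= 0) stop("invalid parameter: C must be > 0")
  for (g in c("g_Na_bar", "g_K_bar", "g_leak", "g_Na_virtual"))
    if (params[[g]] < 0) stop("invalid parameter: ", g, " must be >= 0")
  if (params$p < 0 || params$p > 1)
    stop("invalid parameter: p must lie in [0, 1]")
  if (params$gamma_m <= 0) stop("invalid parameter: gamma_m must be > 0")
  if (params$gamma_w <= 0) stop("invalid parameter: gamma_w must be > 0")
  if (params$gamma_h >= 0) stop("invalid parameter: gamma_h must be < 0")
  invisible(params)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>", if (!is.null(attr(x, "preset")))
    paste0("preset: ", attr(x, "preset")), "\n")
  flds <- unlist(x[vapply(x, is.numeric, logical(1))])
  print(flds)
  invisible(x)
}

#' Conductance/current density unit conversions
#'
#' Experimentally, conductances are reported normalized by membrane
#' capacitance (nS/pF) so that results are independent of cell size; the
#' model computes in areal densities (mS/cm2). Because membrane
#' capacitance is proportional to surface area, the two scales are related
#' through the specific capacitance: 1 nS/pF is identical to 1 mS/uF, so
#' `g[mS/cm2] = g[nS/pF] * C[uF/cm2]`. The same factor converts current
#' densities between pA/pF and uA/cm2.
#'
#' @param g conductance in nS/pF (or current in pA/pF for
#'   [papf_to_density()]).
#' @param C membrane capacitance density in uF/cm2.
#' @return the corresponding areal density (mS/cm2 or uA/cm2).
#' @examples
#' nspf_to_density(2, C = 2)  # 4 mS/cm2
#' @export
nspf_to_density <- function(g, C) g * C

#' @rdname nspf_to_density
#' @export
density_to_nspf <- function(g, C) g / C

#' @rdname nspf_to_density
#' @export
papf_to_density <- function(g, C) g * C

#' Steady-state gating curve
#'
#' Boltzmann-style steady state `0.5 * (1 + tanh((V - beta) / gamma))`
#' shared by the instantaneous sodium activation `m`, the recovery
#' variable `w` and the inactivation gate `h` (the latter with negative
#' slope `gamma` so it closes with depolarization).
#'
#' @param V membrane potential (mV); vectorized.
#' @param beta half-activation midpoint (mV).
#' @param gamma slope factor (mV); must be nonzero.
#' @return activation fraction in (0, 1).
#' @export
gating_steady <- function(V, beta, gamma) {
  if (!is.numeric(gamma) || any(gamma == 0))
    stop("invalid parameter: gamma must be nonzero")
  0.5 * (1 + tanh((V - beta) / gamma))
}

#' Gating time-constant factor
#'
#' `tau(V) = 1 / cosh((V - beta) / (2 * gamma))`, an even function of
#' `V - beta` with maximum 1 at `V = beta`. The gating rate is
#' `phi * (x_inf(V) - x) / tau(V)`.
#'
#' @inheritParams gating_steady
#' @return dimensionless time factor in (0, 1].
#' @export
gating_tau <- function(V, beta, gamma) {
  if (!is.numeric(gamma) || any(gamma == 0))
    stop("invalid parameter: gamma must be nonzero")
  1 / cosh((V - beta) / (2 * gamma))
}

#' Membrane model right-hand side
#'
#' Time derivative of the state `(V, w, h)` under the current-balance
#' equation
#' `C dV/dt = I_stim - I_Na - I_K - I_leak - g_GABA(t) (V - E_GABA)`,
#' where the sodium current is split by the inactivating fraction `p`:
#' `I_Na = p gNa m_inf(V) h (V - E_Na) + (1 - p) gNa m_inf(V) (V - E_Na)`,
#' plus any virtual sodium conductance. With `p = 0` the gate `h` has no
#' effect on `dV/dt` and the model reduces to the plain three-current
#' form. `w` and `h` relax toward their steady states with rates scaled by
#' `phi_w` and `phi_h`.
#'
#' This R implementation defines the model; the integration engine uses an
#' identical compiled version for speed.
#'
#' @param state named numeric vector or list with `V` (mV), `w`, `h`.
#' @param t time (ms); unused unless stimuli are time-dependent and
#'   supplied as functions.
#' @param params a [neuron_params()] object.
#' @param g_gaba GABA conductance density at `t` (mS/cm2).
#' @param e_gaba GABA reversal potential (mV).
#' @param i_stim stimulating current density at `t` (uA/cm2).
#' @return numeric vector `c(dV, dw, dh)` (per ms).
#' @export
membrane_rhs <- function(state, t = 0, params = neuron_params(),
                         g_gaba = 0, e_gaba = -35, i_stim = 0) {
  V <- state[["V"]]; w <- state[["w"]]; h <- state[["h"]]
  if (!all(is.finite(c(V, w, h))))
    stop("numerical-state error: non-finite state")
  if (!all(is.finite(c(g_gaba, i_stim))))
    stop("g_gaba and i_stim must be finite")
  pp <- params
  m <- gating_steady(V, pp$beta_m, pp$gamma_m)
  i_na <- pp$g_Na_bar * m * (V - pp$E_Na) * (pp$p * h + (1 - pp$p))
  if (pp$g_Na_virtual > 0)
    i_na <- i_na + nspf_to_density(pp$g_Na_virtual, pp$C) *
      gating_steady(V, pp$beta_mv, pp$gamma_mv) * (V - pp$E_Na)
  i_k <- pp$g_K_bar * w * (V - pp$E_K)
  i_l <- pp$g_leak * (V - pp$E_leak)
  dV <- (i_stim - i_na - i_k - i_l - g_gaba * (V - e_gaba)) / pp$C
  dw <- pp$phi_w * (gating_steady(V, pp$beta_w, pp$gamma_w) - w) /
    gating_tau(V, pp$beta_w, pp$gamma_w)
  dh <- pp$phi_h * (gating_steady(V, pp$beta_h, pp$gamma_h) - h) /
    gating_tau(V, pp$beta_h, pp$gamma_h)
  c(dV = dV, dw = dw, dh = dh)
}

#' Resting state of the model
#'
#' Finds the stimulus-free fixed point by solving the one-dimensional
#' steady-state current equation with `w = w_inf(V)` and `h = h_inf(V)` by
#' bracketed root finding on `[-100, 0]` mV (tolerance 1e-9 mV). This
#' provides deterministic initial conditions for every protocol. For the
#' default parameters the rest sits near -69.4 mV, just above the leak
#' reversal.
#'
#' @param params a [neuron_params()] object.
#' @return named numeric vector `c(V, w, h)` at rest.
#' @export
resting_state <- function(params = neuron_params()) {
  validate_neuron_params(params)
  ssc <- function(V) {
    h <- gating_steady(V, params$beta_h, params$gamma_h)
    w <- gating_steady(V, params$beta_w, params$gamma_w)
    i_na <- params$g_Na_bar * gating_steady(V, params$beta_m, params$gamma_m) *
      (V - params$E_Na) * (params$p * h + (1 - params$p))
    if (params$g_Na_virtual > 0)
      i_na <- i_na + nspf_to_density(params$g_Na_virtual, params$C) *
        gating_steady(V, params$beta_mv, params$gamma_mv) * (V - params$E_Na)
    -i_na - params$g_K_bar * w * (V - params$E_K) -
      params$g_leak * (V - params$E_leak)
  }
  # strong regenerative conductances can create several fixed points;
  # take the most hyperpolarized one (the physiological rest)
  vs <- seq(-100, 0, by = 0.5)
  cur <- vapply(vs, ssc, numeric(1))
  if (!all(is.finite(cur)))
    stop("convergence error: non-finite steady-state current")
  flip <- which(cur[-length(cur)] * cur[-1] <= 0)[1]
  if (is.na(flip))
    stop("convergence error: no fixed point bracketed in [-100, 0] mV")
  V0 <- stats::uniroot(ssc, c(vs[flip], vs[flip + 1]), tol = 1e-9)$root
  c(V = V0,
    w = gating_steady(V0, params$beta_w, params$gamma_w),
    h = gating_steady(V0, params$beta_h, params$gamma_h))
}
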